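"""Thin MILP backend: reads a JSON model description, solves it with HiGHS
via scipy.optimize.milp, writes a JSON result. Part of the hospalloc solver
backend contract; holds no modeling logic."""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp

BIG = 1e29


def main(path_in, path_out):
    with open(path_in) as fh:
        spec = json.load(fh)
    n = int(spec["n_var"])
    c = np.asarray(spec["obj"], dtype=float)
    sign = -1.0 if spec.get("maximize", True) else 1.0
    rlb = np.atleast_1d(np.asarray(spec["rlb"], dtype=float))
    rub = np.atleast_1d(np.asarray(spec["rub"], dtype=float))
    rlb[rlb <= -BIG] = -np.inf
    rub[rub >= BIG] = np.inf
    m = rlb.size
    ai = np.atleast_1d(np.asarray(spec["ai"], dtype=np.int64)) - 1
    aj = np.atleast_1d(np.asarray(spec["aj"], dtype=np.int64)) - 1
    av = np.atleast_1d(np.asarray(spec["av"], dtype=float))
    constraints = []
    if m:
        a_mat = sparse.csc_array((av, (ai, aj)), shape=(m, n))
        constraints = LinearConstraint(a_mat, rlb, rub)
    options = {"disp": bool(spec.get("verbose", False))}
    if spec.get("time_limit") is not None:
        options["time_limit"] = float(spec["time_limit"])
    if spec.get("mip_gap") is not None:
        options["mip_rel_gap"] = float(spec["mip_gap"])
    res = milp(
        sign * c,
        constraints=constraints,
        integrality=np.atleast_1d(np.asarray(spec["integrality"], dtype=int)),
        bounds=Bounds(
            np.atleast_1d(np.asarray(spec["lb"], dtype=float)),
            np.atleast_1d(np.asarray(spec["ub"], dtype=float)),
        ),
        options=options,
    )
    gap = getattr(res, "mip_gap", None)
    out = {
        "status": int(res.status),
        "message": str(res.message),
        "x": None if res.x is None else [float(v) for v in res.x],
        "objective": None if res.fun is None else float(sign * res.fun),
        "mip_gap": None if gap is None else float(gap),
    }
    with open(path_out, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
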