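---
title: "Designing a hospital landscape: the model behind hospalloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing a hospital landscape: the model behind hospalloc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A national hospital system faces a three-way trade-off. Concentrating the
treatment of a condition on few locations raises per-site volume and, for
complex conditions, measurably improves outcomes (the volume-outcome
relationship). Dispersing care over many locations shortens patient travel,
which matters most for chronic conditions with frequent visits and for acute
conditions with legal reachability limits. And any location that operates an
operating room (OR), ward or intensive-care unit (ICU) should run it at an
efficient scale.

`hospalloc` casts this trade-off as a mixed-integer program over roughly 30
diagnosis groups, a set of demand zip areas and a set of candidate hospital
sites. For each group $d$ the model chooses which sites offer it
($Z_{q,d}$), which sites are open at all ($X_q$), and which site serves each
zip area's demand ($Y_{p,q,d}$), maximizing

$$\max \sum_d \left( \mathrm{Quality}_d - \mathrm{Travel}_d \right)$$

with

$$\mathrm{Quality}_d = EQ \cdot NP_d \,(a_d\,NL_d + b_d), \qquad
\mathrm{Travel}_d = 2\,ET\,NV_d \sum_{p,q} NP^D_{p,d}\,Y_{p,q,d}\,TT_{p,q}/60,$$

where $NL_d = \sum_q Z_{q,d}$ is the number of locations treating group
$d$, $NP_d$ its annual admissions, $NP^D_{p,d}$ the admissions living in zip
$p$, $NV_d$ visits per patient, $TT_{p,q}$ the drive time in minutes, $EQ$
the monetary value of a QALY and $ET$ the travel cost per person-hour on the
road. The constraints are: every zip's demand for every group is served by
exactly one site; assignments only to offering sites and offerings only at
open sites; a per-group maximum travel time $maxt_d$ (45 minutes for acute
groups, 120 otherwise), enforced by simply not creating assignment variables
beyond the limit; minimum annual facility utilization (below); and one
obligatory co-location pair - gynaecology and pregnancy/childbirth care must
offer at identical site sets.

Two published constraint lines deserve a note. The printed completeness
constraint reduces to a bare "$X_p = 1$"; read literally it would force all
sites open and make the location choice vacuous, so the package implements
the only reading consistent with the model's results, assignment
completeness $\sum_q Y_{p,q,d} = 1$ for all $p, d$. Likewise the printed
utilization constraint indexes sites by the demand index $p$; the package
corrects it to the site index $q$.

# Quality calibration

Per-patient quality is a piecewise-linear function of $NL_d$ anchored on a
single quantified reference: concentrating the strongest
("high") volume-outcome category from 94 to 15 locations gains 0.5 QALY per
patient. The high-category slope is therefore $-0.5/79 \approx -0.00633$
QALY/patient per location, and the other categories are fixed fractions of
it: intermediate 50%, low 5%, none 0%. The intercept is normalized so the
gain is zero at the 94-location baseline: quality is reported as gain versus
the status quo, which shifts the objective by a constant and never changes
the argmax, but makes reports interpretable.

The underlying relationship is in truth convex (the first locations removed
gain the most), so the model works with linear segments over location-count
intervals, with default knots at 1, 15, 40, 94 and the candidate count.
The default build uses one slope everywhere (the function is globally
linear, and the segments only matter to the refinement loop); an optional
convex build steepens the slope below 15 locations by a configurable factor
(default 2), preserving continuity at the knots to within $10^{-9}$
QALY/patient. The knot positions are a package choice - they bracket the
location-count range the model actually visits - as the exact intervals
behind the published analysis are not recorded. Similarly, whether the
published intercepts encoded absolute QALYs or gains is not recorded; only
differences matter to the optimum, so the gain normalization is safe.

Because each solve uses one linear segment per group, an outer refinement
loop reconciles segment choice with the optimum: start on the segment
containing the baseline, solve, and whenever a group's optimal $NL_d$ falls
outside its active segment's interval, activate the segment containing it
and re-solve. The loop stops at a fixed point, on a detected cycle, or at an
iteration cap (default 10), returning the visited solution with the best
objective evaluated on the full piecewise function (all reported solution
objectives are evaluated that way, never on the active segment, so iterates
are comparable and the returned solution is never worse than any iterate).

# Utilization semantics

Benchmark-derived annual minima make a site's facilities "efficient": OR
$0.65 \times 48 \times 5 \times 8 = 1248$ h, ward $0.8 \times 12 \times 365
= 3504$ bed-days, ICU $6 \times 365 = 2190$ bed-days. Facilities are shared
across groups at a site and uncapacitated.

Read literally, the published constraint forces every open site to run an
efficient OR, ward *and* ICU - which contradicts its own headline result of
chronic care at every location, since chronic-only sites need no OR. The
package's default mode `conditional` therefore introduces a facility-present
binary $W_{q,f}$ with semicontinuous usage: a facility at a site is either
absent (zero usage) or efficiently used (usage $\ge minu_f$). The `literal`
mode implements the printed form for fidelity experiments;
`compare_landscapes()` puts the two side by side, and the conditional
objective is provably never worse (it is a relaxation).

# Travel costs

$ET$ defaults to 172 euro per person-hour: taxi transport at 2.20 euro/km
and 60 km/h (132 euro/h) plus lost income at the median 32,000 euro over
1,600 working hours (20 euro/h) for the patient and one accompanying
person. The factor 2 in $\mathrm{Travel}_d$ is read as out-and-back travel;
whether the published factor was the round trip or the companion is
ambiguous, but both readings scale travel identically, so the companion is
folded into $ET$ and the factor kept at 2. Drive times are carried in
minutes everywhere and converted to hours exactly once, inside
`compute_travel_eur()`.

# The synthetic country

The real inputs - the national drive-time matrix, zip-level demographics and
registry resource use - are proprietary, so `generate_instance()` builds a
synthetic stand-in that targets their statistical shape, not their
geography:

* **Zips**: a clustered spatial process (one urban core per ~50 zips plus a
  40% uniform rural background) on a square region; log-normal populations
  rescaled to a 16.6M total.
* **Region size**: the full-scale configuration is 794 zips and 150
  candidate sites on a 200 km square. Scaled-down instances keep the
  *candidate density* of that configuration ($200\sqrt{n_{sites}/150}$ km),
  so reachability behaves the same at desk scale as at full scale.
* **Candidate sites**: the highest-population zips stand in for existing
  hospitals; a greedy disk-cover pass then guarantees every zip a candidate
  within the acute travel radius (with a 6-minute slack against travel-time
  noise) - reachability outranks the existing-hospital prior if the budget
  binds, mirroring the fact that the real candidate set trivially satisfies
  the 45-minute rule; the remaining budget minimizes population-weighted
  travel (greedy p-median plus coverage-preserving single-swap search).
* **Drive times**: Euclidean kilometers times a road detour factor (1.3) at
  60 km/h, plus zero-truncated Gaussian noise (sd 1.5 min); symmetric by
  construction (the model never uses the reverse direction).
* **Demand**: each group's admissions spread proportionally to zip
  population and rounded by largest remainder, so column sums are exact.
* **Resource use**: per-patient OR hours, ward and ICU bed-days drawn from
  uniform ranges by care class (chronic groups: no OR or ICU use; acute
  groups the highest ICU fractions).
* **Visits per patient** are not published per group; the defaults by care
  class (chronic 8, elective 3, acute 2, mixed 5) are package choices and
  configurable.

What passing tests on this generator do *not* show: agreement with real
geography, asymmetric road networks, heterogeneous per-group demand
geography, or patient choice behavior. The published headline numbers
(12-14 locations for the strongest groups, 150 for chronic groups, 14.9
versus 28.9 minutes) depend on the proprietary inputs and are reproduced in
*pattern* only: on synthetic countries the strong-volume-outcome groups
settle on strictly fewer locations than the no-relationship groups, and
dispersed chronic-style demand travels less than concentrated demand.

# Numerical choices

* The solver backend is HiGHS (via `scipy.optimize.milp` in a Python
  subprocess), single-threaded and deterministic; any MILP engine honoring
  the JSON model contract can be swapped in via `options(hospalloc.backend=)`.
* Default linking is the per-pair form $Y \le Z$, $Z \le X$; the published
  aggregated big-M inequalities are available as `linking_mode = "big_m"`
  and reach the same integer optimum with a weaker LP relaxation.
* Quality, travel and the objective of every returned solution are
  recomputed in R from the variable values; nothing is trusted from the
  solver, and every solution must pass the independent validator.
* For groups with no volume-outcome relation, offering variables are
  objective-neutral wherever unused, so solutions are canonicalized to
  minimal offerings (only sites actually serving demand count toward
  $NL_d$), except inside co-location pairs. Objectives are unaffected.
* Ties among equidistant sites are broken by the lower site index in the
  oracle and validator; MIP solves may return either tied optimum.
* Demand conservation tolerates one patient per group (integer rounding);
  monetary bookkeeping is checked to $10^{-6}$ relative.
* Degenerate inputs: uncovered zip-group pairs are diagnosed *before* any
  solve and raised as a structured condition listing the pairs; infeasible
  utilization demands return a solution object with status `infeasible`
  rather than an exception.

# Problem sizes

The exact brute-force oracle (independent of the MIP machinery: bitmask
enumeration of offerings, closed-form nearest assignment when no minima
couple zips, full assignment enumeration otherwise) anchors correctness on
instances up to 8 zips, 5 sites and 3 groups; beyond its `max_states` guard
it refuses with a size estimate rather than run unbounded. The package's
test suite cross-validates the optimizer against it on over 50 seeded
micro-instances in both utilization modes, runs the willingness-to-pay
sensitivity direction on 20 single-group instances, and runs the landscape
experiment on synthetic countries of 100 zips, 20 candidate sites and the
full 30-group table over 5 seeds - sizes chosen so the whole suite completes
in minutes on one CPU while still exercising every constraint family at
national structure. The landscape experiment accepts a $10^{-3}$ relative
MIP gap; the qualitative orderings it asserts are far coarser than that.

# Known limitations

* Demand is deterministic and single-year; no stochastic or multi-year
  dynamics.
* Patients are assigned, not choosing: individual willingness-to-travel
  heterogeneity is out of scope.
* Economies of scale and scope, and competition price effects, are excluded
  by design.
* The oracle does not scale beyond micro-instances; at national scale the
  only optimality certificate is the solver's bound (reported as `gap`).
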