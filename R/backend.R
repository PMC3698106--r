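# Solver backend contract: milp_solve() takes a `hosp_model` plus limits and
# returns variable values, a status and a bound gap. The shipped backend
# hands the sparse model to HiGHS through scipy.optimize.milp in a Python
# subprocess; any MILP engine honoring the same JSON contract is pluggable
# via options("hospalloc.backend").

python_bin <- function() {
  opt <- getOption("hospalloc.python", NULL)
  if (!is.null(opt)) return(opt)
  for (cand in c("python", "python3"))
    if (nzchar(Sys.which(cand))) return(cand)
  stop("no python interpreter found on PATH; the HiGHS backend requires ",
       "python with scipy >= 1.9", call. = FALSE)
}

#' Solve an abstract MILP model
#'
#' Dispatches a [build_model()] result to the configured backend (default:
#' HiGHS through `scipy.optimize.milp` in a Python subprocess, single-threaded
#' and deterministic).
#'
#' @param model a `hosp_model`.
#' @param time_limit_s wall-clock limit in seconds.
#' @param mip_gap relative optimality gap.
#' @param verbose print the solver log.
#' @return list with elements `status` (one of `"optimal"`, `"feasible"`,
#'   `"infeasible"`, `"error"`), `x` (variable values or `NULL`),
#'   `objective` (including the model's constant term) and `gap`.
#' @export
milp_solve <- function(model, time_limit_s = 120, mip_gap = 1e-6,
                       verbose = FALSE) {
  backend <- getOption("hospalloc.backend", milp_solve_highs)
  backend(model, time_limit_s = time_limit_s, mip_gap = mip_gap,
          verbose = verbose)
}

milp_solve_highs <- function(model, time_limit_s = 120, mip_gap = 1e-6,
                             verbose = FALSE) {
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  clip <- function(v) { v[v == Inf] <- 1e30; v[v == -Inf] <- -1e30; v }
  payload <- list(
    n_var = model$n_var, maximize = model$maximize,
    obj = model$obj,
    ai = model$ai, aj = model$aj, av = model$av,
    rlb = clip(model$rlb), rub = clip(model$rub),
    lb = model$lb, ub = model$ub,
    integrality = model$integrality,
    time_limit = time_limit_s, mip_gap = mip_gap,
    verbose = verbose)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA,
                       null = "null")
  script <- system.file("python", "milp_highs.py", package = "hospalloc")
  res <- suppressWarnings(system2(python_bin(), c(shQuote(script),
                                                  shQuote(fin), shQuote(fout)),
                                  stdout = if (verbose) "" else TRUE,
                                  stderr = if (verbose) "" else TRUE))
  if (!file.exists(fout) || !file.size(fout))
    stop("MILP backend failed: ",
         paste(utils::tail(as.character(res), 20), collapse = "\n"),
         call. = FALSE)
  out <- jsonlite::fromJSON(fout)
  status <- switch(as.character(out$status),
                   "0" = "optimal",
                   "1" = if (is.null(out$x)) "error" else "feasible",
                   "2" = "infeasible",
                   "error")
  list(status = status,
       x = if (is.null(out$x)) NULL else as.numeric(out$x),
       objective = if (is.null(out$objective)) NA_real_
                   else out$objective + model$constant,
       gap = if (is.null(out$mip_gap)) NA_real_ else out$mip_gap,
       message = out$message)
}
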