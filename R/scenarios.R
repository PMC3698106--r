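# Desk-scale analysis patterns: willingness-to-pay sensitivity sweeps over
# the euro-per-QALY rate, patient-weighted travel-time reporting by care
# class, and side-by-side scenario comparison.

#' Sensitivity sweep over the euro-per-QALY rate
#'
#' Re-solves the instance (with segment refinement) at each willingness-to-
#' pay value and records per-group optimal location counts, objectives,
#' total quality in QALYs and patient-weighted travel times by care class.
#' Raising the price of a QALY makes concentration more attractive, so
#' location counts of groups with a volume-outcome relationship fall (and
#' total quality in QALYs rises) along the sweep.
#'
#' @param inst a `hosp_instance`.
#' @param eq_values euro-per-QALY values (default 20000, 50000, 100000).
#' @param options a [solve_options()].
#' @param keep_solutions keep the full solution objects (default `TRUE`).
#' @return object of class `sweep_result`: list with `eq_values`,
#'   `n_locations` (groups x values matrix), `objectives`, `quality_qaly`,
#'   `travel_minutes_mean` (care classes x values), and optionally
#'   `solutions`.
#' @export
eq_sweep <- function(inst, eq_values = c(20000, 50000, 100000),
                     options = solve_options(), keep_solutions = TRUE) {
  stopifnot(length(eq_values) >= 1, all(eq_values > 0))
  D <- nrow(inst$groups)
  nl <- matrix(NA_integer_, D, length(eq_values),
               dimnames = list(inst$groups$id, eq_values))
  objs <- qaly <- numeric(length(eq_values))
  classes <- sort(unique(inst$groups$care_class))
  tmeans <- matrix(NA_real_, length(classes), length(eq_values),
                   dimnames = list(classes, eq_values))
  sols <- vector("list", length(eq_values))
  for (e in seq_along(eq_values)) {
    inst_e <- inst
    inst_e$config$euros_per_qaly <- eq_values[e]
    sol <- solve_with_refinement(inst_e, options)
    if (sol$solver_status %in% c("infeasible", "error"))
      stop("sweep aborted: solve at EQ = ", eq_values[e], " returned status ",
           sol$solver_status, call. = FALSE)
    nl[, e] <- sol$n_locations
    objs[e] <- sol$objective_eur
    qaly[e] <- sum(sol$quality_eur) / eq_values[e]
    rep_e <- travel_report(inst_e, sol)
    tmeans[, e] <- rep_e$mean_min[match(classes, rep_e$care_class)]
    if (keep_solutions) sols[[e]] <- sol
  }
  structure(list(eq_values = eq_values, n_locations = nl,
                 objectives = objs, quality_qaly = qaly,
                 travel_minutes_mean = tmeans,
                 solutions = if (keep_solutions) sols),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("EQ sweep over", paste(format(x$eq_values, big.mark = ","),
                             collapse = ", "), "euro/QALY\n")
  cat("locations per group:\n")
  print(x$n_locations)
  cat("total quality (QALY):", format(round(x$quality_qaly, 1)), "\n")
  invisible(x)
}

#' Patient-weighted travel times by care class
#'
#' One-way drive minutes to the assigned site, weighted by patient visits
#' (`NP^D x NV`), summarized per care class and overall, next to the
#' all-candidate-sites-open nearest-site baseline (the current-landscape
#' analog). The objective prices round trips in euros; this report stays in
#' one-way minutes.
#'
#' @param inst a `hosp_instance`.
#' @param sol a feasible `hosp_solution` for it.
#' @return data frame with columns `care_class` (including `"overall"`),
#'   `mean_min` and `baseline_mean_min`.
#' @export
travel_report <- function(inst, sol) {
  P <- nrow(inst$zips); D <- nrow(inst$groups)
  w <- sweep(inst$demand, 2, inst$groups$n_visits, "*")
  tt <- vapply(seq_len(D), function(j)
    inst$travel[cbind(seq_len(P), sol$assign[, j])], numeric(P))
  tt0 <- apply(inst$travel, 1, min)
  classes <- sort(unique(inst$groups$care_class))
  rows <- lapply(classes, function(cl) {
    js <- which(inst$groups$care_class == cl)
    data.frame(care_class = cl,
               mean_min = sum(w[, js] * tt[, js]) / sum(w[, js]),
               baseline_mean_min = sum(w[, js] * tt0) / sum(w[, js]))
  })
  overall <- data.frame(care_class = "overall",
                        mean_min = sum(w * tt) / sum(w),
                        baseline_mean_min = sum(w * rep(tt0, D)) / sum(w))
  out <- rbind(do.call(rbind, rows), overall)
  rownames(out) <- NULL
  out
}

#' Compare labeled solution landscapes side by side
#'
#' @param inst a `hosp_instance`.
#' @param solutions named list of feasible `hosp_solution` objects; labels
#'   must be unique.
#' @return tidy data frame with one row per (label, group): location counts,
#'   quality and travel euros, plus per-label objective and open-site count.
#' @export
compare_landscapes <- function(inst, solutions) {
  if (is.null(names(solutions)) || any(names(solutions) == "") ||
      anyDuplicated(names(solutions)))
    stop("solutions must carry unique, non-empty labels", call. = FALSE)
  out <- lapply(names(solutions), function(lbl) {
    s <- solutions[[lbl]]
    if (is.null(s$offers))
      stop("solution '", lbl, "' is ", s$solver_status,
           " and cannot be tabulated", call. = FALSE)
    data.frame(label = lbl,
               group_id = inst$groups$id,
               care_class = inst$groups$care_class,
               n_locations = as.integer(s$n_locations),
               quality_eur = as.numeric(s$quality_eur),
               travel_eur = as.numeric(s$travel_eur),
               objective_eur = s$objective_eur,
               open_sites = sum(s$open),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
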