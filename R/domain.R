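#' Facility types and their default minimum annual utilizations
#'
#' Three shared, uncapacitated facility types are modeled at each site:
#' operating rooms (OR, hours/year), wards (occupied bed-days/year) and
#' intensive-care units (ICU, occupied bed-days/year). The default minima are
#' benchmark-derived: OR 65% of 48 weeks x 5 days x 8 hours = 1248 h/yr;
#' ward 80% of 12 beds x 365 days = 3504 bed-days/yr; ICU 6 beds x 365 days
#' = 2190 bed-days/yr.
#'
#' @return named numeric vector `c(OR=, WARD=, ICU=)`.
#' @export
default_min_utilization <- function() {
  c(OR = 0.65 * 48 * 5 * 8, WARD = 0.8 * 12 * 365, ICU = 6 * 365)
}

facility_types <- function() c("OR", "WARD", "ICU")

#' Model configuration
#'
#' @param euros_per_qaly willingness to pay per QALY (`EQ`), euros.
#' @param euros_per_travel_hour travel cost per person-hour on the road
#'   (`ET`). The default 172 combines taxi cost (2.20 euro/km at 60 km/h =
#'   132 euro/h) with lost income for the patient and one accompanying person
#'   (2 x 32000/1600 = 40 euro/h).
#' @param round_trip_factor trips are out-and-back (default 2).
#' @param big_m big-M constant for the aggregated linking mode.
#' @param mip_gap relative MIP optimality gap passed to the solver.
#' @param utilization_mode `"conditional"` (a facility at a site is either
#'   absent or meets its minimum utilization; default) or `"literal"` (every
#'   open site must meet every facility minimum).
#' @param min_utilization named vector of per-facility annual minima; zeros
#'   disable the constraint.
#' @param seed integer seed controlling any randomized component.
#' @param max_refinement_iters cap on piecewise-segment refinement iterations.
#' @return object of class `model_config`.
#' @export
model_config <- function(euros_per_qaly = 50000,
                         euros_per_travel_hour = 172,
                         round_trip_factor = 2,
                         big_m = 1e6,
                         mip_gap = 1e-6,
                         utilization_mode = c("conditional", "literal"),
                         min_utilization = default_min_utilization(),
                         seed = 1L,
                         max_refinement_iters = 10L) {
  utilization_mode <- match.arg(utilization_mode)
  euros_per_qaly <- as.numeric(euros_per_qaly)
  euros_per_travel_hour <- as.numeric(euros_per_travel_hour)
  round_trip_factor <- as.numeric(round_trip_factor)
  big_m <- as.numeric(big_m)
  mip_gap <- as.numeric(mip_gap)
  stopifnot(euros_per_qaly > 0, euros_per_travel_hour > 0,
            round_trip_factor > 0, big_m > 0, mip_gap >= 0,
            max_refinement_iters >= 1)
  mu <- rep(0, 3); names(mu) <- facility_types()
  mu[names(min_utilization)] <- min_utilization
  if (any(mu < 0)) stop("min_utilization must be non-negative", call. = FALSE)
  structure(list(euros_per_qaly = euros_per_qaly,
                 euros_per_travel_hour = euros_per_travel_hour,
                 round_trip_factor = round_trip_factor,
                 big_m = big_m, mip_gap = mip_gap,
                 utilization_mode = utilization_mode,
                 min_utilization = mu,
                 seed = as.integer(seed),
                 max_refinement_iters = as.integer(max_refinement_iters)),
            class = "model_config")
}

#' Assemble an optimization instance
#'
#' Bundles diagnosis groups, zip areas, candidate sites, the drive-time
#' matrix, the zip-by-group demand matrix, per-patient facility usage,
#' per-group quality functions and the model configuration into a validated
#' `hosp_instance`.
#'
#' @param groups data frame with columns `id`, `name`, `care_class`,
#'   `vo_category`, `n_patients`, `n_visits`, `max_travel_min` (and optionally
#'   `annual_cost_meur`).
#' @param zips data frame with columns `id`, `x_km`, `y_km`, `population`.
#' @param sites data frame with columns `id`, `x_km`, `y_km` (and optionally
#'   `from_existing_hospital`).
#' @param travel numeric matrix of drive times in minutes, zips x sites.
#' @param demand integer matrix of patients/year, zips x groups; each column
#'   must sum to the group's `n_patients` within one patient.
#' @param usage numeric matrix groups x facilities (`OR`, `WARD`, `ICU`) of
#'   facility units used per patient.
#' @param quality named list of [build_quality_function()] objects, one per
#'   group id (as character names).
#' @param colocate two-column matrix/data frame of group-id pairs that must
#'   offer care at identical site sets; default pairs gynecology (21) with
#'   pregnancy/childbirth care (23) when both are present.
#' @param config a [model_config()].
#' @return object of class `hosp_instance`.
#' @export
hosp_instance <- function(groups, zips, sites, travel, demand, usage,
                          quality, colocate = NULL, config = model_config()) {
  groups <- as.data.frame(groups)
  zips <- as.data.frame(zips)
  sites <- as.data.frame(sites)
  if (is.null(sites$from_existing_hospital))
    sites$from_existing_hospital <- FALSE
  if (is.null(colocate)) {
    colocate <- if (all(c(21L, 23L) %in% groups$id))
      matrix(c(21L, 23L), ncol = 2) else matrix(integer(0), ncol = 2)
  }
  colocate <- matrix(as.integer(as.matrix(colocate)), ncol = 2)
  travel <- as.matrix(travel)
  demand <- as.matrix(demand)
  usage <- as.matrix(usage)
  dimnames(travel) <- list(zips$id, sites$id)
  dimnames(demand) <- list(zips$id, groups$id)
  dimnames(usage) <- list(groups$id, colnames(usage))
  inst <- structure(list(groups = groups, zips = zips, sites = sites,
                         travel = travel, demand = demand, usage = usage,
                         quality = quality, colocate = colocate,
                         config = config),
                    class = "hosp_instance")
  validate_instance(inst)
  inst
}

#' Validate an instance's structural invariants
#'
#' Checks dimensions, positivity of populations and admissions, finiteness and
#' non-negativity of drive times, presence of a usage entry for every facility
#' type, per-group demand conservation (column sums equal `n_patients` within
#' one patient, absorbing integer rounding of the spread), and quality
#' function domains.
#'
#' @param inst a `hosp_instance`.
#' @return the instance, invisibly; stops with an informative message on the
#'   first violation.
#' @export
validate_instance <- function(inst) {
  stopifnot(inherits(inst, "hosp_instance"))
  g <- inst$groups
  need <- c("id", "name", "care_class", "vo_category", "n_patients",
            "n_visits", "max_travel_min")
  miss <- setdiff(need, names(g))
  if (length(miss))
    stop("groups table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(g$id)) stop("duplicate group ids", call. = FALSE)
  if (any(g$n_patients <= 0)) stop("n_patients must be positive", call. = FALSE)
  if (any(g$max_travel_min <= 0)) stop("max_travel_min must be positive", call. = FALSE)
  if (any(inst$zips$population <= 0)) stop("zip populations must be positive", call. = FALSE)
  if (anyDuplicated(inst$sites$id)) stop("duplicate site ids", call. = FALSE)
  if (!all(is.finite(inst$travel)) || any(inst$travel < 0))
    stop("travel times must be finite and non-negative", call. = FALSE)
  if (!identical(dim(inst$travel), c(nrow(inst$zips), nrow(inst$sites))))
    stop("travel matrix must be zips x sites", call. = FALSE)
  if (!identical(dim(inst$demand), c(nrow(inst$zips), nrow(g))))
    stop("demand matrix must be zips x groups", call. = FALSE)
  if (any(inst$demand < 0)) stop("demand entries must be non-negative", call. = FALSE)
  bad <- which(abs(colSums(inst$demand) - g$n_patients) > 1)
  if (length(bad))
    stop("demand conservation violated for group(s) ",
         paste(g$id[bad], collapse = ", "),
         " (column sum differs from n_patients by more than 1)", call. = FALSE)
  if (!all(facility_types() %in% colnames(inst$usage)))
    stop("usage matrix must have columns OR, WARD, ICU", call. = FALSE)
  if (nrow(inst$usage) != nrow(g))
    stop("usage matrix must have one row per group", call. = FALSE)
  if (any(inst$usage < 0)) stop("usage entries must be non-negative", call. = FALSE)
  if (!all(as.character(g$id) %in% names(inst$quality)))
    stop("quality function missing for some group", call. = FALSE)
  for (id in as.character(g$id)) {
    qf <- inst$quality[[id]]
    if (max(qf$nl_hi) < nrow(inst$sites))
      stop("quality function for group ", id,
           " does not cover [1, n_sites]", call. = FALSE)
  }
  if (length(inst$colocate) &&
      !all(inst$colocate %in% g$id))
    stop("colocate refers to unknown group ids", call. = FALSE)
  invisible(inst)
}

#' Construct a solution object
#'
#' @param inst the instance the solution refers to.
#' @param open logical vector over sites (`X_q`).
#' @param offers 0/1 matrix sites x groups (`Z_{q,d}`).
#' @param assign integer matrix zips x groups, entry = index of the site
#'   serving that zip's demand for that group (`Y_{p,q,d}` in single-
#'   assignment form).
#' @param status solver status string.
#' @param gap reported relative MIP gap (0 for exact methods).
#' @return object of class `hosp_solution` with derived per-group location
#'   counts, quality and travel euros and the total objective.
#' @export
hosp_solution <- function(inst, open, offers, assign,
                          status = "optimal", gap = 0) {
  Q <- nrow(inst$sites); D <- nrow(inst$groups); P <- nrow(inst$zips)
  stopifnot(length(open) == Q, identical(dim(offers), c(Q, D)),
            identical(dim(assign), c(P, D)))
  offers <- matrix(as.integer(offers), Q, D,
                   dimnames = list(inst$sites$id, inst$groups$id))
  assign <- matrix(as.integer(assign), P, D,
                   dimnames = list(inst$zips$id, inst$groups$id))
  nl <- colSums(offers)
  eq <- inst$config$euros_per_qaly
  quality_eur <- travel_eur <- numeric(D)
  for (j in seq_len(D)) {
    gid <- as.character(inst$groups$id[j])
    quality_eur[j] <- evaluate_quality_eur(inst$groups[j, ],
                                           inst$quality[[gid]], nl[j], eq)
    travel_eur[j] <- compute_travel_eur(inst, assign, j)
  }
  names(nl) <- names(quality_eur) <- names(travel_eur) <- inst$groups$id
  structure(list(open = stats::setNames(as.logical(open), inst$sites$id),
                 offers = offers, assign = assign,
                 n_locations = nl, quality_eur = quality_eur,
                 travel_eur = travel_eur,
                 objective_eur = sum(quality_eur - travel_eur),
                 solver_status = status, gap = gap),
            class = "hosp_solution")
}

#' Travel cost in euros for one group under an assignment
#'
#' `Travel_d = rt * ET * NV_d * sum_p NP^D_{p,d} * TT_{p, assign(p)} / 60`:
#' drive times are carried in minutes throughout the package and converted to
#' hours only here, where they meet the per-hour travel cost.
#'
#' @param inst instance.
#' @param assign zips x groups site-index matrix (see [hosp_solution()]).
#' @param group_idx column index of the group in `inst$groups`.
#' @return euros per year.
#' @export
compute_travel_eur <- function(inst, assign, group_idx) {
  j <- group_idx
  tt <- inst$travel[cbind(seq_len(nrow(inst$zips)), assign[, j])]
  w <- inst$demand[, j]
  inst$config$round_trip_factor * inst$config$euros_per_travel_hour *
    inst$groups$n_visits[j] * sum(w * tt) / 60
}

# annual facility usage at each site implied by an assignment:
# sites x facilities matrix
site_usage <- function(inst, assign) {
  Q <- nrow(inst$sites)
  out <- matrix(0, Q, 3, dimnames = list(inst$sites$id, facility_types()))
  for (j in seq_len(nrow(inst$groups))) {
    w <- inst$demand[, j]
    if (!any(w > 0)) next
    per_site <- vapply(seq_len(Q), function(q) sum(w[assign[, j] == q]),
                       numeric(1))
    for (f in facility_types())
      out[, f] <- out[, f] + per_site * inst$usage[j, f]
  }
  out
}

#' Independent feasibility validation of a solution
#'
#' Re-checks every model constraint directly against the instance data,
#' without reference to any solver: completeness of zip assignments,
#' assignment-to-offering and offering-to-open linking, maximum travel times,
#' minimum facility utilization (under the configured mode), co-location
#' pairs, location-count accounting, and the internal quality/travel/objective
#' bookkeeping.
#'
#' @param inst a `hosp_instance`.
#' @param sol a `hosp_solution` over the same index sets; mismatched
#'   dimensions raise a structural error (condition class
#'   `hosp_structural_error`), which is distinct from an infeasibility report.
#' @param tol relative tolerance for the monetary bookkeeping checks.
#' @return data frame of violations with columns `kind` and `detail`;
#'   zero rows means the solution is feasible.
#' @export
validate_solution <- function(inst, sol, tol = 1e-6) {
  stopifnot(inherits(inst, "hosp_instance"), inherits(sol, "hosp_solution"))
  Q <- nrow(inst$sites); D <- nrow(inst$groups); P <- nrow(inst$zips)
  if (length(sol$open) != Q || !identical(dim(sol$offers), c(Q, D)) ||
      !identical(dim(sol$assign), c(P, D)))
    stop(structure(class = c("hosp_structural_error", "error", "condition"),
                   list(message = "solution index sets do not match instance",
                        call = sys.call())))
  v <- list()
  add <- function(kind, detail) v[[length(v) + 1L]] <<- data.frame(
    kind = kind, detail = detail, stringsAsFactors = FALSE)

  # (a) completeness: every (zip, group) assigned to exactly one valid site
  bad <- which(is.na(sol$assign) | sol$assign < 1 | sol$assign > Q,
               arr.ind = TRUE)
  for (i in seq_len(nrow(bad)))
    add("assignment_missing",
        sprintf("zip %s group %s has no site assignment",
                inst$zips$id[bad[i, 1]], inst$groups$id[bad[i, 2]]))
  if (nrow(bad)) {
    out <- do.call(rbind, v); return(out)
  }

  for (j in seq_len(D)) {
    gid <- inst$groups$id[j]
    # (b) Y <= Z
    notoff <- which(sol$offers[cbind(sol$assign[, j], j)] == 0L)
    for (p in notoff)
      add("assign_to_non_offering",
          sprintf("zip %s group %s assigned to site %s which does not offer it",
                  inst$zips$id[p], gid, inst$sites$id[sol$assign[p, j]]))
    # (d) max travel
    tt <- inst$travel[cbind(seq_len(P), sol$assign[, j])]
    over <- which(tt > inst$groups$max_travel_min[j] + 1e-9)
    for (p in over)
      add("max_travel",
          sprintf("zip %s group %s site %s: %.1f min > limit %.1f",
                  inst$zips$id[p], gid, inst$sites$id[sol$assign[p, j]],
                  tt[p], inst$groups$max_travel_min[j]))
  }
  # (c) Z <= X
  zx <- which(sol$offers > 0 & !sol$open, arr.ind = TRUE)
  for (i in seq_len(nrow(zx)))
    add("offer_at_closed_site",
        sprintf("site %s offers group %s but is not open",
                inst$sites$id[zx[i, 1]], inst$groups$id[zx[i, 2]]))

  # (e) utilization minima
  mu <- inst$config$min_utilization
  if (any(mu > 0)) {
    usage <- site_usage(inst, sol$assign)
    for (f in facility_types()) {
      if (mu[[f]] <= 0) next
      if (inst$config$utilization_mode == "conditional") {
        bad_q <- which(usage[, f] > 1e-9 & usage[, f] < mu[[f]] * (1 - tol))
      } else {
        bad_q <- which(sol$open & usage[, f] < mu[[f]] * (1 - tol))
      }
      for (q in bad_q)
        add("min_utilization",
            sprintf("site %s facility %s usage %.1f below minimum %.1f",
                    inst$sites$id[q], f, usage[q, f], mu[[f]]))
    }
  }

  # (f) co-location
  for (i in seq_len(nrow(inst$colocate))) {
    j1 <- match(inst$colocate[i, 1], inst$groups$id)
    j2 <- match(inst$colocate[i, 2], inst$groups$id)
    if (!identical(sol$offers[, j1], sol$offers[, j2]))
      add("colocation",
          sprintf("groups %s and %s offered at different site sets",
                  inst$colocate[i, 1], inst$colocate[i, 2]))
  }

  # (g) NL accounting and monetary bookkeeping
  nl <- colSums(sol$offers)
  for (j in which(nl != sol$n_locations))
    add("nl_accounting",
        sprintf("group %s: stored NL %d != sum of offers %d",
                inst$groups$id[j], sol$n_locations[j], nl[j]))
  eq <- inst$config$euros_per_qaly
  for (j in seq_len(D)) {
    gid <- as.character(inst$groups$id[j])
    qeur <- evaluate_quality_eur(inst$groups[j, ], inst$quality[[gid]],
                                 nl[j], eq)
    teur <- compute_travel_eur(inst, sol$assign, j)
    if (abs(qeur - sol$quality_eur[j]) > tol * max(1, abs(qeur)))
      add("quality_bookkeeping", sprintf("group %s quality mismatch", gid))
    if (abs(teur - sol$travel_eur[j]) > tol * max(1, abs(teur)))
      add("travel_bookkeeping", sprintf("group %s travel mismatch", gid))
  }
  obj <- sum(sol$quality_eur - sol$travel_eur)
  if (abs(obj - sol$objective_eur) > tol * max(1, abs(obj)))
    add("objective_bookkeeping", "objective != sum(quality - travel)")

  if (!length(v))
    return(data.frame(kind = character(0), detail = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, v)
}

#' @export
print.hosp_instance <- function(x, ...) {
  cat(sprintf("Hospital landscape instance: %d groups, %d zips, %d sites\n",
              nrow(x$groups), nrow(x$zips), nrow(x$sites)))
  cat(sprintf("  total demand %s patients/yr, EQ = %s euro/QALY, mode = %s\n",
              format(sum(x$groups$n_patients), big.mark = ","),
              format(x$config$euros_per_qaly, big.mark = ","),
              x$config$utilization_mode))
  invisible(x)
}

#' @export
print.hosp_solution <- function(x, ...) {
  cat(sprintf("Solution (%s, gap %.2g): %d open sites, objective %.0f euro\n",
              x$solver_status, x$gap, sum(x$open), x$objective_eur))
  cat("  locations per group: ",
      paste(sprintf("%s:%d", names(x$n_locations), x$n_locations),
            collapse = " "), "\n")
  invisible(x)
}
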