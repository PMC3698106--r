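# Synthetic-instance generation: a seeded spatial process standing in for the
# national geography (zip areas, candidate hospital sites, drive times),
# population-proportional demand spreading and registry-like per-patient
# resource usage. All randomness is controlled by explicit seeds and the
# caller's RNG state is restored on exit.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Default outpatient visits per patient by care class
#'
#' Total visits per patient including follow-up: chronic care requires
#' frequent contact (8/yr), elective episodes a handful (3), acute episodes
#' few (2); mixed elective/chronic groups sit in between (5).
#' @return named numeric vector.
#' @export
default_visits_per_patient <- function() {
  c(acute = 2, chronic = 8, elective = 3, mixed = 5)
}

#' Load the packaged 30-group diagnosis table
#'
#' Reads the packaged diagnosis-group characteristics (name, care class,
#' annual admissions, volume-outcome category, maximum travel time, annual
#' cost). The table carries 31 printed rows; the "Signs, symptoms and
#' ill-defined conditions" row is excluded from the model set for lack of
#' information and is only returned when `include_excluded = TRUE`.
#'
#' @param include_excluded keep the excluded row (default `FALSE`, yielding
#'   the 30 modeled groups).
#' @param visits_per_patient named vector mapping care class to visits per
#'   patient, used to fill the `n_visits` column.
#' @return data frame of diagnosis groups.
#' @export
load_diagnosis_groups <- function(include_excluded = FALSE,
                                  visits_per_patient = default_visits_per_patient()) {
  path <- system.file("extdata", "diagnosis_groups.csv", package = "hospalloc")
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!include_excluded) g <- g[g$in_model, ]
  g$n_visits <- ifelse(is.na(g$care_class), NA_real_,
                       unname(visits_per_patient[g$care_class]))
  rownames(g) <- NULL
  g
}

#' Generator configuration
#'
#' @param n_zips number of zip (demand) areas.
#' @param n_sites number of candidate hospital sites.
#' @param n_sites_from_population_centers how many candidate sites are placed
#'   at the highest-population zips, standing in for existing hospitals.
#' @param region_extent_km side of the square study region. The default
#'   (`NULL`) scales the full-size 200 km extent by `sqrt(n_sites / 150)`,
#'   holding the candidate-site density of the full configuration constant,
#'   so scaled-down instances keep the same reachability character.
#' @param population_total total population the zip populations are rescaled
#'   to sum to.
#' @param population_lognormal_mu,population_lognormal_sigma log-normal
#'   parameters of raw zip populations before rescaling.
#' @param road_factor network detour multiplier on Euclidean distance.
#' @param speed_kmh average driving speed.
#' @param travel_noise_sd_min standard deviation (minutes) of the zero-
#'   truncated Gaussian perturbation applied to drive times.
#' @param coverage_time_min,coverage_slack_min the candidate-site selection
#'   guarantees every zip a candidate within
#'   `coverage_time_min - coverage_slack_min` deterministic minutes, so the
#'   acute maximum-travel rule stays satisfiable by construction.
#' @param seed integer seed.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_zips = 794L, n_sites = 150L,
                             n_sites_from_population_centers = 88L,
                             region_extent_km = NULL,
                             population_total = 16.6e6,
                             population_lognormal_mu = 9,
                             population_lognormal_sigma = 1,
                             road_factor = 1.3, speed_kmh = 60,
                             travel_noise_sd_min = 1.5,
                             coverage_time_min = 45,
                             coverage_slack_min = 6,
                             seed = 1L) {
  if (is.null(region_extent_km))
    region_extent_km <- 200 * sqrt(n_sites / 150)
  stopifnot(n_zips >= 1, n_sites >= 1, n_sites <= n_zips,
            n_sites_from_population_centers <= n_sites,
            region_extent_km > 0, population_total > 0,
            road_factor >= 1, speed_kmh > 0, travel_noise_sd_min >= 0)
  structure(list(n_zips = as.integer(n_zips), n_sites = as.integer(n_sites),
                 n_sites_from_population_centers =
                   as.integer(n_sites_from_population_centers),
                 region_extent_km = region_extent_km,
                 population_total = population_total,
                 population_lognormal_mu = population_lognormal_mu,
                 population_lognormal_sigma = population_lognormal_sigma,
                 road_factor = road_factor, speed_kmh = speed_kmh,
                 travel_noise_sd_min = travel_noise_sd_min,
                 coverage_time_min = coverage_time_min,
                 coverage_slack_min = coverage_slack_min,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate zip areas
#'
#' Coordinates come from a clustered spatial process — a few urban cores with
#' Gaussian spread plus a uniform rural background — clipped to the square
#' region; populations are i.i.d. log-normal, rescaled to the configured
#' national total. Deterministic under the config seed.
#'
#' @param cfg a [generator_config()].
#' @return data frame with columns `id`, `x_km`, `y_km`, `population`.
#' @export
generate_zips <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"), cfg$n_zips >= 1)
  with_seed(cfg$seed, {
    n <- cfg$n_zips; ext <- cfg$region_extent_km
    n_cores <- max(1L, ceiling(n / 50))
    core_xy <- matrix(stats::runif(2 * n_cores, 0.15 * ext, 0.85 * ext),
                      ncol = 2)
    clustered <- stats::rbinom(n, 1, 0.6) == 1
    pick <- sample.int(n_cores, n, replace = TRUE)
    x <- ifelse(clustered,
                core_xy[pick, 1] + stats::rnorm(n, 0, ext / 15),
                stats::runif(n, 0, ext))
    y <- ifelse(clustered,
                core_xy[pick, 2] + stats::rnorm(n, 0, ext / 15),
                stats::runif(n, 0, ext))
    x <- pmin(pmax(x, 0), ext); y <- pmin(pmax(y, 0), ext)
    pop <- stats::rlnorm(n, cfg$population_lognormal_mu,
                         cfg$population_lognormal_sigma)
    pop <- pop * cfg$population_total / sum(pop)
    data.frame(id = sprintf("Z%04d", seq_len(n)),
               x_km = x, y_km = y, population = pop,
               stringsAsFactors = FALSE)
  })
}

# population-weighted total distance from every zip to its nearest site
weighted_nearest_cost <- function(zx, zy, pop, sx, sy) {
  d2min <- rep(Inf, length(zx))
  for (s in seq_along(sx))
    d2min <- pmin(d2min, (zx - sx[s])^2 + (zy - sy[s])^2)
  sum(pop * sqrt(d2min))
}

#' Select candidate hospital sites
#'
#' The first `n_sites_from_population_centers` candidates are placed at the
#' highest-population zips (standing in for existing hospital locations). The
#' remainder are placed at zip locations by a greedy population-weighted
#' p-median heuristic followed by single-swap local search, so that the total
#' population-weighted driving distance is as small as possible. A final
#' repair pass relocates the least-loaded non-anchor sites until every zip
#' has a candidate within the configured coverage radius. Ties are broken by
#' zip order; the procedure is deterministic given the zips.
#'
#' @param zips output of [generate_zips()].
#' @param cfg a [generator_config()].
#' @return data frame with columns `id`, `x_km`, `y_km`,
#'   `from_existing_hospital`.
#' @export
select_candidate_sites <- function(zips, cfg) {
  stopifnot(cfg$n_sites <= nrow(zips))
  zx <- zips$x_km; zy <- zips$y_km; pop <- zips$population
  n <- nrow(zips)
  if (max(stats::dist(cbind(zx, zy))) < 1e-9 && n > 1)
    warning("all zips coincident; candidate sites will be deduplicated")

  radius_km <- (cfg$coverage_time_min - cfg$coverage_slack_min) / 60 *
    cfg$speed_kmh / cfg$road_factor
  d2_to <- function(idx) lapply(idx, function(s)
    (zx - zx[s])^2 + (zy - zy[s])^2)
  covered_by <- function(idx) {
    if (!length(idx)) return(rep(FALSE, n))
    sqrt(Reduce(pmin, d2_to(idx))) <= radius_km
  }

  # 1) anchors at the highest-population zips (existing hospitals)
  ord <- order(-pop, seq_len(n))
  na <- cfg$n_sites_from_population_centers
  anchor_idx <- ord[seq_len(na)]
  chosen <- anchor_idx

  # 2) greedy disk cover so the acute travel rule is satisfiable by
  #    construction; reachability outranks the existing-hospital prior, so
  #    low-population anchors are released if the budget runs out
  repeat {
    uncov <- which(!covered_by(chosen))
    if (!length(uncov)) break
    if (length(chosen) >= cfg$n_sites) {
      if (na > 0L) {            # release the least-populous anchor
        chosen <- chosen[-na]
        na <- na - 1L
        anchor_idx <- anchor_idx[seq_len(na)]
        next
      }
      # last resort: re-purpose a slot that covers nothing uniquely
      cov <- sqrt(outer(zx, zx[chosen], "-")^2 +
                  outer(zy, zy[chosen], "-")^2) <= radius_km
      critical <- colSums(cov & (rowSums(cov) == 1)) > 0
      red <- which(!critical)
      if (length(red)) { chosen[max(red)] <- uncov[1]; next }
      warning(length(uncov), " zip(s) remain beyond the coverage radius; ",
              "increase n_sites or the coverage time")
      break
    }
    gain <- vapply(seq_len(n), function(c_)
      sum(sqrt((zx[uncov] - zx[c_])^2 + (zy[uncov] - zy[c_])^2) <= radius_km),
      integer(1))
    gain[chosen] <- -1L
    target <- which.max(gain)
    chosen <- c(chosen, target)
  }

  # 3) remaining budget: greedy population-weighted p-median additions
  d2min <- if (length(chosen)) Reduce(pmin, d2_to(chosen)) else rep(Inf, n)
  while (length(chosen) < cfg$n_sites) {
    cand <- setdiff(seq_len(n), chosen)
    best <- cand[1]; best_cost <- Inf
    for (cidx in cand) {
      cost <- sum(pop * sqrt(pmin(d2min, (zx - zx[cidx])^2 + (zy - zy[cidx])^2)))
      if (cost < best_cost - 1e-12) { best_cost <- cost; best <- cidx }
    }
    chosen <- c(chosen, best)
    d2min <- pmin(d2min, (zx - zx[best])^2 + (zy - zy[best])^2)
  }

  # 4) single-swap local search on the non-anchor sites; swaps must keep the
  #    coverage guarantee intact
  movable <- setdiff(seq_along(chosen), seq_along(anchor_idx))
  full_cover <- all(covered_by(chosen))
  cur_cost <- weighted_nearest_cost(zx, zy, pop, zx[chosen], zy[chosen])
  improved <- TRUE; passes <- 0L
  while (improved && passes < 20L) {
    improved <- FALSE; passes <- passes + 1L
    for (slot in movable) {
      for (cidx in setdiff(seq_len(n), chosen)) {
        trial <- chosen; trial[slot] <- cidx
        cost <- weighted_nearest_cost(zx, zy, pop, zx[trial], zy[trial])
        if (cost < cur_cost - 1e-9 &&
            (!full_cover || all(covered_by(trial)))) {
          chosen <- trial; cur_cost <- cost; improved <- TRUE
        }
      }
    }
  }

  xy <- cbind(zx[chosen], zy[chosen])
  dup <- duplicated(round(xy, 9))
  if (any(dup)) {
    warning(sum(dup), " duplicate candidate location(s) removed")
    chosen <- chosen[!dup]
  }
  data.frame(id = sprintf("S%03d", seq_along(chosen)),
             x_km = zx[chosen], y_km = zy[chosen],
             from_existing_hospital = seq_along(chosen) <= na,
             stringsAsFactors = FALSE)
}

#' Build a synthetic drive-time matrix
#'
#' Minutes are Euclidean kilometers scaled by a road detour factor and the
#' average speed, plus a zero-truncated Gaussian perturbation emulating
#' network irregularity. Zip/site pairs at the same point keep an exact zero.
#'
#' @param zips,sites coordinate tables.
#' @param cfg a [generator_config()]; the noise draw uses `cfg$seed + 1`.
#' @return numeric matrix zips x sites of minutes.
#' @export
build_travel_matrix <- function(zips, sites, cfg) {
  dx <- outer(zips$x_km, sites$x_km, "-")
  dy <- outer(zips$y_km, sites$y_km, "-")
  km <- sqrt(dx^2 + dy^2)
  minutes <- km * cfg$road_factor / cfg$speed_kmh * 60
  if (cfg$travel_noise_sd_min > 0) {
    noise <- with_seed(cfg$seed + 1L,
                       matrix(stats::rnorm(length(minutes), 0,
                                           cfg$travel_noise_sd_min),
                              nrow(minutes)))
    minutes <- pmax(minutes + noise, 0)
    minutes[km < 1e-12] <- 0
  }
  dimnames(minutes) <- list(zips$id, sites$id)
  minutes
}

#' Spread national demand over zip areas
#'
#' Each group's admissions are distributed proportionally to zip population
#' (the percentage-wise spread is identical for all groups) and rounded to
#' integers by the largest-remainder method, so each column sums exactly to
#' the group's admissions.
#'
#' @param groups diagnosis-group table with `n_patients`.
#' @param zips zip table with `population`.
#' @return integer matrix zips x groups.
#' @export
spread_demand <- function(groups, zips) {
  stopifnot(all(zips$population > 0))
  share <- zips$population / sum(zips$population)
  out <- vapply(groups$n_patients, function(np) {
    exact <- np * share
    base <- floor(exact)
    rem <- as.integer(round(np - sum(base)))
    if (rem > 0) {
      extra <- order(-(exact - base), seq_along(base))[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    as.integer(base)
  }, integer(nrow(zips)))
  out <- matrix(out, nrow(zips), nrow(groups),
                dimnames = list(zips$id, groups$id))
  out
}

#' Generate per-patient facility usage
#'
#' Samples per-patient operating-room hours, ward bed-days and ICU bed-days
#' from uniform ranges conditioned on care class: elective and acute groups
#' use OR time, chronic groups none; acute groups have the highest ICU
#' fractions, chronic groups none; every class accrues ward bed-days.
#' Deterministic under the seed.
#'
#' @param groups diagnosis-group table with `care_class`.
#' @param seed integer seed.
#' @return numeric matrix groups x `c("OR","WARD","ICU")`.
#' @export
generate_usage <- function(groups, seed = 1L) {
  ranges <- list(
    OR   = list(acute = c(0.5, 2), chronic = c(0, 0),
                elective = c(1, 3), mixed = c(0.5, 2)),
    WARD = list(acute = c(3, 8), chronic = c(2, 6),
                elective = c(1, 4), mixed = c(2, 5)),
    ICU  = list(acute = c(0.2, 1), chronic = c(0, 0),
                elective = c(0.05, 0.3), mixed = c(0.02, 0.1)))
  with_seed(seed, {
    out <- matrix(0, nrow(groups), 3,
                  dimnames = list(groups$id, facility_types()))
    for (f in facility_types())
      for (j in seq_len(nrow(groups))) {
        r <- ranges[[f]][[groups$care_class[j]]]
        out[j, f] <- stats::runif(1, r[1], r[2])
      }
    out
  })
}

#' Generate a complete synthetic instance
#'
#' Runs the full pipeline — zips, candidate sites, drive-time matrix, demand
#' spread, resource usage, quality-function calibration — and assembles a
#' validated [hosp_instance()]. By default the packaged 30-group diagnosis
#' table provides the demand side.
#'
#' @param cfg a [generator_config()].
#' @param groups diagnosis-group table (default the packaged fixture).
#' @param calib a [calibration_spec()].
#' @param config a [model_config()]; its seed defaults to the generator seed.
#' @param shape quality-function shape passed to [build_quality_function()].
#' @return a `hosp_instance`.
#' @export
generate_instance <- function(cfg = generator_config(),
                              groups = load_diagnosis_groups(),
                              calib = calibration_spec(),
                              config = model_config(seed = cfg$seed),
                              shape = "linear") {
  zips <- generate_zips(cfg)
  sites <- select_candidate_sites(zips, cfg)
  travel <- build_travel_matrix(zips, sites, cfg)
  demand <- spread_demand(groups, zips)
  usage <- generate_usage(groups, seed = cfg$seed + 2L)
  quality <- stats::setNames(lapply(seq_len(nrow(groups)), function(j)
    build_quality_function(groups[j, ], calib, max_sites = nrow(sites),
                           shape = shape)),
    as.character(groups$id))
  hosp_instance(groups, zips, sites, travel, demand, usage, quality,
                config = config)
}

# single linear segment covering [1, max_sites]; zero gain at `baseline`
single_segment_qf <- function(slope, max_sites, baseline = max_sites,
                              group_id = NA_integer_) {
  structure(data.frame(nl_lo = 1L, nl_hi = as.integer(max_sites),
                       slope = slope, intercept = -slope * baseline),
            class = c("quality_function", "data.frame"),
            group_id = group_id, vo_category = if (slope == 0) "none" else "high",
            baseline_nl = as.integer(baseline))
}

#' Random micro-instance for cross-validation against the exact oracle
#'
#' Builds a tiny but fully featured instance: clustered zips, p-median
#' candidate sites, noisy drive times, synthetic diagnosis groups with
#' admissions in the tens-to-hundreds, single-segment quality functions with
#' random negative (or, with probability 0.3, zero) slopes anchored at the
#' all-sites-open landscape, and per-zip maximum travel limits generous
#' enough that every zip can be served. Optionally activates utilization
#' minima scaled to be attainable yet occasionally binding.
#'
#' @param seed integer seed.
#' @param n_zips,n_sites,n_groups instance dimensions.
#' @param utilization `"none"`, `"conditional"` or `"literal"`.
#' @param colocate_prob probability of tying two groups together when
#'   `n_groups >= 2`.
#' @return a `hosp_instance`.
#' @export
random_micro_instance <- function(seed, n_zips = 5L, n_sites = 3L,
                                  n_groups = 2L,
                                  utilization = c("none", "conditional",
                                                  "literal"),
                                  colocate_prob = 0.25) {
  utilization <- match.arg(utilization)
  cfg <- generator_config(n_zips = n_zips, n_sites = n_sites,
                          n_sites_from_population_centers = 0L,
                          region_extent_km = 60,
                          population_total = 1e5,
                          travel_noise_sd_min = 1,
                          coverage_slack_min = 0,
                          seed = seed)
  zips <- generate_zips(cfg)
  sites <- select_candidate_sites(zips, cfg)
  travel <- build_travel_matrix(zips, sites, cfg)
  with_seed(seed + 10L, {
    np <- sample(20:200, n_groups, replace = TRUE)
    groups <- data.frame(
      id = seq_len(n_groups),
      name = paste0("G", seq_len(n_groups)),
      care_class = sample(c("acute", "chronic", "elective", "mixed"),
                          n_groups, replace = TRUE),
      vo_category = "high",
      n_patients = np,
      n_visits = sample(2:8, n_groups, replace = TRUE),
      max_travel_min = NA_real_,
      stringsAsFactors = FALSE)
    slopes <- ifelse(stats::runif(n_groups) < 0.3, 0,
                     -stats::runif(n_groups, 0.002, 0.02))
    groups$vo_category <- ifelse(slopes == 0, "none", "high")
    # every zip keeps at least one reachable site, but far sites are cut off;
    # with utilization minima active the limits instead cover the 1-center
    # radius, so demand can always consolidate into one efficient site
    if (utilization == "none") {
      need <- max(apply(travel, 1, min))
      tf <- stats::runif(n_groups, 1.15, 1.8)
    } else {
      need <- min(apply(travel, 2, max))
      tf <- stats::runif(n_groups, 1.05, 1.5)
    }
    groups$max_travel_min <- need * tf + 1
    demand <- spread_demand(groups, zips)
    usage <- matrix(stats::runif(n_groups * 3, 0, 2), n_groups, 3,
                    dimnames = list(groups$id, facility_types()))
    mu <- c(OR = 0, WARD = 0, ICU = 0)
    if (utilization != "none") {
      tot <- as.numeric(groups$n_patients %*% usage)
      mu <- stats::setNames(tot / n_sites * stats::runif(3, 0.2, 0.6),
                            facility_types())
    }
    colocate <- NULL
    if (n_groups >= 2 && stats::runif(1) < colocate_prob)
      colocate <- matrix(c(1L, 2L), ncol = 2)
    config <- model_config(
      euros_per_qaly = 50000, euros_per_travel_hour = 172,
      utilization_mode = if (utilization == "literal") "literal" else "conditional",
      min_utilization = mu, mip_gap = 1e-9, seed = seed)
    quality <- stats::setNames(lapply(seq_len(n_groups), function(j)
      single_segment_qf(slopes[j], n_sites, group_id = j)),
      as.character(groups$id))
    hosp_instance(groups, zips, sites, travel, demand, usage, quality,
                  colocate = colocate, config = config)
  })
}
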