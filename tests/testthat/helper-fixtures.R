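# In-code fixtures: a fully hand-specified single-cell instance and a small
# 3-zip / 2-site / 2-group instance with known travel arithmetic.

tiny_instance <- function(tt = 10, maxt = 45, np = 10L, slope = 0,
                          nv = 2, et = 60, eq = 50000,
                          mu = c(OR = 0, WARD = 0, ICU = 0),
                          mode = "conditional") {
  groups <- data.frame(id = 1L, name = "G1", care_class = "elective",
                       vo_category = if (slope == 0) "none" else "high",
                       n_patients = np, n_visits = nv, max_travel_min = maxt)
  zips <- data.frame(id = "Z1", x_km = 0, y_km = 0, population = 100)
  sites <- data.frame(id = "S1", x_km = 0, y_km = 0,
                      from_existing_hospital = TRUE)
  travel <- matrix(tt, 1, 1)
  demand <- matrix(np, 1, 1)
  usage <- matrix(1, 1, 3, dimnames = list("1", c("OR", "WARD", "ICU")))
  quality <- list("1" = hospalloc:::single_segment_qf(slope, 1L, group_id = 1L))
  hosp_instance(groups, zips, sites, travel, demand, usage, quality,
                colocate = matrix(integer(0), ncol = 2),
                config = model_config(euros_per_qaly = eq,
                                      euros_per_travel_hour = et,
                                      utilization_mode = mode,
                                      min_utilization = mu,
                                      mip_gap = 1e-9))
}

# 3 zips on a line at x = 0, 10, 40; sites at x = 0 and 40; travel = |dx| min
hand_instance <- function(slopes = c(-0.01, 0), maxt = c(60, 60),
                          np = c(60L, 90L), nv = c(2, 3),
                          mu = c(OR = 0, WARD = 0, ICU = 0),
                          mode = "conditional", colocate = NULL,
                          eq = 50000, et = 60) {
  groups <- data.frame(id = 1:2, name = c("G1", "G2"),
                       care_class = c("elective", "chronic"),
                       vo_category = ifelse(slopes == 0, "none", "high"),
                       n_patients = np, n_visits = nv, max_travel_min = maxt)
  zips <- data.frame(id = c("Z1", "Z2", "Z3"), x_km = c(0, 10, 40),
                     y_km = 0, population = c(100, 200, 100))
  sites <- data.frame(id = c("S1", "S2"), x_km = c(0, 40), y_km = 0,
                      from_existing_hospital = FALSE)
  travel <- abs(outer(zips$x_km, sites$x_km, "-"))
  pops <- zips$population / sum(zips$population)
  demand <- spread_demand(groups, zips)
  usage <- matrix(c(1, 0.5, 2, 1.5, 0.2, 0.1), 2, 3,
                  dimnames = list(1:2, c("OR", "WARD", "ICU")))
  quality <- list("1" = hospalloc:::single_segment_qf(slopes[1], 2L, group_id = 1L),
                  "2" = hospalloc:::single_segment_qf(slopes[2], 2L, group_id = 2L))
  hosp_instance(groups, zips, sites, travel, demand, usage, quality,
                colocate = if (is.null(colocate))
                  matrix(integer(0), ncol = 2) else colocate,
                config = model_config(euros_per_qaly = eq,
                                      euros_per_travel_hour = et,
                                      utilization_mode = mode,
                                      min_utilization = mu,
                                      mip_gap = 1e-9))
}

micro_opts <- function() solve_options(time_limit_s = 60)

rel_diff <- function(a, b) abs(a - b) / max(1, abs(a), abs(b))

# helper: a 1-zip / 3-site instance whose single group carries an arbitrary
# two-segment quality function, for exercising the segment refinement loop
two_segment_instance <- function(s1, s2, baseline = 3L) {
  groups <- data.frame(id = 1L, name = "G1", care_class = "elective",
                       vo_category = "high", n_patients = 100L,
                       n_visits = 2, max_travel_min = 1e6)
  zips <- data.frame(id = "Z1", x_km = 0, y_km = 0, population = 100)
  sites <- data.frame(id = c("S1", "S2", "S3"), x_km = c(0, 5, 10), y_km = 0,
                      from_existing_hospital = FALSE)
  travel <- matrix(c(5, 10, 20), 1, 3)
  demand <- matrix(100L, 1, 1)
  usage <- matrix(0.5, 1, 3, dimnames = list("1", c("OR", "WARD", "ICU")))
  b2 <- -s2 * baseline                      # zero gain at the baseline
  b1 <- (s2 - s1) * 1 + b2                  # continuity at the knot NL = 1
  qf <- structure(data.frame(nl_lo = c(1L, 2L), nl_hi = c(1L, 3L),
                             slope = c(s1, s2), intercept = c(b1, b2)),
                  class = c("quality_function", "data.frame"),
                  group_id = 1L, vo_category = "high",
                  baseline_nl = baseline)
  hosp_instance(groups, zips, sites, travel, demand, usage,
                quality = list("1" = qf),
                colocate = matrix(integer(0), ncol = 2),
                config = model_config(mip_gap = 1e-9,
                                      min_utilization = c(OR = 0, WARD = 0,
                                                          ICU = 0)))
}

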