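test_that("a single-cell instance is solved by the forced configuration", {
  inst <- tiny_instance(tt = 10, maxt = 45, np = 10L)
  sol <- solve_instance(inst, micro_opts())
  expect_equal(sol$solver_status, "optimal")
  expect_true(sol$open[["S1"]])
  expect_equal(unname(sol$n_locations), 1L)
  expect_equal(unname(sol$assign[1, 1]), 1L)
  # travel = 2 * 60 euro/h * 2 visits * 10 patients * (10/60) h = 400
  expect_equal(unname(sol$travel_eur[1]), 400)
  expect_equal(sol$objective_eur, -400)
  expect_equal(nrow(validate_solution(inst, sol)), 0)
})

test_that("travel cost formula matches hand arithmetic and scales in visits", {
  inst <- tiny_instance(tt = 30, nv = 2, et = 60, np = 10L)
  assign <- matrix(1L, 1, 1)
  expect_equal(compute_travel_eur(inst, assign, 1), 1200)  # 2*60*2*10*0.5
  inst0 <- tiny_instance(tt = 0)
  expect_equal(compute_travel_eur(inst0, assign, 1), 0)
  inst2 <- tiny_instance(tt = 30, nv = 4, et = 60, np = 10L)
  expect_equal(compute_travel_eur(inst2, assign, 1), 2400)
})

test_that("with zero slopes and no minima every zip gets its nearest site", {
  inst <- hand_instance(slopes = c(0, 0), maxt = c(1e6, 1e6))
  sol <- solve_instance(inst, micro_opts())
  nearest <- apply(inst$travel, 1, which.min)
  expect_equal(unname(sol$assign[, 1]), unname(nearest))
  expect_equal(unname(sol$assign[, 2]), unname(nearest))
  bound <- sum(vapply(1:2, function(j) {
    tt <- apply(inst$travel, 1, min)
    inst$config$round_trip_factor * inst$config$euros_per_travel_hour *
      inst$groups$n_visits[j] * sum(inst$demand[, j] * tt) / 60
  }, numeric(1)))
  expect_equal(sol$objective_eur, -bound)
})

test_that("solutions returned by the solver always pass the validator", {
  for (s in c(12, 31)) {
    inst <- random_micro_instance(seed = s, n_zips = 6, n_sites = 4,
                                  n_groups = 3)
    sol <- solve_instance(inst, micro_opts())
    expect_equal(nrow(validate_solution(inst, sol)), 0)
  }
})

test_that("tightening a travel limit never improves the optimum", {
  inst <- random_micro_instance(seed = 17, n_zips = 6, n_sites = 4,
                                n_groups = 2)
  base <- solve_instance(inst, micro_opts())
  tight <- inst
  # keep coverage: shrink toward (but not beyond) each zip's nearest site
  floor_t <- max(apply(inst$travel, 1, min))
  tight$groups$max_travel_min <- pmax(floor_t + 0.5,
                                      0.7 * inst$groups$max_travel_min)
  sol_t <- solve_instance(tight, micro_opts())
  expect_lte(sol_t$objective_eur, base$objective_eur + 1e-6)
})

test_that("dropping utilization minima never hurts the optimum", {
  for (mode in c("conditional", "literal")) {
    inst <- random_micro_instance(seed = 23, n_zips = 4, n_sites = 3,
                                  n_groups = 2, utilization = mode)
    with_min <- solve_instance(inst, micro_opts())
    relaxed <- inst
    relaxed$config$min_utilization[] <- 0
    without <- solve_instance(relaxed, micro_opts())
    # relaxing can never lose feasibility or objective
    expect_false(without$solver_status == "infeasible" &&
                   with_min$solver_status != "infeasible")
    if (with_min$solver_status != "infeasible")
      expect_gte(without$objective_eur, with_min$objective_eur - 1e-6)
  }
})

test_that("infeasible utilization demands are reported, not crashed", {
  inst <- tiny_instance(mu = c(OR = 1e9, WARD = 0, ICU = 0), mode = "literal")
  sol <- solve_instance(inst, micro_opts())
  expect_equal(sol$solver_status, "infeasible")
  expect_true(is.na(sol$objective_eur))
})
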