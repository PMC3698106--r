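test_that("nearest-feasible assignment follows distance with id tie-breaks", {
  inst <- hand_instance(maxt = c(1e6, 1e6))
  offers <- matrix(1L, 2, 2)
  a <- nearest_feasible_assignment(inst, offers)
  expect_equal(unname(a[, 1]), c(1L, 1L, 2L))  # zip2 at 10 vs 30 min
  # single offering site takes everything
  one <- matrix(c(0L, 1L), 2, 2)
  a1 <- nearest_feasible_assignment(inst, one)
  expect_true(all(a1 == 2L))
  # equidistant pair: lower site index wins
  inst_tie <- hand_instance()
  inst_tie$travel[2, ] <- c(15, 15)
  a2 <- nearest_feasible_assignment(inst_tie, offers)
  expect_equal(unname(a2[2, 1]), 1L)
  # uncovered pair raises the structured condition
  blocked <- hand_instance(maxt = c(5, 1e6))
  expect_error(nearest_feasible_assignment(blocked, offers),
               class = "hosp_uncovered_demand")
})

test_that("a forced configuration is returned as the optimum", {
  inst <- tiny_instance(tt = 10)
  orc <- enumerate_optimum(inst)
  expect_equal(orc$solver_status, "optimal")
  expect_true(orc$open[["S1"]])
  expect_equal(unname(orc$n_locations), 1L)
})

test_that("the oracle dominates any hand-built feasible solution", {
  inst <- hand_instance(slopes = c(-0.02, 0), maxt = c(1e6, 1e6))
  orc <- enumerate_optimum(inst)
  # candidate: everything open and nearest assignment
  offers <- matrix(1L, 2, 2)
  cand <- hosp_solution(inst, c(TRUE, TRUE), offers,
                        nearest_feasible_assignment(inst, offers))
  expect_equal(nrow(validate_solution(inst, cand)), 0)
  expect_gte(orc$objective_eur, cand$objective_eur - 1e-9)
  # candidate: only site 1 open
  offers1 <- matrix(c(1L, 0L), 2, 2)
  cand1 <- hosp_solution(inst, c(TRUE, FALSE), offers1,
                         nearest_feasible_assignment(inst, offers1))
  expect_gte(orc$objective_eur, cand1$objective_eur - 1e-9)
})

test_that("the oracle refuses oversized state spaces with an estimate", {
  inst <- random_micro_instance(seed = 2, n_zips = 8, n_sites = 5,
                                n_groups = 3)
  expect_error(enumerate_optimum(inst, oracle_limits(max_sites = 4)),
               "exceeds oracle limits")
  inst_u <- random_micro_instance(seed = 2, n_zips = 5, n_sites = 4,
                                  n_groups = 3, utilization = "conditional")
  expect_error(enumerate_optimum(inst_u, oracle_limits(max_states = 10)),
               "state space too large")
})

test_that("co-located groups share one offering set in the oracle optimum", {
  inst <- hand_instance(slopes = c(-0.05, 0),
                        colocate = matrix(c(1L, 2L), ncol = 2))
  orc <- enumerate_optimum(inst)
  expect_identical(orc$offers[, 1], orc$offers[, 2])
  expect_equal(nrow(validate_solution(inst, orc)), 0)
})
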