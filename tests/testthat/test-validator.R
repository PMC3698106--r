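test_that("a minimal feasible configuration yields an empty report", {
  inst <- tiny_instance(tt = 10, maxt = 45)
  sol <- hosp_solution(inst, open = TRUE, offers = matrix(1L, 1, 1),
                       assign = matrix(1L, 1, 1))
  rep <- validate_solution(inst, sol)
  expect_equal(nrow(rep), 0)
  # pure function: identical inputs, identical reports
  expect_identical(rep, validate_solution(inst, sol))
})

test_that("an over-limit drive produces exactly one max_travel violation", {
  inst <- tiny_instance(tt = 50, maxt = 45)
  sol <- hosp_solution(inst, open = TRUE, offers = matrix(1L, 1, 1),
                       assign = matrix(1L, 1, 1))
  rep <- validate_solution(inst, sol)
  expect_equal(nrow(rep), 1)
  expect_equal(rep$kind, "max_travel")
})

test_that("linking, co-location and utilization violations are all caught", {
  inst <- hand_instance(slopes = c(-0.01, 0))
  # assignment to a site that does not offer the group
  sol <- hosp_solution(inst, open = c(TRUE, FALSE),
                       offers = matrix(c(1L, 0L, 1L, 1L), 2, 2),
                       assign = matrix(c(1L, 1L, 2L, 1L, 1L, 1L), 3, 2))
  rep <- validate_solution(inst, sol)
  expect_true("assign_to_non_offering" %in% rep$kind)
  expect_true("offer_at_closed_site" %in% rep$kind)

  # co-location: different site sets for a tied pair
  inst2 <- hand_instance(colocate = matrix(c(1L, 2L), ncol = 2))
  sol2 <- hosp_solution(inst2, open = c(TRUE, TRUE),
                        offers = matrix(c(1L, 0L, 1L, 1L), 2, 2),
                        assign = matrix(1L, 3, 2))
  expect_true("colocation" %in% validate_solution(inst2, sol2)$kind)

  # literal utilization: open site below an OR minimum
  inst3 <- tiny_instance(mu = c(OR = 1e6, WARD = 0, ICU = 0),
                         mode = "literal")
  sol3 <- hosp_solution(inst3, open = TRUE, offers = matrix(1L, 1, 1),
                        assign = matrix(1L, 1, 1))
  expect_true("min_utilization" %in% validate_solution(inst3, sol3)$kind)
})

test_that("index-set mismatch raises a structural error, not a violation", {
  inst <- tiny_instance()
  inst2 <- hand_instance()
  sol2 <- hosp_solution(inst2, open = c(TRUE, TRUE),
                        offers = matrix(1L, 2, 2), assign = matrix(1L, 3, 2))
  expect_error(validate_solution(inst, sol2),
               class = "hosp_structural_error")
})

test_that("oracle solutions always pass the independent validator", {
  for (s in c(2, 7)) {
    inst <- random_micro_instance(seed = s, n_zips = 4, n_sites = 3,
                                  n_groups = 2)
    orc <- enumerate_optimum(inst)
    expect_equal(nrow(validate_solution(inst, orc)), 0)
  }
})
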