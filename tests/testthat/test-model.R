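test_that("variable counts follow the instance dimensions", {
  inst <- tiny_instance()
  m <- build_model(inst)
  expect_equal(length(m$x_idx), 1)
  expect_equal(length(m$z_idx), 1)
  expect_equal(nrow(m$ymap), 1)
  expect_null(m$w_idx)  # no utilization minima, no facility binaries
  expect_equal(m$n_var, 3)
})

test_that("max-travel enforcement restricts the assignment variable domain", {
  inst <- hand_instance(maxt = c(45, 60))
  m <- build_model(inst)
  # group 1 (maxt 45): zip1-site2 and zip3-site1 are 40 km = 40 min, allowed;
  # but a 50-min pair must vanish. Tighten to see the domain shrink:
  inst2 <- hand_instance(maxt = c(30, 60))
  m2 <- build_model(inst2)
  expect_lt(nrow(m2$ymap[m2$ymap$j == 1, ]), nrow(m$ymap[m$ymap$j == 1, ]))
  expect_true(all(inst2$travel[as.matrix(m2$ymap[m2$ymap$j == 1, c("p", "q")])]
                  <= 30))
})

test_that("uncovered zip-group pairs are diagnosed before any solve", {
  inst <- tiny_instance(tt = 50, maxt = 45)
  err <- tryCatch(build_model(inst), condition = function(e) e)
  expect_s3_class(err, "hosp_uncovered_demand")
  expect_equal(nrow(err$uncovered), 1)
  expect_error(solve_instance(inst), class = "hosp_uncovered_demand")
})

test_that("tight and big-M linking reach the same optimum", {
  for (s in c(3, 8)) {
    inst <- random_micro_instance(seed = s, n_zips = 5, n_sites = 3,
                                  n_groups = 2)
    a <- solve_instance(inst, solve_options(linking_mode = "tight"))
    b <- solve_instance(inst, solve_options(linking_mode = "big_m"))
    expect_lt(rel_diff(a$objective_eur, b$objective_eur), 1e-6)
  }
})
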