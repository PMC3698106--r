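test_that("zero-slope instances are insensitive to the QALY price", {
  inst <- hand_instance(slopes = c(0, 0), maxt = c(1e6, 1e6))
  sw <- eq_sweep(inst, c(20000, 50000, 100000), micro_opts())
  expect_true(all(sw$n_locations[, 1] == sw$n_locations[, 2]))
  expect_true(all(sw$n_locations[, 2] == sw$n_locations[, 3]))
  expect_equal(sw$objectives[1], sw$objectives[3])
})

test_that("a length-one sweep reduces to a single refined solve", {
  inst <- random_micro_instance(seed = 41, n_zips = 5, n_sites = 3,
                                n_groups = 2)
  sw <- eq_sweep(inst, 50000, micro_opts())
  sol <- solve_with_refinement(inst, micro_opts())
  expect_equal(unname(sw$objectives[1]), sol$objective_eur)
  expect_equal(unname(sw$n_locations[, 1]), unname(sol$n_locations))
})

test_that("raising the QALY price concentrates care monotonically", {
  inst <- random_micro_instance(seed = 53, n_zips = 6, n_sites = 4,
                                n_groups = 1)
  # force a clearly negative slope
  inst$quality[["1"]]$slope <- -0.01
  inst$quality[["1"]]$intercept <- 0.01 * 4
  inst$groups$vo_category <- "high"
  sw <- eq_sweep(inst, c(20000, 50000, 100000), micro_opts())
  expect_true(all(diff(as.integer(sw$n_locations[1, ])) <= 0))
  expect_true(all(diff(sw$quality_qaly) >= -1e-9))
})

test_that("travel report reproduces hand arithmetic and its identities", {
  inst <- hand_instance(slopes = c(0, 0), maxt = c(1e6, 1e6))
  offers <- matrix(1L, 2, 2)
  sol <- hosp_solution(inst, c(TRUE, TRUE), offers,
                       nearest_feasible_assignment(inst, offers))
  rep <- travel_report(inst, sol)
  # demand zips (100,200,100) pops; group1 elective nv 2, group2 chronic nv 3
  w <- sweep(inst$demand, 2, inst$groups$n_visits, "*")
  tt <- apply(inst$travel, 1, min)
  expect_equal(rep$mean_min[rep$care_class == "elective"],
               sum(w[, 1] * tt) / sum(w[, 1]))
  expect_equal(rep$mean_min[rep$care_class == "chronic"],
               sum(w[, 2] * tt) / sum(w[, 2]))
  # overall mean is the demand-weighted average of class means
  overall <- rep$mean_min[rep$care_class == "overall"]
  cls <- rep[rep$care_class != "overall", ]
  wcls <- c(sum(w[, 1]), sum(w[, 2]))[match(cls$care_class,
                                            c("elective", "chronic"))]
  expect_equal(overall, sum(cls$mean_min * wcls) / sum(wcls))
  # opening everything can only shorten trips
  expect_true(all(rep$baseline_mean_min <= rep$mean_min + 1e-9))
})

test_that("landscape comparison tables are tidy and label-safe", {
  inst <- random_micro_instance(seed = 61, n_zips = 4, n_sites = 3,
                                n_groups = 2, utilization = "conditional")
  sol_c <- solve_instance(inst, micro_opts())
  inst_l <- inst
  inst_l$config$utilization_mode <- "literal"
  sol_l <- solve_instance(inst_l, micro_opts())
  expect_error(compare_landscapes(inst, list(a = sol_c, a = sol_c)), "unique")
  if (sol_l$solver_status != "infeasible") {
    tab <- compare_landscapes(inst, list(conditional = sol_c,
                                         literal = sol_l))
    expect_equal(nrow(tab), 2 * nrow(inst$groups))
    # conditional mode relaxes the literal one
    expect_gte(unique(tab$objective_eur[tab$label == "conditional"]),
               unique(tab$objective_eur[tab$label == "literal"]) - 1e-6)
  }
  tab1 <- compare_landscapes(inst, list(only = sol_c))
  expect_equal(unique(tab1$label), "only")
})
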