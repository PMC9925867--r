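test_that("discount factors follow (1+r)^-t with cycle 0 undiscounted", {
  expect_equal(discount_factor(0, 0.035), 1.0)
  expect_equal(discount_factor(1, 0.035), 1 / 1.035)
  expect_equal(round(discount_factor(1, 0.035), 6), 0.966184)
  expect_equal(discount_factor(0:10, 0), rep(1, 11))
  expect_error(discount_factor(1, -0.01), "non-negative")
})

test_that("transition matrix encodes quit/cessation/relapse with death first", {
  lt0 <- zero_mortality_surfaces()$life_table
  rates <- list(net_cessation = 0.02, relapse = 0)
  # post-12-month cycle, zero mortality: current row is the net rates
  m <- build_transition_matrix(5, 40, "female", 0.173, rates, lt0, 2.22)
  expect_equal(unname(m["current", ]), c(0.98, 0.02, 0))
  expect_equal(unname(m["former", ]), c(0, 1, 0))
  # 12-month boundary uses the arm's quit probability
  m1 <- build_transition_matrix(1, 40, "female", 0.173, rates, lt0, 2.22)
  expect_equal(unname(m1["current", ]), c(0.827, 0.173, 0))
  # death competes first: current -> former = (1 - d) * q
  lt <- lt0
  lt[] <- 0.3
  md <- build_transition_matrix(1, 40, "male", 0.5, rates, lt, 1)
  expect_equal(unname(md["current", ]), c(0.35, 0.35, 0.3))
  expect_error(build_transition_matrix(2, 40, "male", 0.5,
    list(net_cessation = 1.4, relapse = 0), lt0, 1), "\\[0, 1\\]")
})

test_that("transition matrix rows always sum to one", {
  withr::with_seed(11, {
    for (i in 1:25) {
      lt <- random_life_table()
      rates <- list(net_cessation = runif(1), relapse = runif(1))
      m <- build_transition_matrix(sample(1:30, 1), sample(12:100, 1),
                                   sample(c("female", "male"), 1), runif(1),
                                   rates, lt, runif(1, 0.5, 3))
      expect_equal(unname(rowSums(m)), c(1, 1, 1), tolerance = 1e-12)
    }
  })
})

test_that("state utility combines base, status, SMI and comorbidity decrements", {
  utils_l <- list(base = 0.88, decrement_current = 0.04,
                  decrement_former = 0.02, smi_decrement = 0.125)
  pv <- blank_prevalence()
  cu <- setNames(base_pset$comorbidities$utility_mean,
                 base_pset$comorbidities$condition)
  expect_equal(state_utility("current", 40, "female", utils_l, pv, cu), 0.715)
  # zero decrements reduce to the base utility
  u0 <- list(base = 0.88, decrement_current = 0, decrement_former = 0,
             smi_decrement = 0)
  expect_equal(state_utility("former", 40, "female", u0, pv, cu), 0.88)
  # full stroke prevalence subtracts (base - u_stroke)
  pv["stroke", , , ] <- 1
  expect_equal(state_utility("former", 70, "male", utils_l, pv, cu),
               0.88 - 0.02 - 0.125 - (0.88 - 0.48))
  expect_error(state_utility("dead", 40, "female", utils_l, pv, cu), "live")
})

test_that("state cost is the prevalence-weighted sum of condition costs", {
  pv <- blank_prevalence()
  costs <- setNames(base_pset$comorbidities$annual_cost_mean,
                    base_pset$comorbidities$condition)
  expect_equal(state_cost("current", 50, "female", pv, costs), 0)
  pv["copd", , , ] <- 0.5
  expect_equal(state_cost("current", 50, "female", pv, costs), 0.5 * 636)
})

test_that("cohort trace conserves occupancy and accumulates the dead state", {
  tr <- run_cohort(40, "male", "bsci", base_pset, base_surfaces)
  expect_equal(tr$current + tr$former + tr$dead, rep(1, nrow(tr)),
               tolerance = 1e-10)
  expect_true(all(diff(tr$dead) >= -1e-12))
  expect_true(all(tr$disc_cost[-1] <= tr$cost[-1] + 1e-12))
  expect_true(all(tr$disc_qaly[-1] <= tr$qaly[-1] + 1e-12))
  expect_equal(nrow(tr), 101 - 40)
  expect_equal(tr$age, 40:100)
  # everyone dead once past age 100 (absorbing last cycle)
  expect_equal(tr$current[1], 1)
})

test_that("degenerate cohorts behave as expected", {
  # no quitting ever: former occupancy stays zero
  cfg <- list(quit_prob = 0, rates = list(net_cessation = 0, relapse = 0))
  tr <- run_cohort(60, "female", "bsci", base_pset, base_surfaces, cfg)
  expect_equal(tr$former, rep(0, nrow(tr)))
  # certain death at entry age: totals reduce to cycle-0 accruals
  sf <- base_surfaces
  sf$life_table[] <- 1
  tr <- run_cohort(50, "male", "usual_care", base_pset, sf)
  expect_equal(tr$dead[2], 1)
  tot <- attr(tr, "totals")
  expect_equal(tot[["disc_cost"]], tr$cost[1])
  expect_equal(tot[["disc_qaly"]], tr$qaly[1])
  expect_error(run_cohort(40, "male", "bsci", base_pset, base_surfaces,
                          list(horizon = 0)), "horizon")
  expect_error(run_cohort(8, "male", "bsci", base_pset, base_surfaces),
               "12-100")
})

test_that("with mortality off, former occupancy follows 1-(1-q0)(1-c)^(t-1)", {
  sf0 <- zero_mortality_surfaces()
  q0 <- 0.173
  tr <- run_cohort(30, "female", "bsci", base_pset, sf0,
                   list(quit_prob = q0))
  t_idx <- tr$cycle[tr$cycle >= 1]
  expect_equal(tr$former[tr$cycle >= 1],
               1 - (1 - q0) * 0.98^(t_idx - 1), tolerance = 1e-12)
  # ten cycles after the 12-month effect
  expect_equal(round(tr$former[tr$cycle == 11], 5), 0.32428)
})

test_that("vectorised population engine agrees with per-cohort runs", {
  ec <- smicea:::build_eval_context(base_pset, base_surfaces)
  cells <- smicea:::population_outcomes(ec, quit_prob = 0.173)
  for (age in c(12, 37, 64, 85, 100)) {
    for (sx in c("female", "male")) {
      tr <- run_cohort(age, sx, "bsci", base_pset, base_surfaces,
                       list(quit_prob = 0.173, intervention_cost = 0))
      tot <- attr(tr, "totals")
      row <- cells[cells$age == age & cells$sex == sx, ]
      expect_equal(row$disc_cost_comorbidity, tot[["disc_cost_comorbidity"]],
                   tolerance = 1e-10)
      expect_equal(row$disc_qaly, tot[["disc_qaly"]], tolerance = 1e-10)
    }
  }
  # and under a restricted horizon
  cells5 <- smicea:::population_outcomes(ec, 0.173, horizon = 5)
  tr5 <- run_cohort(40, "male", "bsci", base_pset, base_surfaces,
                    list(quit_prob = 0.173, intervention_cost = 0,
                         horizon = 5))
  row <- cells5[cells5$age == 40 & cells5$sex == "male", ]
  expect_equal(row$disc_qaly, attr(tr5, "totals")[["disc_qaly"]],
               tolerance = 1e-10)
})

test_that("equal effectiveness leaves only the intervention cost difference", {
  cfg <- list(quit_prob = list(bsci = 0.119, usual_care = 0.119))
  res <- run_comparison(base_pset, base_surfaces, "bsci_vs_uc", cfg)
  expect_equal(res$delta_qalys, 0, tolerance = 1e-12)
  expect_equal(res$delta_cost_comorbidity, 0, tolerance = 1e-10)
  expect_equal(res$delta_cost, 581 - 96, tolerance = 1e-10)
})

test_that("higher quit probability never hurts QALYs nor raises comorbidity costs", {
  qs <- seq(0.05, 0.9, by = 0.1)
  outs <- lapply(qs, function(q) {
    arm_outcome("bsci", base_pset, base_surfaces, list(quit_prob = q))
  })
  qalys <- vapply(outs, function(o) o$qalys, numeric(1))
  costs <- vapply(outs, function(o) o$cost_comorbidity, numeric(1))
  expect_true(all(diff(qalys) >= -1e-12))
  expect_true(all(diff(costs) <= 1e-12))
})

test_that("neutral SMI adjustments reduce to the general-population structure", {
  ps <- base_pset
  ps$smi$rr_mortality[["mean"]] <- 1
  ps$smi$or_comorbidity[["mean"]] <- 1
  ps$smi$smi_disutility[["mean"]] <- 0
  ec <- smicea:::build_eval_context(ps, base_surfaces)
  # prevalence unadjusted, mortality untouched
  expect_equal(ec$prevalence, base_surfaces$prevalence)
  expect_equal(ec$death[, "female", "current"],
               base_surfaces$life_table[, "female", "current"])
  # utility for a mid-age current smoker matches the hand formula without SMI
  pv <- base_surfaces$prevalence[, "50", "male", "current"]
  cu <- ps$comorbidities$utility_mean
  expect_equal(unname(ec$util["50", "male", "current"]),
               0.88 - 0.04 - sum(pv * (0.88 - cu)), tolerance = 1e-12)
})
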