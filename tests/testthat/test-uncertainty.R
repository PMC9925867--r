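test_that("sampling with zero SDs returns the deterministic set exactly", {
  ps0 <- degenerate_pset()
  expect_identical(sample_iteration(ps0), ps0)
})

test_that("sampling is reproducible per seed and respects parameter supports", {
  s1 <- withr::with_seed(5, sample_iteration(base_pset))
  s2 <- withr::with_seed(5, sample_iteration(base_pset))
  expect_identical(s1, s2)
  withr::with_seed(6, {
    for (i in 1:20) {
      s <- sample_iteration(base_pset)
      expect_true(all(s$effectiveness$quit_prob_12m >= 0 &
                        s$effectiveness$quit_prob_12m <= 1))
      expect_true(all(s$comorbidities$annual_cost_mean >= 0))
      expect_true(all(s$comorbidities$utility_mean >= 0 &
                        s$comorbidities$utility_mean <= 1))
      expect_true(s$smi$rr_mortality[["mean"]] > 0)
      expect_true(s$smi$smi_disutility[["mean"]] >= 0 &
                    s$smi$smi_disutility[["mean"]] <= 1)
    }
  })
})

test_that("set_parameter writes into every block and rejects unknown names", {
  ps <- set_parameter(base_pset, "effectiveness_bsci", 0.3)
  expect_equal(ps$effectiveness$quit_prob_12m[ps$effectiveness$arm == "bsci"],
               0.3)
  ps <- set_parameter(base_pset, "cost_stroke", 1234)
  expect_equal(ps$comorbidities$annual_cost_mean[
    ps$comorbidities$condition == "stroke"], 1234)
  ps <- set_parameter(base_pset, "rr_mortality", 1.5)
  expect_equal(ps$smi$rr_mortality[["mean"]], 1.5)
  expect_error(set_parameter(base_pset, "nonesuch", 1), "unknown parameter")
})

test_that("all-degenerate PSA reproduces the deterministic result exactly", {
  ps0 <- degenerate_pset()
  det <- run_comparison(ps0, base_surfaces, "bsci_vs_uc")
  psa <- run_psa(ps0, base_surfaces, "bsci_vs_uc", n_iterations = 5, seed = 3)
  expect_equal(psa$mean_delta_cost, det$delta_cost, tolerance = 1e-12)
  expect_equal(psa$mean_delta_qalys, det$delta_qalys, tolerance = 1e-12)
  expect_equal(psa$sd_delta_cost, 0)
  expect_equal(psa$probabilistic_icer, det$icer, tolerance = 1e-12)
  expect_equal(psa$prob_cost_effective, as.numeric(det$cost_effective))
})

test_that("degenerate PSA probabilities hit 0 and 1 for strictly ordered arms", {
  ps0 <- degenerate_pset()
  psa <- run_psa(ps0, base_surfaces, "bsci_vs_uc", n_iterations = 3, seed = 1)
  expect_equal(psa$prob_cost_effective, 1)
  # make the intervention strictly worse: no extra quitting, huge cost
  cfg <- list(quit_prob = list(bsci = 0.119, usual_care = 0.119),
              intervention_cost = list(bsci = 5000, usual_care = 0))
  psa <- run_psa(ps0, base_surfaces, "bsci_vs_uc", n_iterations = 3, seed = 1,
                 config = cfg)
  expect_equal(psa$prob_cost_effective, 0)
})

test_that("the CEAC path agrees with the headline probability at the threshold", {
  psa <- run_psa(base_pset, base_surfaces, "ic_vs_scc", n_iterations = 60,
                 seed = 9, thresholds = c(0, 20000, 50000))
  at_thr <- psa$ceac$probability[psa$ceac$threshold == 20000]
  expect_equal(psa$prob_cost_effective, at_thr)
  expect_true(all(psa$ceac$probability >= 0 & psa$ceac$probability <= 1))
  # threshold 0: cost-effective only when costs are saved
  expect_equal(psa$ceac$probability[psa$ceac$threshold == 0],
               mean(psa$delta_cost < 0))
})

test_that("DSA bounds sit at mean +/- 1.96 SD (log scale for log-normal)", {
  b <- smicea:::dsa_bounds("beta", 0.173, 0.024)
  expect_equal(unname(b), c(0.173 - 1.96 * 0.024, 0.173 + 1.96 * 0.024))
  expect_equal(unname(smicea:::dsa_bounds("gamma", 636, 95)),
               c(636 - 1.96 * 95, 636 + 1.96 * 95))
  spec <- moment_match("lognormal", 2.22, 0.02)
  expect_equal(unname(smicea:::dsa_bounds("lognormal", 2.22, 0.02)),
               exp(spec$params$meanlog + c(-1.96, 1.96) * spec$params$sdlog))
  # zero SD pins both bounds at the mean
  expect_equal(unname(smicea:::dsa_bounds("beta", 0.5, 0)), c(0.5, 0.5))
  # clamped to support
  expect_equal(unname(smicea:::dsa_bounds("beta", 0.88, 0.13))[2], 1)
})

test_that("one-way DSA: null perturbation reproduces the base ICER; zero-SD rows are flat", {
  base <- run_comparison(base_pset, base_surfaces, "bsci_vs_uc")
  for (nm in c("rr_mortality", "cost_copd", "effectiveness_bsci")) {
    tab <- psa_parameter_table(base_pset)
    m <- tab$mean[tab$name == nm]
    r <- run_comparison(set_parameter(base_pset, nm, m), base_surfaces,
                        "bsci_vs_uc")
    expect_equal(r$icer, base$icer, tolerance = 1e-12)
  }
  d <- run_dsa(base_pset, base_surfaces, "bsci_vs_uc", parameters = "relapse")
  expect_equal(d$low, d$high)
  expect_equal(d$icer_low, base$icer, tolerance = 1e-12)
  expect_equal(d$icer_high, base$icer, tolerance = 1e-12)
})

test_that("DSA flags dominance when effectiveness drops below the comparator", {
  # shrink BSCI effectiveness so its lower 95% bound falls under usual care
  ps <- base_pset
  ps$effectiveness$quit_prob_12m[ps$effectiveness$arm == "bsci"] <- 0.125
  ps$effectiveness$sd[ps$effectiveness$arm == "bsci"] <- 0.02
  d <- run_dsa(ps, base_surfaces, "bsci_vs_uc",
               parameters = "effectiveness_bsci")
  expect_identical(d$label_low, "dominated")
  expect_true(is.na(d$icer_low))
})

test_that("a wider comorbidity-cost SD widens the tornado bar", {
  ps_wide <- base_pset
  i <- ps_wide$comorbidities$condition == "stroke"
  ps_wide$comorbidities$annual_cost_sd[i] <-
    2 * ps_wide$comorbidities$annual_cost_sd[i]
  d1 <- run_dsa(base_pset, base_surfaces, "ic_vs_scc",
                parameters = "cost_stroke")
  d2 <- run_dsa(ps_wide, base_surfaces, "ic_vs_scc",
                parameters = "cost_stroke")
  expect_gt(d2$icer_range, d1$icer_range)
})

test_that("scenario substitutions reduce to the base case at neutral settings", {
  base <- run_comparison(base_pset, base_surfaces, "bsci_vs_uc")
  s3 <- run_scenario(base_pset, base_surfaces, "bsci_vs_uc", "3",
                     list(s3_cessation = 0.02, s3_relapse = 0))
  expect_equal(s3$icer, base$icer, tolerance = 1e-12)
  s2 <- run_scenario(base_pset, base_surfaces, "bsci_vs_uc", "2",
                     list(service_utilisation = c(
                       bsci = 0, usual_care = 0, integrated_care = 0,
                       scc_referral = 0)))
  expect_equal(s2$icer, base$icer, tolerance = 1e-12)
  ps <- base_pset
  ps$selfreport_effectiveness <- NULL
  expect_error(run_scenario(ps, base_surfaces, "bsci_vs_uc", "1"),
               "self-report")
})

test_that("restricting the horizon to 5 years shrinks the incremental QALYs", {
  life <- run_comparison(base_pset, base_surfaces, "ic_vs_scc")
  five <- run_comparison(base_pset, base_surfaces, "ic_vs_scc",
                         list(horizon = 5))
  expect_lt(five$delta_qalys, life$delta_qalys)
  expect_gt(five$icer, life$icer)
})

test_that("full evaluation writes a complete, reproducible result bundle", {
  run_once <- function(dir) {
    run_full_evaluation(list(comparison = "ic_vs_scc", scenarios = c("2", "3"),
                             psa_iterations = 25, seed = 11,
                             reference_seed = 4, out_dir = dir),
                        quiet = TRUE)
  }
  d1 <- tempfile("eval1"); d2 <- tempfile("eval2")
  r1 <- run_once(d1); r2 <- run_once(d2)
  files <- c("ic_vs_scc_base.csv", "ic_vs_scc_scenario2.csv",
             "ic_vs_scc_scenario3.csv", "ic_vs_scc_tornado.csv",
             "ic_vs_scc_psa_iterations.csv", "ic_vs_scc_ceac.csv",
             "ic_vs_scc_manifest.json")
  expect_true(all(file.exists(file.path(d1, files))))
  for (f in setdiff(files, "ic_vs_scc_manifest.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_equal(r1$manifest$psa_seed, 11)
  summ <- read.csv(file.path(d1, "ic_vs_scc_base.csv"))
  expect_equal(summ$row, c("integrated_care", "scc_referral", "incremental"))
  expect_error(run_full_evaluation(list(comparison = "nope"), quiet = TRUE),
               "valid options")
  expect_error(run_full_evaluation(list(scenarios = "9"), quiet = TRUE),
               "valid options")
})
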