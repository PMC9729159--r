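test_that("correlated indices hit the target correlation and reproduce", {
  cfg <- reliability_sim_config(n_subjects = 10000, true_r = 0.9,
                                data_kind = "binary")
  idx <- simulate_correlated_indices(cfg, seed = 3)
  expect_equal(cor(idx[, 1], idx[, 2]), 0.9, tolerance = 0.01)
  idx2 <- simulate_correlated_indices(cfg, seed = 3)
  expect_identical(idx, idx2)

  cfg0 <- reliability_sim_config(n_subjects = 10000, true_r = 0,
                                 data_kind = "continuous")
  idx0 <- simulate_correlated_indices(cfg0, seed = 4)
  expect_lt(abs(cor(idx0[, 1], idx0[, 2])), 0.03)
  expect_error(reliability_sim_config(true_r = 1.2), "true_r")
})

test_that("trial data reflect the indices in both kinds", {
  ones <- matrix(1, 5, 2)
  tb <- simulate_trial_data(ones, 50, "binary", seed = 5)
  expect_true(all(tb == 1))
  idx <- matrix(700, 4, 2)
  tc <- simulate_trial_data(idx, 30, "continuous", noise_sd = 0, seed = 6)
  expect_true(all(tc == 700))
  p <- matrix(0.7, 1, 2)
  tb2 <- simulate_trial_data(p, 160, "binary", seed = 7)
  ci <- qnorm(0.995) * sqrt(0.7 * 0.3 / 160)
  expect_lt(abs(mean(tb2[1, , 1]) - 0.7), ci + 1e-9)
  expect_error(simulate_trial_data(matrix(1.2, 2, 2), 10, "binary"),
               "probabilities")
})

test_that("reliability recovery runs all four routes reproducibly", {
  cfg <- reliability_sim_config(n_datasets = 4, n_subjects = 20,
                                n_trials = 60, true_r = 0.7,
                                data_kind = "binary")
  r1 <- suppressMessages(recover_reliability(cfg, seed = 8))
  r2 <- suppressMessages(recover_reliability(cfg, seed = 8))
  expect_identical(r1$results, r2$results)
  expect_setequal(unique(r1$results$route),
                  c("means", "separate", "joint", "model"))
  expect_true(all(r1$results$icc >= -1 & r1$results$icc <= 1))
  expect_true(all(r1$results$sq_error >= 0))
})

test_that("negligible trial noise makes every route recover the truth", {
  # trial noise of 1 ms against an index SD of 100 ms: attenuation is
  # nil, so all four routes should average to the generating correlation
  # (the residual is kept > 0 so the mixed models stay non-degenerate)
  cfg <- reliability_sim_config(n_datasets = 20, n_subjects = 38,
                                n_trials = 40, true_r = 0.7,
                                data_kind = "continuous", noise_sd = 1)
  r <- suppressWarnings(suppressMessages(recover_reliability(cfg,
                                                             seed = 9)))
  expect_identical(r$n_failed, 0L)
  expect_true(all(abs(r$summary$mean_icc - 0.7) < 0.05))
})

test_that("parameter recovery is deterministic and sharp when identifiable", {
  sm <- get_model("SU-beta-alpha")
  set.seed(44)
  truth <- cbind(rep(log(5), 14), rnorm(14, 0, 1))
  sched <- build_schedule(n_trials = 1000,
                          reversal_after = seq(50, 950, 50))
  t1 <- parameter_recovery(truth, sm, sched, methods = "ml",
                           n_datasets = 1, seed = 5, n_restarts = 3)
  t2 <- parameter_recovery(truth, sm, sched, methods = "ml",
                           n_datasets = 1, seed = 5, n_restarts = 3)
  expect_identical(t1, t2)
  expect_gt(t1$mean_r[t1$parameter == "alpha"], 0.9)
})

test_that("model recovery self-selects with a single candidate", {
  sm <- get_model("SU-rho-alpha")
  conf <- model_recovery(list(sm), n_datasets = 2, n_subjects = 8,
                         seed = 10, em_max_iter = 5, em_tol = 0.5,
                         K = 500)
  expect_identical(unname(conf[1, 1]), 2L)
  expect_equal(unname(rowSums(conf)) + attr(conf, "n_failed"), 2)
})

test_that("posterior predictive checks close the self-consistency loop", {
  m <- get_model("DU-2rho-alpha")
  pop <- population_spec(n_subjects = 38)
  pars <- sample_population_params(pop, seed = 77)
  set.seed(77)
  cohort <- sim_cohort_rows(pars$native$s1, m, build_schedule())
  fe <- fit_em(cohort, m, max_iter = 15, tol = 0.05, n_restarts = 2,
               n_repeats = 1, seed = 5)
  ppc <- posterior_predictive_check(fe$estimates_native[[1]], m,
                                    build_schedule(), cohort,
                                    n_sims = 60, seed = 6)
  expect_gt(ppc$correlations[["accuracy"]], 0.5)
  expect_gt(ppc$correlations[["stay_overall"]], 0.7)
  expect_gt(ppc$correlations[["stay_after_loss"]], 0.7)
  # regression to the mean: generated metrics vary less than observed
  expect_lte(var(ppc$per_subject$gen_accuracy),
             var(ppc$per_subject$obs_accuracy))
})
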