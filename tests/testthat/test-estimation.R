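sched320 <- build_schedule(n_trials = 320, reversal_after = seq(40, 280, 40))

test_that("ML recovers the learning rate in a well-identified regime", {
  sm <- get_model("SU-beta-alpha")
  set.seed(42)
  cohort <- sim_cohort(c(beta = 5, alpha = 0.7), sm, sched320, 20)
  fit <- fit_ml(cohort, sm, n_restarts = 3, n_repeats = 1, seed = 1)
  err <- abs(fit$estimates_native[[1]][, "alpha"] - 0.7)
  expect_lt(median(err), 0.15)
  # restart determinism
  fit2 <- fit_ml(cohort, sm, n_restarts = 3, n_repeats = 1, seed = 1)
  expect_identical(fit$estimates_unc, fit2$estimates_unc)
})

test_that("a constant-choice subject yields finite flagged-or-converged output", {
  sm <- get_model("SU-beta-alpha")
  df <- trials_df(choice = rep(1L, 80), feedback = sample(c(-1, 1), 80, TRUE),
                  correct = rep(1L, 80))
  set.seed(2)
  fit <- fit_ml(df, sm, n_restarts = 4, n_repeats = 1, seed = 3)
  expect_true(all(is.finite(fit$estimates_unc[[1]])))
  expect_true(all(fit$convergence[[1]] %in% c(0L, 1L, 99L)))
})

test_that("the MAP0 prior regularizes and washes out with data volume", {
  sm <- get_model("SU-beta-alpha")
  gaps <- c()
  for (nt in c(40, 640)) {
    sched <- build_schedule(n_trials = nt,
                            reversal_after = seq(20, nt - 20, 20))
    set.seed(9)
    cohort <- sim_cohort(c(beta = 3, alpha = 0.6), sm, sched, 8)
    fml <- fit_ml(cohort, sm, n_restarts = 4, n_repeats = 1, seed = 2)
    fm0 <- fit_map0(cohort, sm, n_restarts = 4, n_repeats = 1, seed = 3)
    gaps <- c(gaps, mean(abs(fm0$estimates_unc[[1]] -
                               fml$estimates_unc[[1]])))
    # MAP0 objective at the optimum beats the prior mean
    for (i in 1:2) {
      obj0 <- negative_log_likelihood(
        c(0, 0), cohort[cohort$subject_id == sprintf("S%03d", i), ], sm)
      expect_lte(fm0$objective[[1]][i], obj0 + 1e-6)
    }
  }
  expect_lt(gaps[2], gaps[1])
})

test_that("joint likelihood is exactly additive across sessions", {
  m <- get_model("DU-2rho-alpha")
  sched <- build_schedule()
  set.seed(14)
  s1 <- sim_cohort(c(3, 2, 0.5), m, sched, 2, session = 1L)
  s2 <- sim_cohort(c(2, 1, 0.4), m, sched, 2, session = 2L)
  cs <- concat_sessions(s1, s2, m)
  th1 <- c(0.5, 0.3, -0.2); th2 <- c(1.1, -0.4, 0.6)
  one <- cs$data[cs$data$subject_id == "S001", ]
  expect_equal(
    negative_log_likelihood_joint(c(th1, th2), one, cs$spec),
    negative_log_likelihood(th1, one[one$session == 1, ], m) +
      negative_log_likelihood(th2, one[one$session == 2, ], m),
    tolerance = 1e-12)
  expect_error(concat_sessions(s1, s2[s2$subject_id == "S001", ], m),
               "same subjects")
})

test_that("ML joint and separate fits coincide (no cross-session coupling)", {
  sm <- get_model("SU-beta-alpha")
  sched <- build_schedule()
  set.seed(15)
  cohort <- rbind(sim_cohort(c(beta = 4, alpha = 0.6), sm, sched, 6, 1L),
                  sim_cohort(c(beta = 4, alpha = 0.6), sm, sched, 6, 2L))
  fs <- fit_ml(cohort, sm, "separate", n_restarts = 5, n_repeats = 1,
               seed = 4)
  fj <- fit_ml(cohort, sm, "joint", n_restarts = 5, n_repeats = 1,
               seed = 5)
  sep_obj <- fs$objective[["1"]] + fs$objective[["2"]]
  expect_equal(unname(fj$objective$joint), unname(sep_obj),
               tolerance = 0.05)
  for (s in c("1", "2")) {
    a <- fj$estimates_unc[[s]]; b <- fs$estimates_unc[[s]]
    # near-deterministic subjects push beta toward infinity along a flat
    # likelihood ridge; compare only well-identified estimates
    ok <- abs(a) < 5 & abs(b) < 5
    expect_gt(mean(ok), 0.7)
    expect_equal(a[ok], b[ok], tolerance = 0.05)
  }
})

test_that("EM recovers the population mean and shrinks toward it", {
  m <- get_model("DU-2rho-alpha")
  pop <- population_spec(n_subjects = 38)
  pars <- sample_population_params(pop, seed = 101)
  set.seed(101)
  cohort <- sim_cohort_rows(pars$native$s1, m, sched320)
  fe <- fit_em(cohort, m, max_iter = 40, tol = 0.02, n_restarts = 2,
               n_repeats = 1, seed = 7)
  mu_hat <- fe$prior[["1"]]$mean
  expect_lt(max(abs(mu_hat - colMeans(pars$unconstrained$s1))), 0.2)
  expect_true(fe$prior[["1"]]$converged)

  # penalized group log-likelihood is non-decreasing (small numerical slack)
  tr <- fe$trace[["1"]]
  expect_true(all(diff(tr) > -0.5))

  # partial pooling: EM estimates sit closer to the group mean and vary
  # less than ML estimates, for every parameter
  fm <- fit_ml(cohort, m, n_restarts = 3, n_repeats = 1, seed = 8)
  eml <- fm$estimates_unc[[1]]; eem <- fe$estimates_unc[[1]]
  for (j in 1:3) {
    expect_lt(mean(abs(eem[, j] - mu_hat[j])),
              mean(abs(eml[, j] - mu_hat[j])))
    expect_lt(var(eem[, j]), var(eml[, j]))
  }
})

test_that("a shared true parameter makes the EM prior variance shrink", {
  sm <- get_model("SU-beta-alpha")
  set.seed(55)
  cohort <- sim_cohort(c(beta = 4, alpha = 0.6), sm, build_schedule(), 15)
  fe <- fit_em(cohort, sm, max_iter = 12, tol = 1e-5, n_restarts = 2,
               n_repeats = 1, seed = 9)
  # alpha prior variance well below its starting value of 10
  expect_lt(fe$prior[["1"]]$cov["alpha", "alpha"], 1)
})

test_that("iBIC prefers the generating (simpler) nested model", {
  simple <- get_model("SU-rho-alpha")
  complx <- get_model("DU-2rho-2alpha-kappa")
  sched <- build_schedule()
  wins <- 0
  for (k in 1:5) {
    set.seed(500 + k)
    nat <- transform_params(simple, cbind(rnorm(20, 1, 0.4),
                                          rnorm(20, 0, 0.7)))
    cohort <- sim_cohort_rows(nat, simple, sched)
    fs <- fit_em(cohort, simple, max_iter = 15, tol = 0.05,
                 n_restarts = 2, n_repeats = 1, seed = 600 + k)
    fc <- fit_em(cohort, complx, max_iter = 15, tol = 0.05,
                 n_restarts = 2, n_repeats = 1, seed = 700 + k)
    wins <- wins + (ibic(fs, cohort, K = 2000, seed = 800 + k) <
                      ibic(fc, cohort, K = 2000, seed = 900 + k))
  }
  expect_gte(wins, 4)
})

test_that("iBIC is invariant to subject ordering and MC-stable", {
  m <- get_model("DU-2rho-alpha")
  pop <- population_spec(n_subjects = 20)
  pars <- sample_population_params(pop, seed = 61)
  set.seed(61)
  cohort <- sim_cohort_rows(pars$native$s1, m, build_schedule())
  fe <- fit_em(cohort, m, max_iter = 15, tol = 0.05, n_restarts = 2,
               n_repeats = 1, seed = 10)
  i_a <- ibic(fe, cohort, K = 2000, seed = 1)
  shuffled <- cohort[order(rev(cohort$subject_id), cohort$trial), ]
  i_b <- ibic(fe, shuffled, K = 2000, seed = 1)
  expect_equal(i_a, i_b, tolerance = 1e-8)
  # doubling the Monte-Carlo sample moves iBIC by less than its MC error
  i_c <- ibic(fe, cohort, K = 4000, seed = 2)
  expect_lt(abs(i_a - i_c), 10)
  expect_warning(ibic(fe, cohort, K = 50, seed = 3), "unstable")
})

test_that("model ranking by iBIC is deterministic and well-formed", {
  tab <- select_model(c(a = 100, b = 90, c = 95))
  expect_identical(tab$model, c("b", "c", "a"))
  expect_equal(tab$delta, c(0, 5, 10))
  expect_equal(select_model(c(only = 42))$delta, 0)
  expect_error(select_model(c(a = 1, b = NaN)), "NaN")
})
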