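test_that("raw metrics match hand counts on worked fixtures", {
  # always-correct agent: accuracy 1, no perseveration window
  df <- trials_df(choice = rep(1L, 6), feedback = c(1, 1, -1, 1, 1, -1),
                  correct = rep(1L, 6))
  m <- compute_raw_metrics(df)
  expect_equal(m$accuracy, 1)
  expect_true(is.na(m$perseveration))
  expect_equal(m$stay_overall, 1)

  # strict alternator never stays
  alt <- trials_df(choice = rep(c(0L, 1L), 4),
                   feedback = sample(c(-1, 1), 8, TRUE),
                   correct = rep(0L, 8))
  expect_equal(compute_raw_metrics(alt)$stay_overall, 0)

  # perseveration fixture: windows at trials 3 (repeat) and 4 (switch)
  per <- trials_df(choice = c(0L, 0L, 0L, 1L, 1L, 1L),
                   feedback = c(-1, -1, -1, 1, 1, 1),
                   correct = rep(1L, 6))
  expect_equal(compute_raw_metrics(per)$perseveration, 0.5)

  # conditioned stays and RT summaries
  df2 <- trials_df(choice = c(0L, 0L, 1L, 1L), feedback = c(1, -1, -1, 1),
                   correct = rep(0L, 4), rt = c(500, 400, 600, 700))
  m2 <- compute_raw_metrics(df2)
  expect_equal(m2$stay_after_win, 1)    # trial 2 follows a win and stays
  expect_equal(m2$stay_after_loss, 0.5) # trials 3 (switch), 4 (stay)
  expect_equal(m2$rt_after_win, 400)
  expect_equal(m2$rt_after_loss, 650)
  expect_equal(m2$delta_rt, -250)
})

test_that("empty conditioning sets yield NA, never 0/0", {
  df <- trials_df(choice = c(0L, 1L, 0L), feedback = c(1, 1, 1),
                  correct = rep(0L, 3))
  m <- compute_raw_metrics(df)
  expect_true(is.na(m$stay_after_loss))
  expect_true(is.na(m$rt_mean))
})

test_that("odd/even split is a deterministic partition", {
  df <- trials_df(choice = rep(0:1, 10), feedback = rep(c(1, -1), 10),
                  correct = rep(0L, 20))
  h <- split_half(df)
  expect_identical(sort(c(h$odd$trial, h$even$trial)), df$trial)
  expect_true(all(h$odd$trial %% 2 == 1))
  # duplicated-trial data -> identical halves
  dup <- df
  dup$choice <- rep(c(0L, 0L, 1L, 1L), 5)
  dup$feedback <- rep(c(1, 1, -1, -1), 5)
  h2 <- split_half(dup)
  expect_identical(h2$odd$choice, h2$even$choice)
  expect_identical(h2$odd$feedback, h2$even$feedback)
})

test_that("split-half consistency of accuracy grows with trial count", {
  m <- get_model("DU-2rho-alpha")
  pop <- population_spec(n_subjects = 25)
  pars <- sample_population_params(pop, seed = 33)
  rs <- c()
  for (nt in c(80, 320)) {
    sched <- build_schedule(n_trials = nt,
                            reversal_after = seq(20, nt - 20, 20))
    set.seed(33)
    cohort <- sim_cohort_rows(pars$native$s1, m, sched)
    h <- split_half(cohort)
    a_o <- cohort_metrics(h$odd)$accuracy
    a_e <- cohort_metrics(h$even)$accuracy
    rs <- c(rs, cor(a_o, a_e))
  }
  expect_gt(rs[2], rs[1])
})

test_that("chance-level performers are excluded by the dual criterion", {
  make_subject <- function(id, p, seed) {
    set.seed(seed)
    trials_df(choice = rbinom(160, 1, p), feedback = sample(c(-1, 1), 160,
                                                            TRUE),
              correct = rep(1L, 160), subject = id)
  }
  good <- do.call(rbind, lapply(1:38, function(i)
    make_subject(sprintf("G%02d", i), 0.8, i)))
  bad <- do.call(rbind, lapply(1:2, function(i)
    make_subject(sprintf("X%02d", i), 0.5, 100 + i)))
  cohort <- rbind(good, bad)
  out <- exclude_chance_performers(cohort)
  expect_identical(out$excluded, c("X01", "X02"))
  expect_length(out$kept, 38)
  # order invariance
  out2 <- exclude_chance_performers(cohort[rev(seq_len(nrow(cohort))), ])
  expect_identical(out2$excluded, out$excluded)
  # a uniformly strong cohort loses nobody
  out3 <- exclude_chance_performers(good)
  expect_length(out3$excluded, 0)
})

test_that("joint hierarchical models return one shrunken value per cell", {
  m <- get_model("DU-2rho-alpha")
  pop <- population_spec(n_subjects = 16)
  study <- generate_study(pop, seed = 12)
  h <- fit_hierarchical_metric(study, "accuracy", "joint")
  expect_identical(nrow(h$predicted), 32L)
  expect_identical(anyDuplicated(h$predicted[c("subject_id", "session")]),
                   0L)
  raw <- cohort_metrics(study)
  merged <- merge(h$predicted, raw, by = c("subject_id", "session"))
  # partial pooling: predicted values vary less than raw proportions
  expect_lte(var(merged$value), var(merged$accuracy))
  expect_gt(cor(merged$value, merged$accuracy), 0.9)

  hs <- fit_hierarchical_metric(study, "accuracy", "separate")
  expect_identical(nrow(hs$predicted), 32L)
  expect_true(all(c("var_between", "var_residual") %in%
                    names(hs$varcomp[[1]])))
})

test_that("a homogeneous cohort shows near-zero between-subject variance", {
  sm <- get_model("SU-beta-alpha")
  set.seed(77)
  cohort <- rbind(
    sim_cohort(c(beta = 1e-4, alpha = 0.5), sm, build_schedule(), 18, 1L),
    sim_cohort(c(beta = 1e-4, alpha = 0.5), sm, build_schedule(), 18, 2L))
  # every subject chooses at random: generative accuracy identical (0.5)
  h <- suppressWarnings(fit_hierarchical_metric(cohort, "accuracy",
                                                "joint"))
  expect_lt(h$varcomp$var_between, 0.05)
  expect_lt(max(abs(h$predicted$value - mean(h$predicted$value))), 0.03)
})

test_that("delta-RT models recover a planted feedback effect", {
  pop <- population_spec(n_subjects = 12,
                         rt = list(grand_mean = 700, subject_sd = 80,
                                   win_shift = -22, noise_sd = 0))
  study <- generate_study(pop, seed = 19)
  h <- suppressWarnings(fit_hierarchical_metric(study, "delta_rt",
                                                "joint"))
  expect_equal(nrow(h$predicted), 24)
  expect_lt(max(abs(h$predicted$value - (-22))), 1)
})
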