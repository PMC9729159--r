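test_that("the model space enumerates 12 per family with unique names", {
  all24 <- enumerate_models()
  expect_length(all24, 24)
  expect_length(enumerate_models("softmax"), 12)
  expect_length(enumerate_models("rho"), 12)
  nms <- vapply(all24, `[[`, "", "name")
  expect_false(anyDuplicated(nms) > 0)
  expect_error(enumerate_models(character()), "at least one")

  m <- get_model("DU-2rho-alpha")
  expect_identical(m$param_names, c("rho_win", "rho_loss", "alpha"))
  expect_identical(m$transforms, c("identity", "identity", "logit"))
  mk <- get_model("DU-2beta-2alpha-kappa")
  expect_identical(mk$param_names,
                   c("beta_win", "beta_loss", "alpha_win", "alpha_loss",
                     "kappa"))
  # kappa only in DU-kappa specs
  has_kappa <- vapply(all24, function(x) "kappa" %in% x$param_names, TRUE)
  expect_identical(sum(has_kappa), 8L)
  expect_true(all(vapply(all24[has_kappa], `[[`, "", "update") == "DUk"))
})

test_that("parameter transforms are the documented bijections", {
  sm <- get_model("SU-beta-alpha")
  nat <- transform_params(sm, c(0, 0))
  expect_equal(unname(nat), c(1, 0.5))  # exp(0), inverse-logit(0)
  rho2 <- get_model("DU-2rho-alpha")
  expect_equal(unname(transform_params(rho2, c(1.7, -0.3, 0))[1:2]),
               c(1.7, -0.3))  # dual rho stays native
  # round trips across the space, random draws
  set.seed(3)
  for (m in enumerate_models()) {
    x <- rnorm(length(m$param_names))
    expect_equal(unname(untransform_params(m, transform_params(m, x))), x,
                 tolerance = 1e-10)
  }
  expect_error(untransform_params(sm, c(1, 1.5)), "0,1")
})

test_that("value updates follow the SU/DU/kappa equations", {
  su <- get_model("SU-beta-alpha")
  du <- get_model("DU-beta-alpha")
  duk <- get_model("DU-beta-alpha-kappa")
  expect_equal(update_values(c(0, 0), 0, 1, c(1, 0.5), su), c(0.5, 0))
  expect_equal(update_values(c(0, 0), 0, 1, c(1, 0.5), du), c(0.5, -0.5))
  expect_equal(update_values(c(0, 0), 0, 1, c(beta = 1, alpha = 0.5,
                                              kappa = 0.5), duk),
               c(0.5, -0.25))
  surho <- get_model("SU-rho-alpha")
  expect_equal(update_values(c(0, 0), 0, 1, c(rho = 2, alpha = 0.5), surho),
               c(1, 0))
  # full-update limit: alpha = 1 makes the chosen value exactly r*
  expect_equal(update_values(c(0.3, -0.2), 1, -1, c(rho = 2, alpha = 1),
                             surho)[2], -2)
  expect_equal(update_values(c(0.3, -0.2), 1, -1, c(beta = 5, alpha = 1),
                             su)[2], -1)
})

test_that("choice probabilities are a proper overflow-safe softmax", {
  sm <- get_model("SU-beta-alpha")
  expect_equal(choice_probabilities(c(0.4, 0.4), 1, c(7, 0.5), sm),
               c(0.5, 0.5))
  p <- choice_probabilities(c(1, 0), 1, c(beta = 1, alpha = 0.5), sm)
  expect_equal(p[1], 1 / (1 + exp(-1)), tolerance = 1e-6)
  p_big <- choice_probabilities(c(1, 0), 1, c(beta = 500, alpha = 0.5), sm)
  expect_true(all(is.finite(p_big)))
  expect_gt(p_big[1], 1 - 1e-10)
  # property: probabilities in (0,1), summing to 1, across random draws
  set.seed(11)
  for (m in enumerate_models()) {
    x <- transform_params(m, rnorm(length(m$param_names)))
    pr <- choice_probabilities(rnorm(2, 0, 2), sample(c(-1, 1), 1), x, m)
    expect_true(all(pr > 0 & pr < 1))
    expect_equal(sum(pr), 1)
  }
  # win/loss temperature selection by previous feedback
  b2 <- get_model("SU-2beta-alpha")
  pw <- choice_probabilities(c(1, 0), 1, c(5, 0.5, 0.5), b2)
  pl <- choice_probabilities(c(1, 0), -1, c(5, 0.5, 0.5), b2)
  p1 <- choice_probabilities(c(1, 0), NA, c(5, 0.5, 0.5), b2)
  expect_gt(pw[1], pl[1])
  expect_equal(pw, p1)  # first trial uses the win parameter by default
})

test_that("the likelihood matches an independent brute-force oracle", {
  set.seed(21)
  models <- enumerate_models()
  for (rep_i in 1:50) {
    m <- models[[sample(24, 1)]]
    df <- trials_df(choice = sample(0:1, 20, TRUE),
                    feedback = sample(c(-1, 1), 20, TRUE),
                    correct = sample(0:1, 20, TRUE))
    if (rep_i %% 3 == 0) df$session <- rep(1:2, each = 10)
    x <- rnorm(length(m$param_names), 0, 0.8)
    expect_equal(negative_log_likelihood(x, df, m),
                 oracle_nll(x, df, m), tolerance = 1e-8)
  }
})

test_that("chance and degenerate likelihood limits are exact", {
  sm <- get_model("SU-beta-alpha")
  df <- trials_df(choice = sample(0:1, 160, TRUE),
                  feedback = sample(c(-1, 1), 160, TRUE),
                  correct = rep(1L, 160))
  expect_equal(negative_log_likelihood(c(-60, 0), df, sm), 160 * log(2),
               tolerance = 1e-6)
  expect_identical(negative_log_likelihood(c(0, 0), df[0, ], sm), 0)
  expect_error(negative_log_likelihood(c(NA, 0), df, sm), "finite")
})

test_that("rho family with rho = 1 equals softmax family with beta = 1", {
  set.seed(5)
  df <- trials_df(choice = sample(0:1, 40, TRUE),
                  feedback = sample(c(-1, 1), 40, TRUE),
                  correct = sample(0:1, 40, TRUE))
  for (upd in c("SU", "DU")) {
    mr <- get_model(paste0(upd, "-rho-alpha"))
    mb <- get_model(paste0(upd, "-beta-alpha"))
    a_unc <- 0.4
    expect_equal(
      negative_log_likelihood(c(0, a_unc), df, mr),  # exp(0) = rho = 1
      negative_log_likelihood(c(0, a_unc), df, mb),  # exp(0) = beta = 1
      tolerance = 1e-10)
  }
})

test_that("Q-values stay bounded by max(1, rho) under any sequence", {
  set.seed(31)
  for (rep_i in 1:20) {
    m <- enumerate_models()[[sample(24, 1)]]
    nat <- transform_params(m, rnorm(length(m$param_names), 0, 0.8))
    rho_max <- max(1, abs(nat[grep("rho", names(nat))]), na.rm = TRUE)
    Q <- c(0, 0)
    for (t in 1:200) {
      Q <- update_values(Q, sample(0:1, 1), sample(c(-1, 1), 1), nat, m)
      expect_true(all(abs(Q) <= rho_max + 1e-9))
    }
  }
})

test_that("simulated agents behave as their parameters dictate", {
  sm <- get_model("SU-beta-alpha")
  sched <- build_schedule()
  a <- simulate_agent(c(beta = 5, alpha = 0.6), sm, sched, seed = 4)
  b <- simulate_agent(c(beta = 5, alpha = 0.6), sm, sched, seed = 4)
  expect_identical(a, b)

  set.seed(8)
  acc0 <- mean(replicate(40, {
    d <- simulate_agent(c(beta = 1e-4, alpha = 0.5), sm, sched)
    mean(d$choice == d$correct_option)
  }))
  ci <- qnorm(0.995) * sqrt(0.25 / (40 * 160))
  expect_lt(abs(acc0 - 0.5), ci + 0.01)

  acc1 <- mean(replicate(40, {
    d <- simulate_agent(c(beta = 20, alpha = 1), sm, sched)
    mean(d$choice == d$correct_option)
  }))
  expect_gt(acc1, 0.7)
})
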