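# Independent oracles and fixture builders, deliberately sharing no code
# with the package internals.

# Plain-R trial-by-trial likelihood, written as a direct transcription of
# the model equations (naive exp/sum softmax, no shared helpers).
oracle_nll <- function(unc, df, spec, first_trial = "win") {
  nat <- numeric(length(unc))
  for (j in seq_along(unc)) {
    nat[j] <- switch(spec$transforms[j],
                     logit = 1 / (1 + exp(-unc[j])),
                     exp = exp(unc[j]),
                     identity = unc[j])
  }
  names(nat) <- spec$param_names
  g <- function(nm) nat[[nm]]
  sess <- if (is.null(df$session)) rep(1, nrow(df)) else df$session
  nll <- 0
  for (chunk in split(df, sess)) {
    Q <- c(0, 0); prev <- NA
    for (t in seq_len(nrow(chunk))) {
      ch <- chunk$choice[t]; r <- chunk$feedback[t]
      if (spec$family == "softmax") {
        if (spec$n_choice_params == 1) b <- g("beta")
        else if (is.na(prev)) {
          b <- switch(first_trial, win = g("beta_win"),
                      loss = g("beta_loss"),
                      average = (g("beta_win") + g("beta_loss")) / 2)
        } else b <- if (prev > 0) g("beta_win") else g("beta_loss")
      } else b <- 1
      p <- exp(b * Q) / sum(exp(b * Q))
      nll <- nll - log(max(p[ch + 1], 1e-12))
      a <- if (spec$n_learning_rates == 1) g("alpha")
           else if (r > 0) g("alpha_win") else g("alpha_loss")
      if (spec$family == "rho") {
        rho <- if (spec$n_choice_params == 1) g("rho")
               else if (r > 0) g("rho_win") else g("rho_loss")
        rs <- rho * r
      } else rs <- r
      Q[ch + 1] <- Q[ch + 1] + a * (rs - Q[ch + 1])
      if (spec$update %in% c("DU", "DUk")) {
        w <- if (spec$update == "DUk") g("kappa") else 1
        Q[2 - ch] <- Q[2 - ch] + w * a * ((-rs) - Q[2 - ch])
      }
      prev <- r
    }
  }
  nll
}

# Brute-force ICC oracle through R's aov() ANOVA tables.
oracle_icc <- function(x, y) {
  n <- length(x)
  d <- data.frame(v = c(x, y), subj = factor(rep(seq_len(n), 2)),
                  sess = factor(rep(1:2, each = n)))
  tw <- summary(stats::aov(v ~ subj + sess, data = d))[[1]]
  msr <- tw[1, 3]; msc <- tw[2, 3]; mse <- tw[3, 3]
  ow <- summary(stats::aov(v ~ subj, data = d))[[1]]
  msb <- ow[1, 3]; msw <- ow[2, 3]
  k <- 2
  list(a1 = (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse)),
       one = (msb - msw) / (msb + (k - 1) * msw))
}

# Single-subject trial table builder.
trials_df <- function(choice, feedback, correct, rt = NA_real_,
                      subject = "s1", session = 1L) {
  data.frame(subject_id = subject, session = session,
             trial = seq_along(choice), choice = choice,
             correct_option = correct, feedback = feedback, rt_ms = rt)
}

# Cohort of identical-parameter agents on one session.
sim_cohort <- function(params_native, spec, schedule, n_subjects,
                       session = 1L) {
  do.call(rbind, lapply(seq_len(n_subjects), function(i) {
    df <- simulate_agent(params_native, spec, schedule)
    df$subject_id <- sprintf("S%03d", i)
    df$session <- session
    df
  }))
}

# Cohort from per-subject native parameter rows.
sim_cohort_rows <- function(nat, spec, schedule, session = 1L) {
  do.call(rbind, lapply(seq_len(nrow(nat)), function(i) {
    df <- simulate_agent(nat[i, ], spec, schedule)
    df$subject_id <- rownames(nat)[i] %||% sprintf("S%03d", i)
    df$session <- session
    df
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
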