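# Simulation experiments: recoverability of reliability for binary and
# continuous data, parameter recovery, model recovery, and posterior
# predictive behavioral checks.

#' Configuration for a reliability-recovery simulation
#'
#' Describes the generative design: per-dataset, normally distributed
#' subject indices correlated across two sessions at `true_r`, taken forward
#' to per-trial Bernoulli draws (binary, choice-like data; the index is the
#' success probability, clipped away from 0/1) or Gaussian draws
#' (continuous, reaction-time-like data; the index is the trial mean).
#'
#' @param n_datasets number of simulated datasets.
#' @param n_subjects subjects per dataset (default 38).
#' @param n_trials trials per session (default 160).
#' @param true_r cross-session correlation of the indices, in (-1, 1).
#' @param data_kind `"binary"` or `"continuous"`.
#' @param index_mean,index_sd marginal distribution of the indices;
#'   defaults: binary 0.7 (SD 0.1), continuous 700 ms (SD 100 ms).
#' @param noise_sd trial noise SD for continuous data (default 250 ms).
#' @param clip clipping range for binary indices (applied after correlation
#'   induction); set to `NULL` to disable.
#' @param seed optional integer seed.
#' @return object of class `prl_sim_config`.
#' @export
reliability_sim_config <- function(n_datasets = 500, n_subjects = 38,
                                   n_trials = 160, true_r = 0.7,
                                   data_kind = c("binary", "continuous"),
                                   index_mean = NULL, index_sd = NULL,
                                   noise_sd = NULL, clip = c(0.01, 0.99),
                                   seed = NULL) {
  data_kind <- match.arg(data_kind)
  .assert(true_r > -1 && true_r < 1, "true_r must be in (-1, 1)")
  if (data_kind == "binary") {
    index_mean <- index_mean %||% 0.7
    index_sd <- index_sd %||% 0.1
  } else {
    index_mean <- index_mean %||% 700
    index_sd <- index_sd %||% 100
    noise_sd <- noise_sd %||% 250
  }
  structure(list(n_datasets = n_datasets, n_subjects = n_subjects,
                 n_trials = n_trials, true_r = true_r,
                 data_kind = data_kind, index_mean = index_mean,
                 index_sd = index_sd, noise_sd = noise_sd, clip = clip,
                 seed = seed), class = "prl_sim_config")
}

#' Simulate cross-session correlated subject indices
#'
#' Bivariate normal pairs with the configured marginal mean/SD and target
#' correlation; binary-kind indices are clipped to the configured range
#' (clipping is counted in attribute `"n_clipped"`).
#'
#' @param config a `prl_sim_config`.
#' @param n number of subjects (default from config).
#' @param seed optional integer seed.
#' @return n-by-2 matrix of paired indices.
#' @export
simulate_correlated_indices <- function(config, n = config$n_subjects,
                                        seed = NULL) {
  .set_seed_if(seed)
  s2 <- config$index_sd^2
  Sigma <- matrix(c(s2, config$true_r * s2, config$true_r * s2, s2), 2)
  idx <- MASS::mvrnorm(n, rep(config$index_mean, 2), Sigma)
  n_clipped <- 0L
  if (config$data_kind == "binary" && !is.null(config$clip)) {
    n_clipped <- sum(idx < config$clip[1] | idx > config$clip[2])
    idx <- pmin(pmax(idx, config$clip[1]), config$clip[2])
  }
  attr(idx, "n_clipped") <- n_clipped
  idx
}

#' Simulate trial-by-trial data from subject indices
#'
#' @param indices n-by-2 matrix of per-subject session indices.
#' @param n_trials trials per session.
#' @param data_kind `"binary"` or `"continuous"`.
#' @param noise_sd trial noise SD (continuous kind).
#' @param seed optional integer seed.
#' @return array of dim `c(n_subjects, n_trials, 2)`.
#' @export
simulate_trial_data <- function(indices, n_trials,
                                data_kind = c("binary", "continuous"),
                                noise_sd = NULL, seed = NULL) {
  data_kind <- match.arg(data_kind)
  .set_seed_if(seed)
  n <- nrow(indices)
  out <- array(NA_real_, c(n, n_trials, 2))
  for (s in 1:2) {
    p <- indices[, s]
    if (data_kind == "binary") {
      .assert(all(p >= 0 & p <= 1),
              "binary indices must be probabilities in [0, 1]")
      out[, , s] <- matrix(rbinom(n * n_trials, 1, rep(p, n_trials)),
                           n, n_trials)
    } else {
      out[, , s] <- matrix(rnorm(n * n_trials, rep(p, n_trials),
                                 noise_sd), n, n_trials)
    }
  }
  out
}

# ---- the four ICC estimation routes ----------------------------------------

.routes_binary <- function(trials, routes) {
  n <- dim(trials)[1]; nt <- dim(trials)[2]
  succ <- cbind(rowSums(trials[, , 1]), rowSums(trials[, , 2]))
  out <- c()
  if ("means" %in% routes)
    out["means"] <- icc_a1(succ[, 1] / nt, succ[, 2] / nt)$estimate
  if (!any(c("separate", "joint", "model") %in% routes)) return(out)
  agg <- data.frame(subject_id = factor(rep(seq_len(n), 2)),
                    session = factor(rep(1:2, each = n)),
                    succ = c(succ[, 1], succ[, 2]))
  agg$fail <- nt - agg$succ
  if ("separate" %in% routes) {
    pr <- matrix(NA_real_, n, 2)
    for (s in 1:2) {
      a <- droplevels(agg[agg$session == s, ])
      m <- lme4::glmer(cbind(succ, fail) ~ 1 + (1 | subject_id), data = a,
                       family = binomial())
      pr[, s] <- predict(m, type = "response")
    }
    out["separate"] <- icc_a1(pr[, 1], pr[, 2])$estimate
  }
  if (any(c("joint", "model") %in% routes)) {
    m <- lme4::glmer(cbind(succ, fail) ~ 1 + (1 | subject_id / session),
                     data = agg, family = binomial())
    if ("joint" %in% routes) {
      pv <- predict(m, type = "response")
      out["joint"] <- icc_a1(pv[agg$session == 1],
                             pv[agg$session == 2])$estimate
    }
    if ("model" %in% routes) {
      v_b <- .vc_component(m, "subject_id")
      v_s <- .vc_component(m, "session:subject_id")
      out["model"] <- if (v_b + v_s > 0)
        icc_from_variance_components(v_b, v_s) else NA_real_
    }
  }
  out
}

.routes_continuous <- function(trials, routes) {
  n <- dim(trials)[1]; nt <- dim(trials)[2]
  means <- cbind(rowMeans(trials[, , 1]), rowMeans(trials[, , 2]))
  out <- c()
  if ("means" %in% routes)
    out["means"] <- icc_a1(means[, 1], means[, 2])$estimate
  if (!any(c("separate", "joint", "model") %in% routes)) return(out)
  df <- data.frame(
    subject_id = factor(rep(rep(seq_len(n), nt), 2)),
    session = factor(rep(1:2, each = n * nt)),
    y = c(as.vector(trials[, , 1]), as.vector(trials[, , 2])))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
  if ("separate" %in% routes) {
    pr <- matrix(NA_real_, n, 2)
    for (s in 1:2) {
      d <- droplevels(df[df$session == s, ])
      m <- lme4::lmer(y ~ 1 + (1 | subject_id), data = d, control = ctrl)
      nd <- data.frame(subject_id = factor(seq_len(n)))
      pr[, s] <- predict(m, newdata = nd)
    }
    out["separate"] <- icc_a1(pr[, 1], pr[, 2])$estimate
  }
  if (any(c("joint", "model") %in% routes)) {
    m <- lme4::lmer(y ~ 1 + (1 | subject_id / session), data = df,
                    control = ctrl)
    if ("joint" %in% routes) {
      nd <- unique(df[c("subject_id", "session")])
      pv <- predict(m, newdata = nd)
      out["joint"] <- icc_a1(pv[nd$session == 1],
                             pv[nd$session == 2])$estimate
    }
    if ("model" %in% routes) {
      v_b <- .vc_component(m, "subject_id")
      v_s <- .vc_component(m, "session:subject_id")
      out["model"] <- if (v_b + v_s > 0)
        icc_from_variance_components(v_b, v_s) else NA_real_
    }
  }
  out
}

#' Recoverability of retest reliability by estimation route
#'
#' For each simulated dataset, estimates the cross-session reliability of
#' the subject indices by four routes — per-session means, predicted values
#' from per-session hierarchical models, predicted values from a joint
#' (session-nested-in-subject) hierarchical model, and the model-calculated
#' ICC from the joint model's variance components — and compares them to the
#' known generating correlation.
#'
#' @param config a `prl_sim_config`.
#' @param routes subset of `c("means", "separate", "joint", "model")`.
#' @param seed optional integer seed (overrides `config$seed`).
#' @return object of class `prl_relsim`: list with `results` (one row per
#'   dataset and route: `dataset`, `route`, `icc`, `sq_error`), `summary`
#'   (per-route mean, SD, mean squared error), `n_failed`, and the config.
#' @export
recover_reliability <- function(config,
                                routes = c("means", "separate", "joint",
                                           "model"),
                                seed = NULL) {
  .assert(inherits(config, "prl_sim_config"), "config required")
  routes <- match.arg(routes, several.ok = TRUE)
  .set_seed_if(seed %||% config$seed)
  rows <- list()
  n_failed <- 0L
  for (k in seq_len(config$n_datasets)) {
    idx <- simulate_correlated_indices(config)
    trials <- simulate_trial_data(idx, config$n_trials, config$data_kind,
                                  config$noise_sd)
    est <- tryCatch(
      if (config$data_kind == "binary") .routes_binary(trials, routes)
      else .routes_continuous(trials, routes),
      error = function(e) NULL)
    if (is.null(est) || anyNA(est)) { n_failed <- n_failed + 1L; next }
    rows[[length(rows) + 1]] <- data.frame(
      dataset = k, route = names(est), icc = unname(est),
      sq_error = unname((est - config$true_r)^2))
  }
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(results, results$route),
    function(d) data.frame(route = d$route[1], mean_icc = mean(d$icc),
                           sd_icc = sd(d$icc), mse = mean(d$sq_error),
                           n = nrow(d))))
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary,
                 n_failed = n_failed, config = config),
            class = "prl_relsim")
}

#' @export
print.prl_relsim <- function(x, ...) {
  cat("reliability recovery: ", x$config$data_kind, " data, true r = ",
      x$config$true_r, ", ", x$config$n_datasets, " datasets (",
      x$n_failed, " failed)\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# ---- parameter and model recovery ------------------------------------------

#' Parameter recovery across estimation methods
#'
#' Simulates datasets from known per-subject parameters, refits them with
#' the requested estimation methods, and reports the average correlation
#' (Pearson and ICC(A,1)) between true and re-estimated values per
#' parameter, in unconstrained space.
#'
#' @param true_params_unc n-by-d matrix of per-subject unconstrained
#'   parameters.
#' @param spec a `prl_model`.
#' @param schedule a `prl_schedule` (each dataset is one session).
#' @param methods subset of `c("ml", "map0", "em")`.
#' @param n_datasets number of simulated datasets.
#' @param seed optional integer seed.
#' @param n_restarts,n_repeats,em_max_iter,em_tol fitting controls.
#' @return data.frame with one row per method and parameter: `mean_r`,
#'   `mean_icc_a1`, `n_datasets`.
#' @export
parameter_recovery <- function(true_params_unc, spec,
                               schedule = build_schedule(),
                               methods = c("ml", "em"), n_datasets = 10,
                               seed = NULL, n_restarts = 3, n_repeats = 1,
                               em_max_iter = 30, em_tol = 1e-2) {
  .set_seed_if(seed)
  methods <- match.arg(methods, c("ml", "map0", "em"), several.ok = TRUE)
  n <- nrow(true_params_unc)
  d <- .n_params(spec)
  nat <- transform_params(spec, true_params_unc)
  acc <- list()
  for (k in seq_len(n_datasets)) {
    rows <- lapply(seq_len(n), function(i) {
      df <- simulate_agent(nat[i, ], spec, schedule)
      df$subject_id <- sprintf("S%03d", i)
      df$session <- 1L
      df
    })
    cohort <- do.call(rbind, rows)
    for (m in methods) {
      fit <- switch(m,
        ml = fit_ml(cohort, spec, n_restarts = n_restarts,
                    n_repeats = n_repeats),
        map0 = fit_map0(cohort, spec, n_restarts = n_restarts,
                        n_repeats = n_repeats),
        em = fit_em(cohort, spec, max_iter = em_max_iter, tol = em_tol,
                    n_restarts = n_restarts, n_repeats = n_repeats))
      est <- fit$estimates_unc[[1]]
      for (j in seq_len(d)) {
        ok <- is.finite(est[, j])
        acc[[length(acc) + 1]] <- data.frame(
          dataset = k, method = m, parameter = spec$param_names[j],
          r = suppressWarnings(cor(true_params_unc[ok, j], est[ok, j])),
          icc_a1 = icc_a1(true_params_unc[ok, j], est[ok, j])$estimate,
          n_ok = sum(ok))
      }
    }
  }
  long <- do.call(rbind, acc)
  out <- do.call(rbind, lapply(
    split(long, list(long$method, long$parameter), drop = TRUE),
    function(dd) data.frame(method = dd$method[1],
                            parameter = dd$parameter[1],
                            mean_r = mean(dd$r, na.rm = TRUE),
                            mean_icc_a1 = mean(dd$icc_a1, na.rm = TRUE),
                            n_datasets = nrow(dd))))
  rownames(out) <- NULL
  out
}

# A neutral generating population for a model: centred learning rates and
# attenuation weights, moderate sensitivities, unit-ish spread.
.default_population_unc <- function(spec) {
  mean_unc <- vapply(spec$transforms, function(tr)
    switch(tr, logit = 0, exp = 1, identity = 2.5), 0)
  sd_unc <- vapply(spec$transforms, function(tr)
    switch(tr, logit = 0.7, exp = 0.4, identity = 1), 0)
  list(mean = unname(mean_unc), sd = unname(sd_unc))
}

#' Model recovery confusion matrix
#'
#' Simulates datasets from each candidate model (subjects drawn from a
#' neutral generating population), refits every candidate by EM-MAP, and
#' selects the winner per dataset by iBIC.
#'
#' @param specs list of `prl_model`s (>= 1).
#' @param n_datasets datasets per generating model.
#' @param n_subjects subjects per dataset.
#' @param schedule a `prl_schedule`.
#' @param seed optional integer seed.
#' @param n_restarts,em_max_iter,em_tol,K fitting/iBIC controls.
#' @return integer matrix: rows = generating model, columns = selected
#'   model, entries = selection counts (row sums = `n_datasets` minus
#'   failures, recorded in attribute `"n_failed"`).
#' @export
model_recovery <- function(specs, n_datasets = 10, n_subjects = 38,
                           schedule = build_schedule(), seed = NULL,
                           n_restarts = 2, em_max_iter = 20, em_tol = 0.05,
                           K = 1000) {
  .assert(length(specs) >= 1, "at least one model required")
  .set_seed_if(seed)
  nm <- vapply(specs, `[[`, "", "name")
  conf <- matrix(0L, length(specs), length(specs), dimnames = list(nm, nm))
  n_failed <- 0L
  for (g in seq_along(specs)) {
    gen <- specs[[g]]
    pop <- .default_population_unc(gen)
    for (k in seq_len(n_datasets)) {
      pars <- sapply(seq_along(pop$mean), function(j)
        rnorm(n_subjects, pop$mean[j], pop$sd[j]))
      pars <- matrix(pars, n_subjects)
      nat <- transform_params(gen, pars)
      cohort <- do.call(rbind, lapply(seq_len(n_subjects), function(i) {
        df <- simulate_agent(nat[i, ], gen, schedule)
        df$subject_id <- sprintf("S%03d", i)
        df$session <- 1L
        df
      }))
      scores <- rep(NA_real_, length(specs))
      for (c in seq_along(specs)) {
        scores[c] <- tryCatch({
          fit <- fit_em(cohort, specs[[c]], max_iter = em_max_iter,
                        tol = em_tol, n_restarts = n_restarts,
                        n_repeats = 1)
          ibic(fit, cohort, K = K)
        }, error = function(e) NA_real_)
      }
      if (anyNA(scores)) { n_failed <- n_failed + 1L; next }
      conf[g, which.min(scores)] <- conf[g, which.min(scores)] + 1L
    }
  }
  attr(conf, "n_failed") <- n_failed
  conf
}

#' Posterior predictive check of behavioral metrics
#'
#' Simulates each subject repeatedly from their fitted parameters and
#' compares the simulation-averaged behavioral metrics with those computed
#' from the observed data.
#'
#' @param params_native n-by-d matrix of per-subject native parameters
#'   (rows named by subject id).
#' @param spec a `prl_model`.
#' @param schedule a `prl_schedule`.
#' @param data observed single-session cohort trial table for the same
#'   subjects.
#' @param n_sims simulations per subject.
#' @param seed optional integer seed.
#' @return list with `per_subject` (observed and mean generated metrics)
#'   and `correlations` (Pearson correlation per metric across subjects).
#' @export
posterior_predictive_check <- function(params_native, spec, schedule, data,
                                       n_sims = 100, seed = NULL) {
  .set_seed_if(seed)
  obs <- cohort_metrics(data)
  ids <- rownames(params_native) %||% as.character(seq_len(nrow(params_native)))
  metrics <- c("accuracy", "stay_overall", "stay_after_win",
               "stay_after_loss", "perseveration")
  gen <- do.call(rbind, lapply(seq_len(nrow(params_native)), function(i) {
    sims <- do.call(rbind, lapply(seq_len(n_sims), function(k)
      compute_raw_metrics(simulate_agent(params_native[i, ], spec,
                                         schedule))))
    out <- as.data.frame(t(colMeans(sims[metrics], na.rm = TRUE)))
    out$subject_id <- ids[i]
    out
  }))
  obs <- obs[match(gen$subject_id, obs$subject_id), ]
  cors <- vapply(metrics, function(m) {
    ok <- is.finite(obs[[m]]) & is.finite(gen[[m]])
    if (sum(ok) < 3) return(NA_real_)
    suppressWarnings(cor(obs[[m]][ok], gen[[m]][ok]))
  }, 0)
  per_subject <- data.frame(subject_id = gen$subject_id)
  for (m in metrics) {
    per_subject[[paste0("obs_", m)]] <- obs[[m]]
    per_subject[[paste0("gen_", m)]] <- gen[[m]]
  }
  list(per_subject = per_subject, correlations = cors)
}
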