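# Parameter estimation: ML, MAP0 (uninformative Gaussian prior), and
# expectation-maximization MAP with a multivariate empirical prior, each for
# separate-session or joint-session (value-reset) fitting.

# ---- data preparation -------------------------------------------------------

# Split a cohort trial table into per-subject lists of session chunks.
# sessions = "separate": one batch per session, each unit has 1 chunk.
# sessions = "joint":    one batch, each unit has one chunk per session.
.cohort_batches <- function(data, sessions) {
  .check_cohort(data)
  data <- data[order(data$subject_id, data$session, data$trial), ]
  sess <- sort(unique(data$session))
  chunk <- function(df) list(choice = as.integer(df$choice),
                             reward = as.numeric(df$feedback))
  if (sessions == "separate") {
    batches <- lapply(sess, function(s) {
      d <- data[data$session == s, ]
      lapply(split(d, factor(d$subject_id, unique(d$subject_id))),
             function(df) list(chunk(df)))
    })
    names(batches) <- as.character(sess)
  } else {
    .assert(length(sess) == 2, "joint fitting requires exactly 2 sessions")
    per_subj <- split(data, factor(data$subject_id, unique(data$subject_id)))
    bad <- names(per_subj)[vapply(per_subj, function(df)
      length(unique(df$session)) != 2, TRUE)]
    .assert(length(bad) == 0,
            paste0("subject(s) present in only one session: ",
                   paste(bad, collapse = ", ")))
    batches <- list(joint = lapply(per_subj, function(df)
      lapply(split(df, df$session), chunk)))
  }
  list(batches = batches, sessions = sess)
}

.make_transformer <- function(transforms) {
  i_l <- which(transforms == "logit")
  i_e <- which(transforms == "exp")
  function(x) {
    if (length(i_l)) x[i_l] <- plogis(x[i_l])
    if (length(i_e)) x[i_e] <- exp(x[i_e])
    x
  }
}

# Negative log-likelihood closure for one unit (list of session chunks).
# For multi-chunk units the unconstrained vector is the concatenation of one
# block per chunk (joint fitting; values reset at each chunk).
.unit_nll <- function(unit, spec, first_trial = "win") {
  codes <- .spec_codes(spec)
  fr <- .first_rule_code(first_trial)
  d <- .n_params(spec)
  nb <- length(unit)
  to_native <- .make_transformer(rep(spec$transforms, nb))
  fam <- codes[["family"]]; upd <- codes[["update"]]
  nlr <- codes[["n_lr"]]; nch <- codes[["n_ch"]]
  function(par) {
    nat <- to_native(par)
    tot <- 0
    for (i in seq_len(nb)) {
      ch <- unit[[i]]
      tot <- tot + nll_session_cpp(nat[((i - 1L) * d + 1L):(i * d)],
                                   ch$choice, ch$reward, fam, upd, nlr, nch,
                                   fr)
    }
    tot
  }
}

# ---- numerical machinery ----------------------------------------------------

#' Finite-difference Hessian
#'
#' Central second differences with step `h`, symmetrized. Used for the
#' Laplace approximation of per-subject posterior covariance.
#'
#' @param f scalar function.
#' @param x evaluation point.
#' @param h step size.
#' @return symmetric numeric matrix.
#' @export
fd_hessian <- function(f, x, h = 1e-4) {
  d <- length(x)
  H <- matrix(0, d, d)
  f0 <- f(x)
  for (i in seq_len(d)) {
    ei <- numeric(d); ei[i] <- h
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    if (i < d) for (j in (i + 1):d) {
      ej <- numeric(d); ej[j] <- h
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h^2)
    }
  }
  (H + t(H)) / 2
}

# Diagonal jitter until Cholesky succeeds; returns the (possibly
# regularized) matrix and whether regularization was needed.
.make_pd <- function(M, jitter = 1e-6) {
  M <- (M + t(M)) / 2
  flagged <- FALSE
  for (k in 0:12) {
    ok <- tryCatch({ chol(M); TRUE }, error = function(e) FALSE)
    if (ok) return(list(M = M, flagged = flagged))
    M <- M + diag(jitter * 10^k, nrow(M))
    flagged <- TRUE
  }
  stop("matrix could not be regularized to positive definite")
}

.optimize_unit <- function(obj, starts, control) {
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    res <- tryCatch(optim(starts[s, ], obj, method = "BFGS",
                          control = control),
                    error = function(e) NULL)
    if (!is.null(res) && is.finite(res$value) &&
        (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best))
    return(list(par = rep(NA_real_, ncol(starts)), value = NA_real_,
                convergence = 99L))
  best
}

# ---- point estimation (ML / MAP0) ------------------------------------------

.fit_point <- function(data, spec, sessions, prior_variance, n_restarts,
                       n_repeats, seed, first_trial, control) {
  sessions <- match.arg(sessions, c("separate", "joint"))
  .set_seed_if(seed)
  prep <- .cohort_batches(data, sessions)
  d <- .n_params(spec)
  out_est <- list(); out_obj <- list(); out_conv <- list(); out_hess <- list()

  for (bn in names(prep$batches)) {
    units <- prep$batches[[bn]]
    db <- d * length(units[[1]])
    est <- matrix(NA_real_, length(units), db,
                  dimnames = list(names(units), NULL))
    val <- rep(NA_real_, length(units))
    conv <- rep(99L, length(units))
    hess <- vector("list", length(units))
    for (i in seq_along(units)) {
      nll <- .unit_nll(units[[i]], spec, first_trial)
      obj <- if (is.null(prior_variance)) nll else
        function(par) nll(par) + sum(par^2) / (2 * prior_variance)
      best <- NULL
      for (rep_k in seq_len(n_repeats)) {
        starts <- matrix(rnorm(n_restarts * db), n_restarts, db)
        r <- .optimize_unit(obj, starts, control)
        if (is.null(best) || (is.finite(r$value) && r$value < best$value))
          best <- r
      }
      est[i, ] <- best$par
      val[i] <- best$value
      conv[i] <- best$convergence
      hess[[i]] <- if (all(is.finite(best$par)))
        fd_hessian(obj, best$par) else NULL
    }
    out_est[[bn]] <- est; out_obj[[bn]] <- val
    out_conv[[bn]] <- conv; out_hess[[bn]] <- hess
  }
  .as_prl_fit(method = if (is.null(prior_variance)) "ml" else "map0",
              sessions = sessions, spec = spec, prep = prep,
              est = out_est, obj = out_obj, conv = out_conv,
              hess = out_hess, prior = NULL, trace = NULL)
}

# Reshape batch results into a uniform fit object with per-session matrices.
.as_prl_fit <- function(method, sessions, spec, prep, est, obj, conv, hess,
                        prior, trace) {
  d <- .n_params(spec)
  sess <- as.character(prep$sessions)
  if (sessions == "joint") {
    joint_est <- est$joint
    est_by_sess <- lapply(seq_along(sess), function(i)
      joint_est[, ((i - 1) * d + 1):(i * d), drop = FALSE])
    names(est_by_sess) <- sess
  } else {
    est_by_sess <- est[sess]
  }
  est_native <- lapply(est_by_sess, function(m) {
    out <- transform_params(spec, m)
    rownames(out) <- rownames(m)
    out
  })
  for (m in seq_along(est_by_sess))
    colnames(est_by_sess[[m]]) <- spec$param_names
  structure(list(method = method, sessions = sessions, spec = spec,
                 session_ids = sess,
                 subjects = rownames(est_by_sess[[1]]),
                 estimates_unc = est_by_sess,
                 estimates_native = est_native,
                 estimates_joint = if (sessions == "joint") est$joint,
                 objective = obj, convergence = conv, hessians = hess,
                 prior = prior, trace = trace),
            class = "prl_fit")
}

#' @export
print.prl_fit <- function(x, ...) {
  cat("prl_fit: model ", x$spec$name, ", method ", toupper(x$method),
      ", ", x$sessions, " sessions, ", length(x$subjects), " subjects\n",
      sep = "")
  invisible(x)
}

#' Maximum-likelihood model fit
#'
#' Per subject, minimizes the negative log-likelihood in unconstrained
#' parameter space from `n_restarts` random standard-normal starting points
#' (quasi-Newton BFGS with numerical gradients), optionally repeating the
#' whole procedure `n_repeats` times and keeping the best run. With
#' `sessions = "joint"` both sessions are concatenated with separate
#' per-session parameters and a value reset at the session boundary; for ML
#' (and MAP0) the joint objective has no cross-session coupling, so joint
#' and separate estimates coincide up to optimizer tolerance.
#'
#' @param data cohort trial table (see [read_trials()] for the schema).
#' @param spec a `prl_model`.
#' @param sessions `"separate"` or `"joint"`.
#' @param n_restarts random restarts per optimization.
#' @param n_repeats outer repetitions of the whole procedure; the run with
#'   the best objective is kept.
#' @param seed optional integer seed.
#' @param first_trial see [choice_probabilities()].
#' @param control passed to [stats::optim()].
#' @return a `prl_fit`: per-session matrices of unconstrained and native
#'   estimates, per-subject objective values, convergence codes and Hessians
#'   of the objective at the optimum.
#' @export
fit_ml <- function(data, spec, sessions = "separate", n_restarts = 10,
                   n_repeats = 10, seed = NULL, first_trial = "win",
                   control = list(maxit = 500)) {
  .fit_point(data, spec, sessions, NULL, n_restarts, n_repeats, seed,
             first_trial, control)
}

#' MAP fit with an uninformative Gaussian prior
#'
#' As [fit_ml()], with an independent Gaussian prior of mean 0 and variance
#' `prior_variance` (default 10) on every unconstrained parameter, i.e. the
#' objective is `NLL + sum(theta^2) / (2 * prior_variance)`.
#'
#' @inheritParams fit_ml
#' @param prior_variance prior variance in unconstrained space.
#' @return a `prl_fit`.
#' @export
fit_map0 <- function(data, spec, sessions = "separate", prior_variance = 10,
                     n_restarts = 10, n_repeats = 10, seed = NULL,
                     first_trial = "win", control = list(maxit = 500)) {
  .assert(prior_variance > 0, "prior_variance must be positive")
  .fit_point(data, spec, sessions, prior_variance, n_restarts, n_repeats,
             seed, first_trial, control)
}

# ---- EM-MAP -----------------------------------------------------------------

.em_core <- function(units, d, spec_like, max_iter, tol, n_restarts,
                     control, first_trial) {
  n <- length(units)
  nlls <- lapply(units, .unit_nll, spec = spec_like,
                 first_trial = first_trial)
  mu <- rep(0, d)
  Sigma <- diag(10, d)
  est <- matrix(NA_real_, n, d, dimnames = list(names(units), NULL))
  hess <- vector("list", n)
  conv <- rep(99L, n)
  warm <- NULL
  trace <- numeric(0)
  prev_ll <- -Inf
  converged <- FALSE
  flagged <- logical(n)

  for (it in seq_len(max_iter)) {
    Sinv <- chol2inv(chol(Sigma))
    ldS <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
    vals <- numeric(n)
    for (i in seq_len(n)) {
      nll_i <- nlls[[i]]
      obj <- function(par) {
        dv <- par - mu
        nll_i(par) + 0.5 * sum(dv * (Sinv %*% dv))
      }
      n_rand <- max(n_restarts - !is.null(warm), 1L)
      starts <- MASS::mvrnorm(n_rand, mu, Sigma)
      if (n_rand == 1) starts <- matrix(starts, 1)
      if (!is.null(warm)) starts <- rbind(warm[i, ], starts)
      r <- .optimize_unit(obj, starts, control)
      est[i, ] <- r$par; vals[i] <- r$value; conv[i] <- r$convergence
      H <- fd_hessian(obj, r$par)
      pd <- .make_pd(H)
      hess[[i]] <- pd$M
      flagged[i] <- flagged[i] || pd$flagged
    }
    ll <- sum(-vals) - n * 0.5 * (ldS + d * log(2 * pi))
    trace <- c(trace, ll)
    if (it > 1 && abs(ll - prev_ll) < tol) { converged <- TRUE; break }
    prev_ll <- ll
    # M-step: group moments including per-subject Laplace covariance
    mu <- colMeans(est)
    S <- matrix(0, d, d)
    for (i in seq_len(n))
      S <- S + tcrossprod(est[i, ] - mu) + chol2inv(chol(hess[[i]]))
    S <- S / n
    diag(S) <- pmax(diag(S), 1e-6)
    Sigma <- .make_pd(S)$M
    warm <- est
  }
  list(mu = mu, Sigma = Sigma, est = est, hess = hess, conv = conv,
       vals = vals, trace = trace, converged = converged,
       iterations = length(trace), flagged = flagged)
}

#' EM-MAP fit with a multivariate empirical prior
#'
#' Empirical-Bayes expectation maximization: the E-step computes per-subject
#' MAP estimates under the current multivariate Gaussian group prior (with a
#' Laplace approximation of the posterior covariance from the inverse
#' Hessian); the M-step re-estimates the prior mean as the average of the
#' MAP estimates and the full prior covariance as the across-subject second
#' moment *including* the per-subject Laplace covariances. Iteration stops
#' when the penalized group log-likelihood changes by less than `tol`.
#'
#' With `sessions = "joint"` the prior spans both sessions' parameters, so
#' cross-session covariances inform the per-subject estimates (the source of
#' the joint-estimation reliability benefit); with `"separate"` an
#' independent EM is run per session.
#'
#' @inheritParams fit_ml
#' @param max_iter maximum EM iterations.
#' @param tol convergence tolerance on the penalized group log-likelihood.
#' @param n_restarts E-step restarts (warm start from the previous estimate
#'   plus random draws from the current prior).
#' @param n_repeats outer repetitions; the repeat with the highest final
#'   penalized group log-likelihood is kept.
#' @return a `prl_fit` whose `prior` field holds the estimated group
#'   prior(s): `list(mean, cov, param_names)`, one per session for separate
#'   fits, a single prior over both sessions' parameters for joint fits.
#' @export
fit_em <- function(data, spec, sessions = "separate", max_iter = 100,
                   tol = 1e-3, n_restarts = 10, n_repeats = 10, seed = NULL,
                   first_trial = "win", control = list(maxit = 500)) {
  sessions <- match.arg(sessions, c("separate", "joint"))
  .set_seed_if(seed)
  prep <- .cohort_batches(data, sessions)
  d <- .n_params(spec)
  .assert(length(prep$batches[[1]]) >= 2,
          "EM requires at least 2 subjects")
  out_est <- list(); out_obj <- list(); out_conv <- list()
  out_hess <- list(); priors <- list(); traces <- list()
  for (bn in names(prep$batches)) {
    units <- prep$batches[[bn]]
    db <- d * length(units[[1]])
    best <- NULL
    for (rep_k in seq_len(n_repeats)) {
      r <- .em_core(units, db, spec, max_iter, tol, n_restarts, control,
                    first_trial)
      if (is.null(best) ||
          r$trace[length(r$trace)] > best$trace[length(best$trace)])
        best <- r
    }
    pn <- if (db == d) spec$param_names else
      c(paste0(spec$param_names, "_s1"), paste0(spec$param_names, "_s2"))
    dimnames(best$Sigma) <- list(pn, pn)
    out_est[[bn]] <- best$est; out_obj[[bn]] <- best$vals
    out_conv[[bn]] <- best$conv; out_hess[[bn]] <- best$hess
    priors[[bn]] <- list(mean = setNames(best$mu, pn), cov = best$Sigma,
                         param_names = pn, converged = best$converged,
                         iterations = best$iterations,
                         flagged_subjects = names(units)[best$flagged])
    traces[[bn]] <- best$trace
  }
  fit <- .as_prl_fit("em", sessions, spec, prep, out_est, out_obj, out_conv,
                     out_hess, priors, traces)
  fit
}

#' Concatenate two sessions for joint fitting
#'
#' Builds the joint dataset (session column 1/2) and the joint model
#' specification with session-tagged, doubled parameters. The joint
#' likelihood evaluates session-1 trials under the first parameter block and
#' session-2 trials under the second, with values reset at the boundary, so
#' it is exactly additive in the two separate likelihoods.
#'
#' @param session1_data,session2_data single-session cohort trial tables
#'   covering the same subjects.
#' @param spec a `prl_model`.
#' @return list with `data` (combined table) and `spec` (a
#'   `prl_model_joint` usable with [negative_log_likelihood()]).
#' @export
concat_sessions <- function(session1_data, session2_data, spec) {
  .check_cohort(session1_data); .check_cohort(session2_data)
  s1 <- unique(session1_data$subject_id)
  s2 <- unique(session2_data$subject_id)
  .assert(setequal(s1, s2), "same subjects required in both sessions")
  session1_data$session <- 1L
  session2_data$session <- 2L
  joint <- rbind(session1_data, session2_data)
  jspec <- structure(list(
    name = paste0(spec$name, "-joint"), base = spec,
    param_names = c(paste0(spec$param_names, "_s1"),
                    paste0(spec$param_names, "_s2")),
    transforms = rep(spec$transforms, 2)), class = "prl_model_joint")
  list(data = joint, spec = jspec)
}

#' Joint-session negative log-likelihood
#'
#' Evaluates a doubled (session-tagged) parameter vector on a two-session
#' dataset: block 1 on session 1, block 2 on session 2, values reset at the
#' boundary.
#'
#' @param params_unconstrained unconstrained vector of length `2 * d`.
#' @param data two-session cohort trial table for one subject.
#' @param jspec a `prl_model_joint` from [concat_sessions()].
#' @param first_trial see [choice_probabilities()].
#' @return scalar negative log-likelihood.
#' @export
negative_log_likelihood_joint <- function(params_unconstrained, data, jspec,
                                          first_trial = "win") {
  .assert(inherits(jspec, "prl_model_joint"), "jspec must be a joint spec")
  spec <- jspec$base
  d <- .n_params(spec)
  .assert(length(params_unconstrained) == 2 * d,
          "joint parameter vector must have length 2 * d")
  sess <- sort(unique(data$session))
  .assert(length(sess) == 2, "data must contain exactly 2 sessions")
  total <- 0
  for (i in 1:2) {
    blk <- params_unconstrained[((i - 1) * d + 1):(i * d)]
    total <- total +
      negative_log_likelihood(blk, data[data$session == sess[i], ], spec,
                              first_trial)
  }
  total
}

# ---- iBIC and model selection ----------------------------------------------

#' Integrated Bayesian information criterion
#'
#' Group-level model evidence: the subject-level parameters are integrated
#' out under the empirical Gaussian prior by Monte-Carlo sampling (`K` prior
#' draws, shared across subjects), and the resulting group log marginal
#' likelihood is penalized for the number of free prior parameters:
#' `iBIC = -2 * sum_i log p(data_i | mu, Sigma) + n_prior * log(N)` with `N`
#' the total number of choices. With a full covariance the prior parameter
#' count is `d + d*(d+1)/2`; `diagonal_prior = TRUE` counts `2 * d`.
#'
#' @param fit a `prl_fit` from [fit_em()] (its prior and session mode are
#'   used). For separate-session fits the per-session iBICs are summed.
#' @param data the cohort trial table the fit was computed on.
#' @param K number of Monte-Carlo prior samples (warning if `< 100`).
#' @param seed optional integer seed for the prior draws.
#' @param diagonal_prior count only diagonal covariance entries in the
#'   penalty.
#' @param first_trial see [choice_probabilities()].
#' @return scalar iBIC (lower is better).
#' @export
ibic <- function(fit, data, K = 2000, seed = NULL, diagonal_prior = FALSE,
                 first_trial = "win") {
  .assert(inherits(fit, "prl_fit") && !is.null(fit$prior),
          "ibic requires an EM fit with a group prior")
  if (K < 100) warning("K < 100 Monte-Carlo samples; iBIC will be unstable")
  .set_seed_if(seed)
  spec <- fit$spec
  d <- .n_params(spec)
  codes <- .spec_codes(spec)
  fr <- .first_rule_code(first_trial)
  prep <- .cohort_batches(data, fit$sessions)
  total <- 0
  for (bn in names(prep$batches)) {
    units <- prep$batches[[bn]]
    prior <- fit$prior[[bn]]
    db <- length(prior$mean)
    draws <- MASS::mvrnorm(K, prior$mean, prior$cov)
    to_native <- .make_transformer(rep(spec$transforms, db / d))
    nat <- t(apply(draws, 1, to_native))
    nll_k <- numeric(K)
    logp <- 0
    n_obs <- 0
    for (i in seq_along(units)) {
      nll_k[] <- 0
      for (b in seq_along(units[[i]])) {
        ch <- units[[i]][[b]]
        nll_k <- nll_k +
          nll_batch_cpp(nat[, ((b - 1) * d + 1):(b * d), drop = FALSE],
                        ch$choice, ch$reward, codes[["family"]],
                        codes[["update"]], codes[["n_lr"]],
                        codes[["n_ch"]], fr)
        n_obs <- n_obs + length(ch$choice)
      }
      logp <- logp + .logsumexp(-nll_k) - log(K)
    }
    n_prior <- if (diagonal_prior) 2 * db else db + db * (db + 1) / 2
    total <- total + (-2 * logp + n_prior * log(n_obs))
  }
  total
}

#' Rank models by iBIC
#'
#' @param ibic_values named numeric vector of iBIC values (one per model).
#' @return data.frame with `model`, `ibic` and `delta` (distance from the
#'   best model), sorted best first.
#' @examples
#' select_model(c(a = 100, b = 90, c = 95))
#' @export
select_model <- function(ibic_values) {
  .assert(length(ibic_values) >= 1, "at least one model required")
  .assert(all(is.finite(ibic_values)), "iBIC table contains NaN/NA entries")
  nm <- names(ibic_values) %||% paste0("model", seq_along(ibic_values))
  ord <- order(ibic_values)
  data.frame(model = nm[ord], ibic = unname(ibic_values[ord]),
             delta = unname(ibic_values[ord] - min(ibic_values)),
             row.names = NULL)
}

# ---- reliability of fitted parameters --------------------------------------

#' Test-retest reliability of fitted parameters
#'
#' Computes ICC(A,1), ICC(1) and the Pearson correlation between the
#' session-1 and session-2 estimates for every model parameter, plus the
#' model-calculated Pearson correlation from the joint EM prior covariance
#' when available.
#'
#' @param fit a `prl_fit` covering two sessions.
#' @param space `"unconstrained"` (default; the scale the Gaussian prior
#'   lives on) or `"native"`.
#' @return data.frame with one row per parameter.
#' @export
fit_reliability <- function(fit, space = c("unconstrained", "native")) {
  space <- match.arg(space)
  .assert(length(fit$session_ids) == 2,
          "parameter reliability requires two sessions")
  est <- if (space == "unconstrained") fit$estimates_unc else
    fit$estimates_native
  d <- .n_params(fit$spec)
  rows <- lapply(seq_len(d), function(j) {
    x <- est[[1]][, j]; y <- est[[2]][, j]
    ok <- is.finite(x) & is.finite(y)
    a1 <- icc_a1(x[ok], y[ok])
    i1 <- icc_1(x[ok], y[ok])
    r <- suppressWarnings(cor(x[ok], y[ok]))
    mp <- NA_real_
    if (fit$method == "em" && fit$sessions == "joint")
      mp <- pearson_from_prior_cov(fit$prior$joint$cov, j, d + j)
    data.frame(parameter = fit$spec$param_names[j],
               icc_a1 = a1$estimate, icc_a1_lwr = a1$lower,
               icc_a1_upr = a1$upper, icc_1 = i1$estimate,
               pearson = r, model_pearson = mp, n = sum(ok))
  })
  do.call(rbind, rows)
}
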