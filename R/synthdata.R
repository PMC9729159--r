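# Study-emulating generator: samples a subject population with controlled
# cross-session parameter correlations and produces complete two-session
# PRLT datasets (choices + reaction times).

#' Define a synthetic subject population
#'
#' The population is a multivariate Gaussian over the unconstrained model
#' parameters of both sessions. Its covariance is assembled from per-
#' parameter SDs, a within-session correlation matrix, and a per-parameter
#' cross-session correlation; the defaults describe a healthy-adult-like
#' cohort for the `DU-2rho-alpha` model (reinforcement sensitivities around
#' 3 and 2, learning rate around 0.5, cross-session correlation 0.7) whose
#' simulated accuracies land in a plausible range. These are fixture
#' constants of the generator, not empirical claims.
#'
#' Reaction times are generated by a purely descriptive process (the choice
#' models carry no RT likelihood): a subject-level intercept, a shift after
#' win feedback (negative = faster after wins), and Gaussian trial noise,
#' truncated to (150, 1500] ms.
#'
#' @param model a `prl_model` (default `DU-2rho-alpha`).
#' @param mean_unc named population means in unconstrained space.
#' @param sd_unc population SDs in unconstrained space.
#' @param cross_session_r cross-session correlation per parameter (scalar or
#'   vector), in (-1, 1).
#' @param within_session_cor within-session parameter correlation matrix
#'   (default identity).
#' @param session_shift_unc additive shift of the session-2 population mean
#'   (practice effect), default 0.
#' @param n_subjects cohort size (default 40).
#' @param rt list with `grand_mean`, `subject_sd`, `win_shift`, `noise_sd`
#'   (milliseconds).
#' @return object of class `prl_population`.
#' @export
population_spec <- function(model = get_model("DU-2rho-alpha"),
                            mean_unc = c(3, 2, 0),
                            sd_unc = c(1, 1, 0.8),
                            cross_session_r = 0.7,
                            within_session_cor = NULL,
                            session_shift_unc = 0,
                            n_subjects = 40,
                            rt = list(grand_mean = 700, subject_sd = 100,
                                      win_shift = -22, noise_sd = 150)) {
  d <- .n_params(model)
  .assert(length(mean_unc) == d && length(sd_unc) == d,
          "mean_unc and sd_unc must match the model's parameter count")
  .assert(all(sd_unc >= 0), "sd_unc must be non-negative")
  r <- rep_len(cross_session_r, d)
  .assert(all(r > -1 & r < 1), "cross_session_r must be in (-1, 1)")
  Rw <- within_session_cor %||% diag(d)
  .assert(all(dim(Rw) == c(d, d)), "within_session_cor must be d x d")
  shift <- rep_len(session_shift_unc, d)
  Rc <- diag(r, d)
  R <- rbind(cbind(Rw, Rc), cbind(Rc, Rw))
  D <- diag(rep(sd_unc, 2), 2 * d)
  Sigma <- D %*% R %*% D
  ev <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  .assert(min(ev) > -1e-10 * max(abs(ev), 1),
          "implied population covariance is not positive semi-definite")
  structure(list(model = model,
                 mean_unc = setNames(as.numeric(mean_unc),
                                     model$param_names),
                 sd_unc = setNames(as.numeric(sd_unc), model$param_names),
                 cross_session_r = r, within_session_cor = Rw,
                 session_shift_unc = shift, n_subjects = n_subjects,
                 rt = rt, Sigma = Sigma), class = "prl_population")
}

#' @export
print.prl_population <- function(x, ...) {
  cat("synthetic population: model ", x$model$name, ", ", x$n_subjects,
      " subjects, cross-session r = ",
      paste(round(x$cross_session_r, 2), collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Draw per-subject, per-session parameters from a population
#'
#' Samples from the 2d-dimensional Gaussian over (session 1, session 2)
#' unconstrained parameters.
#'
#' @param pop a `prl_population`.
#' @param n number of subjects (default `pop$n_subjects`).
#' @param seed optional integer seed.
#' @return list with `unconstrained` and `native`, each a list of two
#'   n-by-d matrices (`s1`, `s2`), rows named by subject id.
#' @export
sample_population_params <- function(pop, n = pop$n_subjects,
                                     seed = NULL) {
  .set_seed_if(seed)
  d <- .n_params(pop$model)
  mu <- c(pop$mean_unc, pop$mean_unc + pop$session_shift_unc)
  draws <- MASS::mvrnorm(n, mu, pop$Sigma)
  if (n == 1) draws <- matrix(draws, 1)
  ids <- sprintf("S%03d", seq_len(n))
  s1 <- draws[, seq_len(d), drop = FALSE]
  s2 <- draws[, d + seq_len(d), drop = FALSE]
  dimnames(s1) <- dimnames(s2) <- list(ids, pop$model$param_names)
  nat <- lapply(list(s1 = s1, s2 = s2), function(m) {
    out <- transform_params(pop$model, m)
    rownames(out) <- ids
    out
  })
  list(unconstrained = list(s1 = s1, s2 = s2), native = nat)
}

#' Generate a complete two-session synthetic study
#'
#' For each subject and session, an agent with that subject's parameters
#' plays the scheduled task (choices and feedback from the closed generative
#' loop); task versions alternate across subjects so version order is
#' counterbalanced; reaction times follow the population's descriptive RT
#' process (faster after wins).
#'
#' @param pop a `prl_population`.
#' @param schedules list of two `prl_schedule`s (the counterbalanced task
#'   versions); defaults to version "A" and "B" of the standard design.
#' @param seed optional integer seed; a fixed seed reproduces the dataset
#'   exactly.
#' @return long-format cohort trial table with columns `subject_id`,
#'   `session`, `trial`, `choice`, `correct_option`, `feedback`, `rt_ms`,
#'   `version_id`. The drawn per-subject parameters are attached as
#'   attribute `"true_params"` (list `s1`, `s2`, unconstrained space).
#' @export
generate_study <- function(pop, schedules = NULL, seed = NULL) {
  .set_seed_if(seed)
  schedules <- schedules %||% list(build_schedule(version_id = "A"),
                                   build_schedule(version_id = "B"))
  .assert(length(schedules) == 2, "two task versions required")
  pars <- sample_population_params(pop, pop$n_subjects)
  ids <- rownames(pars$native$s1)
  rtp <- pop$rt
  rows <- vector("list", 2 * length(ids))
  k <- 0
  for (i in seq_along(ids)) {
    intercept <- rnorm(1, rtp$grand_mean, rtp$subject_sd)
    order_ab <- if ((i - 1) %% 2 == 0) c(1, 2) else c(2, 1)
    for (s in 1:2) {
      sched <- schedules[[order_ab[s]]]
      df <- simulate_agent(pars$native[[s]][i, ], pop$model, sched)
      prev_win <- c(0, as.numeric(df$feedback[-nrow(df)] == 1))
      rt <- intercept + rtp$win_shift * prev_win +
        rnorm(nrow(df), 0, rtp$noise_sd)
      df$rt_ms <- pmin(pmax(rt, 151), 1500)
      df$subject_id <- ids[i]
      df$session <- s
      df$version_id <- sched$version_id
      k <- k + 1
      rows[[k]] <- df[c("subject_id", "session", "trial", "choice",
                        "correct_option", "feedback", "rt_ms",
                        "version_id")]
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "true_params") <- pars$unconstrained
  attr(out, "population") <- pop
  out
}
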