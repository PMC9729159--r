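#' Enumerate the reinforcement-learning model space
#'
#' The model space crosses two families with three update rules and
#' win/loss-specific parameterizations:
#' \itemize{
#'   \item family `"softmax"`: values are learned from the raw reward
#'     (+1/-1) and mapped to choice probabilities through a softmax with
#'     inverse temperature beta (one shared, or separate beta for trials
#'     following wins vs. losses);
#'   \item family `"rho"`: the reward is scaled by a reinforcement
#'     sensitivity rho (shared, or win/loss-specific) inside the update and
#'     the softmax slope is fixed at 1, so choice stochasticity is carried by
#'     the bounded value difference instead of a temperature.
#' }
#' Update rules: `SU` (single update, unchosen option untouched), `DU`
#' (double update, the unchosen option receives the mirrored outcome `-r`),
#' and `DU` with an attenuation weight kappa on the counterfactual update.
#' Crossing update rule (SU, DU, DU+kappa) with 1 vs. 2 learning rates and
#' 1 vs. 2 choice parameters yields 12 models per family, 24 in total.
#'
#' Canonical names concatenate the pieces, e.g. `"SU-beta-alpha"`,
#' `"DU-2rho-alpha"`, `"DU-2beta-2alpha-kappa"`.
#'
#' @param families subset of `c("softmax", "rho")`.
#' @return list of `prl_model` objects in a deterministic canonical order.
#' @examples
#' length(enumerate_models())                 # 24
#' length(enumerate_models("rho"))            # 12
#' get_model("DU-2rho-alpha")$param_names     # rho_win, rho_loss, alpha
#' @export
enumerate_models <- function(families = c("softmax", "rho")) {
  .assert(length(families) >= 1, "at least one family required")
  .assert(all(families %in% c("softmax", "rho")),
          "families must be a subset of {softmax, rho}")
  out <- list()
  for (fam in families) {
    for (update in c("SU", "DU", "DUk")) {
      for (n_ch in 1:2) {
        for (n_lr in 1:2) {
          out[[length(out) + 1L]] <- .make_model(fam, update, n_lr, n_ch)
        }
      }
    }
  }
  out
}

.make_model <- function(family, update, n_lr, n_ch) {
  ch <- if (family == "softmax") "beta" else "rho"
  ch_names <- if (n_ch == 1) ch else paste0(ch, c("_win", "_loss"))
  lr_names <- if (n_lr == 1) "alpha" else c("alpha_win", "alpha_loss")
  param_names <- c(ch_names, lr_names, if (update == "DUk") "kappa")
  # transforms map unconstrained -> native space
  ch_tr <- if (family == "rho" && n_ch == 2) "identity" else "exp"
  transforms <- c(rep(ch_tr, n_ch), rep("logit", n_lr),
                  if (update == "DUk") "logit")
  name <- paste(c(if (update == "SU") "SU" else "DU",
                  if (n_ch == 1) ch else paste0("2", ch),
                  if (n_lr == 1) "alpha" else "2alpha",
                  if (update == "DUk") "kappa"),
                collapse = "-")
  structure(list(name = name, family = family, update = update,
                 n_learning_rates = n_lr, n_choice_params = n_ch,
                 param_names = param_names, transforms = transforms),
            class = "prl_model")
}

#' Look up a model by canonical name
#'
#' @param name canonical model name, e.g. `"DU-2rho-alpha"`.
#' @return a `prl_model`.
#' @export
get_model <- function(name) {
  models <- enumerate_models()
  idx <- match(name, vapply(models, `[[`, "", "name"))
  .assert(!is.na(idx), paste0("unknown model name: ", name))
  models[[idx]]
}

#' @export
print.prl_model <- function(x, ...) {
  cat("model ", x$name, " (", x$family, " family, ", x$update, ")\n",
      "parameters: ", paste(x$param_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

.n_params <- function(spec) length(spec$param_names)

.spec_codes <- function(spec) {
  c(family = if (spec$family == "softmax") 0L else 1L,
    update = match(spec$update, c("SU", "DU", "DUk")) - 1L,
    n_lr = spec$n_learning_rates, n_ch = spec$n_choice_params)
}

.first_rule_code <- function(first_trial) {
  match(match.arg(first_trial, c("win", "loss", "average")),
        c("win", "loss", "average")) - 1L
}

#' Map parameters between unconstrained and native space
#'
#' Learning rates and the double-update weight kappa live in (0,1) and are
#' inverse-logit transformed; inverse temperatures and a single reinforcement
#' sensitivity are positivity-constrained via an exponential transform;
#' win/loss-specific reinforcement sensitivities are fitted in native space
#' (identity), so the fitting layer must tolerate negative proposals for
#' them.
#'
#' @param spec a `prl_model`.
#' @param unconstrained,native numeric parameter vectors in the model's
#'   canonical order (or a matrix with one vector per row).
#' @return numeric vector (or matrix) in the other space, named by parameter.
#' @examples
#' m <- get_model("SU-beta-alpha")
#' transform_params(m, c(0, 0))  # beta = 1, alpha = 0.5
#' @export
transform_params <- function(spec, unconstrained) {
  tr <- spec$transforms
  if (is.matrix(unconstrained)) {
    out <- unconstrained
    for (j in seq_along(tr)) out[, j] <- .tr_one(tr[j], unconstrained[, j])
    colnames(out) <- spec$param_names
    return(out)
  }
  .assert(length(unconstrained) == length(tr),
          "parameter vector length does not match model")
  setNames(vapply(seq_along(tr),
                  function(j) .tr_one(tr[j], unconstrained[j]), 0),
           spec$param_names)
}

.tr_one <- function(tr, x) switch(tr, logit = plogis(x), exp = exp(x),
                                  identity = x)

#' @rdname transform_params
#' @export
untransform_params <- function(spec, native) {
  tr <- spec$transforms
  .assert(length(native) == length(tr),
          "parameter vector length does not match model")
  out <- numeric(length(tr))
  for (j in seq_along(tr)) {
    out[j] <- switch(tr[j],
      logit = {
        .assert(native[j] > 0 && native[j] < 1,
                "logit-transformed parameter must be in (0,1)")
        qlogis(native[j])
      },
      exp = {
        .assert(native[j] > 0, "exp-transformed parameter must be positive")
        log(native[j])
      },
      identity = native[j])
  }
  setNames(out, spec$param_names)
}

.native_params <- function(spec, params) {
  # accept a named or ordered native vector
  .assert(length(params) == .n_params(spec),
          "parameter vector length does not match model")
  if (!is.null(names(params)) && all(spec$param_names %in% names(params)))
    params <- params[spec$param_names]
  unname(params)
}

#' One Q-learning value update
#'
#' Applies the model's update rule to a pair of expected values after one
#' trial. The chosen option moves toward the (possibly rho-scaled) reward by
#' a fraction alpha (or alpha_win/alpha_loss, selected by the sign of the
#' feedback); under double updating the unchosen option moves toward the
#' mirrored outcome, attenuated by kappa when present.
#'
#' @param Q numeric length-2 vector of expected values.
#' @param choice chosen option, 0 or 1.
#' @param r feedback, +1 or -1.
#' @param params native-space parameter vector (canonical order or named).
#' @param spec a `prl_model`.
#' @return updated length-2 value vector.
#' @examples
#' update_values(c(0, 0), 0, 1, c(beta = 1, alpha = 0.5),
#'               get_model("SU-beta-alpha"))   # c(0.5, 0)
#' @export
update_values <- function(Q, choice, r, params, spec) {
  .assert(length(Q) == 2 && all(is.finite(Q)), "Q must be 2 finite values")
  .assert(choice %in% c(0L, 1L), "choice must be 0 or 1")
  .assert(r %in% c(-1, 1), "feedback must be +1 or -1")
  p <- .native_params(spec, params)
  .assert(all(is.finite(p)), "non-finite parameters")
  n_ch <- spec$n_choice_params
  ch_win <- p[1]; ch_loss <- if (n_ch == 2) p[2] else p[1]
  a_win <- p[n_ch + 1]
  a_loss <- if (spec$n_learning_rates == 2) p[n_ch + 2] else a_win
  kappa <- if (spec$update == "DUk") p[length(p)] else 1

  a <- if (spec$n_learning_rates == 1) a_win else if (r > 0) a_win else a_loss
  rs <- if (spec$family == "rho") {
    rho <- if (n_ch == 1) ch_win else if (r > 0) ch_win else ch_loss
    rho * r
  } else r

  ci <- choice + 1L; ui <- 2L - choice
  Q[ci] <- Q[ci] + a * (rs - Q[ci])
  if (spec$update %in% c("DU", "DUk")) {
    w <- if (spec$update == "DUk") kappa else 1
    Q[ui] <- Q[ui] + w * a * ((-rs) - Q[ui])
  }
  Q
}

#' Softmax choice probabilities
#'
#' Maps a pair of expected values to choice probabilities. In the softmax
#' family the slope is beta (or beta_win/beta_loss selected by the previous
#' trial's feedback); in the rho family the slope is fixed at 1 because
#' stochasticity is carried by the rho-scaled values. Computed in the
#' overflow-safe max-subtracted form.
#'
#' @param Q numeric length-2 value vector.
#' @param prev_feedback previous trial's feedback (+1/-1) or `NA` on the
#'   first trial of a session.
#' @param params native-space parameter vector.
#' @param spec a `prl_model`.
#' @param first_trial rule for selecting among win/loss choice parameters on
#'   a first trial: `"win"` (default), `"loss"` or `"average"`.
#' @return numeric length-2 probability vector summing to 1.
#' @export
choice_probabilities <- function(Q, prev_feedback, params, spec,
                                 first_trial = "win") {
  .assert(length(Q) == 2 && all(is.finite(Q)), "Q must be 2 finite values")
  p <- .native_params(spec, params)
  b <- 1
  if (spec$family == "softmax") {
    if (spec$n_choice_params == 1) b <- p[1]
    else if (is.na(prev_feedback)) {
      b <- switch(match.arg(first_trial, c("win", "loss", "average")),
                  win = p[1], loss = p[2], average = (p[1] + p[2]) / 2)
    } else b <- if (prev_feedback > 0) p[1] else p[2]
  }
  z <- b * Q
  z <- z - max(z)
  ez <- exp(z)
  ez / sum(ez)
}

#' Negative log-likelihood of a trial sequence
#'
#' Evaluates `-sum(log p(choice_t))` under a model, with values initialized
#' to zero at the start of each session (a `session` column, if present,
#' defines the reset points). The parameter vector is given in unconstrained
#' space, as used by the optimizers.
#'
#' @param params_unconstrained unconstrained parameter vector.
#' @param data data.frame with `choice` (0/1) and `feedback` (+1/-1)
#'   columns, chronologically ordered; optional `session` column.
#' @param spec a `prl_model`.
#' @param first_trial see [choice_probabilities()].
#' @return scalar negative log-likelihood (0 for an empty trial list).
#' @export
negative_log_likelihood <- function(params_unconstrained, data, spec,
                                    first_trial = "win") {
  .assert(all(is.finite(params_unconstrained)), "non-finite parameters")
  if (nrow(data) == 0) return(0)
  .assert(all(data$choice %in% c(0L, 1L)), "choice must be coded 0/1")
  .assert(all(data$feedback %in% c(-1, 1)), "feedback must be coded +1/-1")
  nat <- unname(transform_params(spec, params_unconstrained))
  codes <- .spec_codes(spec)
  fr <- .first_rule_code(first_trial)
  chunks <- if (is.null(data$session)) list(data) else
    split(data, data$session)
  total <- 0
  for (ch in chunks) {
    total <- total + nll_session_cpp(nat, as.integer(ch$choice),
                                     as.numeric(ch$feedback),
                                     codes[["family"]], codes[["update"]],
                                     codes[["n_lr"]], codes[["n_ch"]], fr)
  }
  total
}

#' Simulate an agent playing a schedule
#'
#' Runs the closed generative loop: choices are sampled from the model's
#' choice probabilities, feedback from the schedule's contingencies, and
#' values are updated trial by trial.
#'
#' @param params native-space parameter vector.
#' @param spec a `prl_model`.
#' @param schedule a `prl_schedule`.
#' @param seed optional integer seed for reproducibility.
#' @param first_trial see [choice_probabilities()].
#' @return data.frame with columns `trial`, `choice`, `correct_option`,
#'   `feedback`, `rt_ms` (all `NA`; the choice models carry no response-time
#'   process).
#' @export
simulate_agent <- function(params, spec, schedule, seed = NULL,
                           first_trial = "win") {
  .set_seed_if(seed)
  p <- .native_params(spec, params)
  n <- schedule$n_trials
  choice <- integer(n); feedback <- numeric(n)
  Q <- c(0, 0); prev <- NA_real_
  for (t in seq_len(n)) {
    pr <- choice_probabilities(Q, prev, p, spec, first_trial)
    choice[t] <- if (runif(1) < pr[2]) 1L else 0L
    feedback[t] <- sample_feedback(schedule, t, choice[t])
    Q <- update_values(Q, choice[t], feedback[t], p, spec)
    prev <- feedback[t]
  }
  data.frame(trial = seq_len(n), choice = choice,
             correct_option = schedule$good_option,
             feedback = feedback, rt_ms = NA_real_)
}
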