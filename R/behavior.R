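# Behavioral metrics: raw proportions/means per subject-session and shrunken
# predicted values from mixed-effects (lme4) models, split-half partitioning,
# and chance-level exclusion.

# Annotate a cohort table with derived per-trial indicators, computed within
# each subject-session in trial order.
.annotate_trials <- function(data) {
  .check_cohort(data)
  data <- data[order(data$subject_id, data$session, data$trial), ]
  grp <- interaction(data$subject_id, data$session, drop = TRUE)
  out <- do.call(rbind, unname(lapply(split(data, grp), function(df) {
    n <- nrow(df)
    df$correct <- as.integer(df$choice == df$correct_option)
    df$prev_feedback <- c(NA, df$feedback[-n])
    df$stay <- c(NA, as.integer(df$choice[-1] == df$choice[-n]))
    # perseveration window: previous two trials were the same incorrect
    # option with loss feedback on both; event = repeating that option
    pw <- rep(NA_integer_, n)
    if (n >= 3) for (t in 3:n) {
      if (df$choice[t - 1] == df$choice[t - 2] &&
          df$feedback[t - 1] == -1 && df$feedback[t - 2] == -1 &&
          df$choice[t - 1] != df$correct_option[t - 1] &&
          df$choice[t - 2] != df$correct_option[t - 2])
        pw[t] <- as.integer(df$choice[t] == df$choice[t - 1])
    }
    df$persev <- pw
    df
  })))
  rownames(out) <- NULL
  out
}

.mean_or_na <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0) NA_real_ else mean(v)
}

#' Raw behavioral metrics for one session
#'
#' Computes the task's outcome variables as simple proportions and means:
#' accuracy (choices of the currently better option, regardless of realized
#' feedback), stay probabilities (overall and conditioned on the previous
#' trial's feedback), perseveration (repeating the same incorrect option
#' after two consecutive losses on it), and reaction-time summaries
#' (overall, after wins, after losses, and their difference). Metrics whose
#' conditioning set is empty are `NA`, never 0/0.
#'
#' @param data one subject-session's trials (>= 3 rows), with columns
#'   `trial`, `choice`, `correct_option`, `feedback` and optionally `rt_ms`.
#' @return one-row data.frame with fields `accuracy`, `stay_overall`,
#'   `stay_after_win`, `stay_after_loss`, `perseveration`, `rt_mean`,
#'   `rt_after_win`, `rt_after_loss`, `delta_rt`.
#' @export
compute_raw_metrics <- function(data) {
  .assert(nrow(data) >= 3, "need at least 3 trials")
  df <- data
  if (is.null(df$subject_id)) df$subject_id <- "s"
  if (is.null(df$session)) df$session <- 1L
  .assert(length(unique(df$subject_id)) == 1 &&
            length(unique(df$session)) == 1,
          "compute_raw_metrics expects a single subject-session")
  ann <- .annotate_trials(df)
  rt <- if (is.null(ann$rt_ms)) rep(NA_real_, nrow(ann)) else ann$rt_ms
  win_prev <- !is.na(ann$prev_feedback) & ann$prev_feedback == 1
  loss_prev <- !is.na(ann$prev_feedback) & ann$prev_feedback == -1
  rt_win <- .mean_or_na(rt[win_prev])
  rt_loss <- .mean_or_na(rt[loss_prev])
  data.frame(
    accuracy = mean(ann$correct),
    stay_overall = .mean_or_na(ann$stay),
    stay_after_win = .mean_or_na(ann$stay[win_prev]),
    stay_after_loss = .mean_or_na(ann$stay[loss_prev]),
    perseveration = .mean_or_na(ann$persev),
    rt_mean = .mean_or_na(rt),
    rt_after_win = rt_win,
    rt_after_loss = rt_loss,
    delta_rt = rt_win - rt_loss)
}

#' Raw metrics for every subject-session in a cohort
#'
#' @param data cohort trial table.
#' @return data.frame with `subject_id`, `session` and the metric columns of
#'   [compute_raw_metrics()].
#' @export
cohort_metrics <- function(data) {
  .check_cohort(data)
  grp <- unique(data[c("subject_id", "session")])
  grp <- grp[order(grp$subject_id, grp$session), ]
  rows <- lapply(seq_len(nrow(grp)), function(i) {
    df <- data[data$subject_id == grp$subject_id[i] &
                 data$session == grp$session[i], ]
    cbind(grp[i, , drop = FALSE], compute_raw_metrics(df))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Split trials into odd and even halves
#'
#' Deterministic partition by 1-based trial index (odd = trials 1, 3, 5,
#' ...), for split-half internal-consistency estimation; each half can then
#' be processed by the same metric pipeline.
#'
#' @param data trial table (single session or cohort).
#' @return list with elements `odd` and `even`.
#' @export
split_half <- function(data) {
  .assert(nrow(data) >= 4, "need at least 4 trials to split")
  list(odd = data[data$trial %% 2 == 1, , drop = FALSE],
       even = data[data$trial %% 2 == 0, , drop = FALSE])
}

#' Split-half internal consistency of the raw metrics
#'
#' Re-computes the raw metrics on the odd and even trials of each session
#' and correlates them across subjects, reporting Pearson correlations with
#' and without Spearman-Brown correction.
#'
#' @param data cohort trial table.
#' @return data.frame with one row per session and metric: `r`, `r_lwr`,
#'   `r_upr`, `r_sb`, `n`.
#' @export
internal_consistency <- function(data) {
  .check_cohort(data)
  halves <- split_half(data)
  m_odd <- cohort_metrics(halves$odd)
  m_even <- cohort_metrics(halves$even)
  metrics <- setdiff(names(m_odd), c("subject_id", "session"))
  rows <- list()
  for (s in sort(unique(data$session))) {
    o <- m_odd[m_odd$session == s, ]
    e <- m_even[m_even$session == s, ]
    e <- e[match(o$subject_id, e$subject_id), ]
    for (met in metrics) {
      ok <- is.finite(o[[met]]) & is.finite(e[[met]])
      if (sum(ok) < 4) next
      ct <- suppressWarnings(cor.test(o[[met]][ok], e[[met]][ok]))
      r <- unname(ct$estimate)
      rows[[length(rows) + 1]] <- data.frame(
        session = s, metric = met, r = r,
        r_lwr = ct$conf.int[1], r_upr = ct$conf.int[2],
        r_sb = if (r > -1) spearman_brown(r) else NA_real_, n = sum(ok))
    }
  }
  do.call(rbind, rows)
}

#' Exclude chance-level performers
#'
#' A subject is excluded when, in at least one session, (a) a two-sided
#' binomial test cannot reject chance-level (50%) accuracy at level `alpha`,
#' and (b) the subject's accuracy deviates more than `sd_threshold` standard
#' deviations from the mean of the remaining (non-chance) cohort in that
#' session. Both criteria are reported per subject.
#'
#' @param data cohort trial table.
#' @param alpha significance level of the binomial test.
#' @param sd_threshold standard-deviation cutoff.
#' @return list with `kept` and `excluded` subject ids, `report` (one row
#'   per subject-session) and `data` (the cohort restricted to kept
#'   subjects).
#' @export
exclude_chance_performers <- function(data, alpha = 0.05,
                                      sd_threshold = 3) {
  ann <- .annotate_trials(data)
  agg <- aggregate(correct ~ subject_id + session, ann,
                   function(v) c(sum(v), length(v)))
  rep_df <- data.frame(subject_id = agg$subject_id, session = agg$session,
                       n_correct = agg$correct[, 1],
                       n_trials = agg$correct[, 2])
  rep_df$accuracy <- rep_df$n_correct / rep_df$n_trials
  rep_df$p_binomial <- vapply(seq_len(nrow(rep_df)), function(i)
    binom.test(rep_df$n_correct[i], rep_df$n_trials[i], 0.5)$p.value, 0)
  rep_df$at_chance <- rep_df$p_binomial > alpha
  chance_subj <- unique(rep_df$subject_id[rep_df$at_chance])
  ref <- rep_df[!(rep_df$subject_id %in% chance_subj), ]
  rep_df$deviates <- FALSE
  for (s in unique(rep_df$session)) {
    r <- ref[ref$session == s, ]
    if (nrow(r) < 2) next
    mu <- mean(r$accuracy); sdv <- sd(r$accuracy)
    idx <- rep_df$session == s
    rep_df$deviates[idx] <- abs(rep_df$accuracy[idx] - mu) >
      sd_threshold * sdv
  }
  rep_df$exclude <- rep_df$at_chance & rep_df$deviates
  excl <- sort(unique(rep_df$subject_id[rep_df$exclude]))
  kept <- sort(setdiff(unique(rep_df$subject_id), excl))
  list(kept = kept, excluded = excl, report = rep_df,
       data = data[!(data$subject_id %in% excl), , drop = FALSE])
}

# ---- hierarchical (mixed-effects) metric estimation ------------------------

.conv_fit <- function(formulas, fitter, df, label) {
  for (i in seq_along(formulas)) {
    m <- tryCatch(suppressMessages(fitter(as.formula(formulas[i]), df)),
                  error = function(e) NULL)
    if (!is.null(m)) {
      if (i > 1)
        warning(sprintf("%s: fell back to simplified random effects (%s)",
                        label, formulas[i]), call. = FALSE)
      return(list(model = m, formula = formulas[i], fallback = i > 1))
    }
  }
  stop(sprintf("%s: no mixed-effects structure converged", label),
       call. = FALSE)
}

.vc_component <- function(m, group, term = "(Intercept)") {
  vc <- lme4::VarCorr(m)
  # lme4 suffixes duplicated grouping factors (".1"); prefer exact names
  hit <- names(vc)[names(vc) == group]
  if (length(hit) == 0)
    hit <- grep(paste0("^", group, "(\\.[0-9]+)?$"), names(vc),
                value = TRUE)
  if (length(hit) == 0) return(0)
  block <- vc[[hit[1]]]
  if (term %in% rownames(block)) block[term, term] else 0
}

# outcome builder: returns trial-level data.frame(subject_id, session, y[,x])
.metric_trials <- function(data, metric) {
  ann <- .annotate_trials(data)
  rt <- if (is.null(ann$rt_ms)) rep(NA_real_, nrow(ann)) else ann$rt_ms
  base <- data.frame(subject_id = factor(ann$subject_id),
                     session = factor(ann$session))
  win_prev <- !is.na(ann$prev_feedback) & ann$prev_feedback == 1
  loss_prev <- !is.na(ann$prev_feedback) & ann$prev_feedback == -1
  switch(metric,
    accuracy = cbind(base, y = ann$correct, kind = "binary"),
    stay = cbind(base, y = ann$stay, kind = "binary"),
    stay_win = cbind(base[win_prev, ], y = ann$stay[win_prev],
                     kind = "binary"),
    stay_loss = cbind(base[loss_prev, ], y = ann$stay[loss_prev],
                      kind = "binary"),
    perseveration = cbind(base, y = ann$persev, kind = "binary"),
    rt = cbind(base, y = rt, kind = "gaussian"),
    rt_win = cbind(base[win_prev, ], y = rt[win_prev], kind = "gaussian"),
    rt_loss = cbind(base[loss_prev, ], y = rt[loss_prev],
                    kind = "gaussian"),
    delta_rt = {
      keep <- (win_prev | loss_prev) & !is.na(rt)
      cbind(base[keep, ], y = rt[keep],
            prev_win = as.numeric(win_prev[keep]), kind = "delta")
    },
    stop("unknown metric: ", metric))
}

.agg_binomial <- function(df) {
  df <- df[!is.na(df$y), ]
  agg <- aggregate(y ~ subject_id + session, df,
                   function(v) c(sum(v), length(v)))
  data.frame(subject_id = agg$subject_id, session = agg$session,
             succ = agg$y[, 1], tot = agg$y[, 2])
}

#' Hierarchical (mixed-effects) estimation of a behavioral metric
#'
#' Fits the metric's trial-level outcome with lme4 and returns shrunken
#' per-subject(-session) predicted values on the response scale together
#' with the model's variance components. In `"joint"` mode a single model
#' covers both sessions with session nested within subject
#' (`~ 1 + (1 | subject/session)`); in `"separate"` mode one model per
#' session is fit with a subject random intercept. Binary metrics are fit as
#' aggregated binomial counts (identical likelihood to trial-level
#' Bernoulli); reaction-time metrics as Gaussian trial-level models. The
#' win-loss reaction-time difference is fit with a previous-feedback factor
#' and (maximal) random slopes; on convergence failure the random-effects
#' structure is simplified with a warning.
#'
#' @param data cohort trial table.
#' @param metric one of `"accuracy"`, `"stay"`, `"stay_win"`,
#'   `"stay_loss"`, `"perseveration"`, `"rt"`, `"rt_win"`, `"rt_loss"`,
#'   `"delta_rt"`.
#' @param mode `"joint"` or `"separate"`.
#' @return list with `predicted` (data.frame `subject_id`, `session`,
#'   `value`), `varcomp` (a single component list in joint mode, one per
#'   session in separate mode: `var_between`, `var_session`,
#'   `var_residual`), `mode`, `metric`, and `fallback` flag.
#' @export
fit_hierarchical_metric <- function(data, metric,
                                    mode = c("joint", "separate")) {
  mode <- match.arg(mode)
  df <- .metric_trials(data, metric)
  kind <- df$kind[1]
  label <- paste0(metric, " (", mode, ")")
  if (kind == "binary") {
    agg <- .agg_binomial(df)
    fitter <- function(f, d) lme4::glmer(f, data = d, family = binomial())
    if (mode == "joint") {
      fits <- .conv_fit(c(
        "cbind(succ, tot - succ) ~ 1 + (1 | subject_id/session)",
        "cbind(succ, tot - succ) ~ 1 + (1 | subject_id)"),
        fitter, agg, label)
      pred <- data.frame(subject_id = as.character(agg$subject_id),
                         session = as.character(agg$session),
                         value = predict(fits$model, type = "response"))
      vc <- list(var_between = .vc_component(fits$model, "subject_id"),
                 var_session = .vc_component(fits$model, "session:subject_id"),
                 var_residual = pi^2 / 3)
      return(list(predicted = pred, varcomp = vc, metric = metric,
                  mode = mode, fallback = fits$fallback,
                  model = fits$model))
    }
    preds <- list(); vcs <- list(); fb <- FALSE
    for (s in levels(droplevels(agg$session))) {
      a <- droplevels(agg[agg$session == s, ])
      fits <- .conv_fit("cbind(succ, tot - succ) ~ 1 + (1 | subject_id)",
                        fitter, a, label)
      preds[[s]] <- data.frame(subject_id = as.character(a$subject_id),
                               session = s,
                               value = predict(fits$model,
                                               type = "response"))
      vcs[[s]] <- list(var_between = .vc_component(fits$model, "subject_id"),
                       var_session = NA_real_, var_residual = pi^2 / 3)
      fb <- fb || fits$fallback
    }
    return(list(predicted = do.call(rbind, unname(preds)), varcomp = vcs,
                metric = metric, mode = mode, fallback = fb))
  }

  df <- df[!is.na(df$y), ]
  fitter <- function(f, d)
    lme4::lmer(f, data = d, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular =
                                             "ignore"))
  if (kind == "gaussian") {
    if (mode == "joint") {
      fits <- .conv_fit(c("y ~ 1 + (1 | subject_id/session)",
                          "y ~ 1 + (1 | subject_id)"), fitter, df, label)
      nd <- unique(df[c("subject_id", "session")])
      pred <- data.frame(subject_id = as.character(nd$subject_id),
                         session = as.character(nd$session),
                         value = predict(fits$model, newdata = nd))
      vc <- list(var_between = .vc_component(fits$model, "subject_id"),
                 var_session = .vc_component(fits$model, "session:subject_id"),
                 var_residual = stats::sigma(fits$model)^2)
      return(list(predicted = pred, varcomp = vc, metric = metric,
                  mode = mode, fallback = fits$fallback,
                  model = fits$model))
    }
    preds <- list(); vcs <- list(); fb <- FALSE
    for (s in levels(droplevels(df$session))) {
      d <- droplevels(df[df$session == s, ])
      fits <- .conv_fit("y ~ 1 + (1 | subject_id)", fitter, d, label)
      nd <- unique(d[, "subject_id", drop = FALSE])
      preds[[s]] <- data.frame(subject_id = as.character(nd$subject_id),
                               session = s,
                               value = predict(fits$model, newdata = nd))
      vcs[[s]] <- list(var_between = .vc_component(fits$model, "subject_id"),
                       var_session = NA_real_,
                       var_residual = stats::sigma(fits$model)^2)
      fb <- fb || fits$fallback
    }
    return(list(predicted = do.call(rbind, unname(preds)), varcomp = vcs,
                metric = metric, mode = mode, fallback = fb))
  }

  # delta kind: previous-feedback factor with random slopes
  pred_delta <- function(m, d) {
    nd <- unique(d[c("subject_id", "session")])
    nd1 <- nd; nd1$prev_win <- 1
    nd0 <- nd; nd0$prev_win <- 0
    data.frame(subject_id = as.character(nd$subject_id),
               session = as.character(nd$session),
               value = predict(m, newdata = nd1) -
                 predict(m, newdata = nd0))
  }
  if (mode == "joint") {
    fits <- .conv_fit(c(
      "y ~ prev_win + (1 + prev_win | subject_id/session)",
      "y ~ prev_win + (1 + prev_win | subject_id) + (1 | subject_id:session)",
      "y ~ prev_win + (1 + prev_win | subject_id)"),
      fitter, df, label)
    vc <- list(var_between = .vc_component(fits$model, "subject_id",
                                           "prev_win"),
               var_session = .vc_component(fits$model, "session:subject_id",
                                           "prev_win"),
               var_residual = stats::sigma(fits$model)^2)
    return(list(predicted = pred_delta(fits$model, df), varcomp = vc,
                metric = metric, mode = mode, fallback = fits$fallback,
                model = fits$model))
  }
  preds <- list(); vcs <- list(); fb <- FALSE
  for (s in levels(droplevels(df$session))) {
    d <- droplevels(df[df$session == s, ])
    fits <- .conv_fit(c("y ~ prev_win + (1 + prev_win | subject_id)",
                        "y ~ prev_win + (1 | subject_id)"),
                      fitter, d, label)
    preds[[s]] <- pred_delta(fits$model, d)
    vcs[[s]] <- list(var_between = .vc_component(fits$model, "subject_id",
                                                 "prev_win"),
                     var_session = NA_real_,
                     var_residual = stats::sigma(fits$model)^2)
    fb <- fb || fits$fallback
  }
  list(predicted = do.call(rbind, unname(preds)), varcomp = vcs,
       metric = metric, mode = mode, fallback = fb)
}
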