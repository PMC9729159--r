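# Reliability toolbox: intraclass correlations (McGraw & Wong conventions),
# Spearman-Brown correction, model-calculated reliabilities from variance
# components, Cicchetti interpretation bins, and variance partitioning.

.icc_ms <- function(x, y) {
  n <- length(x); k <- 2
  m <- cbind(x, y)
  grand <- mean(m)
  rm_ <- rowMeans(m); cm_ <- colMeans(m)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm_ - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- max(sst - ssr - ssc, 0)
  ssw <- sum((m - rm_)^2)
  list(n = n, k = k,
       msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), msw = ssw / (n * (k - 1)))
}

#' Two-way absolute-agreement intraclass correlation, ICC(A,1)
#'
#' The two-way mixed, single-measure, absolute-agreement ICC: the
#' appropriate test-retest coefficient when time is a design factor with one
#' observation per subject and time point. A systematic session offset is
#' penalized (unlike a Pearson correlation). Confidence intervals follow the
#' F-distribution construction of the two-way agreement ICC.
#'
#' @param x,y paired per-subject values for sessions 1 and 2 (`n >= 3`).
#' @param conf_level confidence level for the interval.
#' @return object of class `prl_icc`: list with `estimate`, `lower`,
#'   `upper`, `n`, `type`, and `undefined` (TRUE when total variance is
#'   zero, in which case the estimate is `NA`).
#' @examples
#' icc_a1(c(1, 2, 3), c(2, 3, 4))$estimate  # 2/3: the offset is penalized
#' @export
icc_a1 <- function(x, y, conf_level = 0.95) {
  .assert(length(x) == length(y), "x and y must be paired")
  .assert(length(x) >= 3, "need at least 3 subjects")
  .assert(all(is.finite(x)) && all(is.finite(y)), "values must be finite")
  ms <- .icc_ms(x, y)
  tot_var <- ms$msr + ms$msc + ms$mse
  if (tot_var <= .Machine$double.eps * max(1, mean(abs(c(x, y))))^2)
    return(structure(list(estimate = NA_real_, lower = NA_real_,
                          upper = NA_real_, n = ms$n, type = "ICC(A,1)",
                          undefined = TRUE), class = "prl_icc"))
  n <- ms$n; k <- ms$k
  est <- (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse))
  alpha <- 1 - conf_level
  lower <- upper <- NA_real_
  if (ms$mse > 0 && est < 1) {
    a <- (k * est) / (n * (1 - est))
    b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
    v <- (a * ms$msc + b * ms$mse)^2 /
      ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
    fl <- suppressWarnings(qf(1 - alpha / 2, n - 1, v))
    fu <- suppressWarnings(qf(1 - alpha / 2, v, n - 1))
    lower <- n * (ms$msr - fl * ms$mse) /
      (fl * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
    upper <- n * (fu * ms$msr - ms$mse) /
      (k * ms$msc + (k * n - k - n) * ms$mse + n * fu * ms$msr)
  } else if (est >= 1) {
    lower <- upper <- 1
  }
  structure(list(estimate = est, lower = lower, upper = upper, n = n,
                 type = "ICC(A,1)", undefined = FALSE), class = "prl_icc")
}

#' One-way random-effects intraclass correlation, ICC(1)
#'
#' One-way decomposition: subjects are random, sessions are not modeled as a
#' factor, so any session effect is absorbed into within-subject variance.
#'
#' @inheritParams icc_a1
#' @return a `prl_icc`.
#' @examples
#' icc_1(c(1, 2, 3), c(2, 3, 4))$estimate  # 0.6
#' @export
icc_1 <- function(x, y, conf_level = 0.95) {
  .assert(length(x) == length(y), "x and y must be paired")
  .assert(length(x) >= 3, "need at least 3 subjects")
  .assert(all(is.finite(x)) && all(is.finite(y)), "values must be finite")
  ms <- .icc_ms(x, y)
  if (ms$msr + ms$msw <= .Machine$double.eps *
      max(1, mean(abs(c(x, y))))^2)
    return(structure(list(estimate = NA_real_, lower = NA_real_,
                          upper = NA_real_, n = ms$n, type = "ICC(1)",
                          undefined = TRUE), class = "prl_icc"))
  n <- ms$n; k <- ms$k
  est <- (ms$msr - ms$msw) / (ms$msr + (k - 1) * ms$msw)
  alpha <- 1 - conf_level
  lower <- upper <- NA_real_
  if (ms$msw > 0) {
    fobs <- ms$msr / ms$msw
    fl <- fobs / qf(1 - alpha / 2, n - 1, n * (k - 1))
    fu <- fobs * qf(1 - alpha / 2, n * (k - 1), n - 1)
    lower <- (fl - 1) / (fl + k - 1)
    upper <- (fu - 1) / (fu + k - 1)
  } else {
    lower <- upper <- 1
  }
  structure(list(estimate = est, lower = lower, upper = upper, n = n,
                 type = "ICC(1)", undefined = FALSE), class = "prl_icc")
}

#' @export
print.prl_icc <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat(x$type, ": undefined (zero total variance), n = ", x$n, "\n",
        sep = "")
  } else {
    cat(sprintf("%s = %.3f [%.3f, %.3f], n = %d\n", x$type, x$estimate,
                x$lower, x$upper, x$n))
  }
  invisible(x)
}

#' Spearman-Brown correction of a split-half correlation
#'
#' `r_SB = 2 r / (1 + r)`: projects the correlation between two half-length
#' tests up to the reliability of the full-length test.
#'
#' @param r correlation in `(-1, 1]`.
#' @return corrected correlation.
#' @examples
#' spearman_brown(0.84)  # 0.913
#' @export
spearman_brown <- function(r) {
  .assert(all(r > -1 & r <= 1), "r must be in (-1, 1]")
  2 * r / (1 + r)
}

#' Model-calculated ICC from variance components
#'
#' The ratio of between-subject variance to the sum of between-subject and
#' session-within-subject variance, both taken from a hierarchical model
#' fit. The default follows the convention of leaving the residual
#' (observation-level) variance out of the denominator; set
#' `include_residual = TRUE` for the conventional ICC that includes it.
#'
#' @param var_subject between-subject variance (>= 0).
#' @param var_session_within session-within-subject variance (>= 0).
#' @param var_residual residual variance; only used when
#'   `include_residual = TRUE`.
#' @param include_residual include residual variance in the denominator.
#' @return ICC in `[0, 1]`.
#' @export
icc_from_variance_components <- function(var_subject, var_session_within,
                                         var_residual = 0,
                                         include_residual = FALSE) {
  .assert(var_subject >= 0 && var_session_within >= 0,
          "variances must be non-negative")
  denom <- var_subject + var_session_within +
    if (include_residual) var_residual else 0
  .assert(denom > 0, "both variance components are zero")
  var_subject / denom
}

#' Model-calculated Pearson correlation from a joint prior covariance
#'
#' For a joint-session EM fit, the cross-session reliability of a parameter
#' is the prior covariance between its session-1 and session-2 copies,
#' normalized by the two standard deviations. Because the prior covariance
#' incorporates per-subject estimation uncertainty, this is the
#' model-calculated analogue of the Pearson correlation of point estimates.
#'
#' @param Sigma joint prior covariance matrix.
#' @param i,j indices of the matched parameter in sessions 1 and 2.
#' @return correlation.
#' @export
pearson_from_prior_cov <- function(Sigma, i, j) {
  .assert(is.matrix(Sigma) && nrow(Sigma) == ncol(Sigma),
          "Sigma must be square")
  .assert(Sigma[i, i] > 0 && Sigma[j, j] > 0,
          "zero variance for the requested parameter")
  Sigma[i, j] / sqrt(Sigma[i, i] * Sigma[j, j])
}

#' Interpret an ICC on Cicchetti's clinical-significance scale
#'
#' Below .40 poor, .40 to .60 fair, .60 to .75 good, .75 to 1 excellent
#' (half-open bins).
#'
#' @param value ICC value(s), `<= 1`.
#' @return character vector of labels.
#' @examples
#' classify_icc(c(0.30, 0.45, 0.66, 0.80))
#' @export
classify_icc <- function(value) {
  .assert(all(value <= 1), "ICC cannot exceed 1")
  cut(value, breaks = c(-Inf, 0.40, 0.60, 0.75, 1),
      labels = c("poor", "fair", "good", "excellent"), right = FALSE,
      include.lowest = TRUE) |> as.character()
}

#' Two-way variance partition of a subject-by-session matrix
#'
#' Decomposes paired values into between-subject variance, a
#' session-within-subject (systematic session) component and error variance
#' via the two-way ANOVA mean squares, and reports them as shares of their
#' sum. Negative method-of-moments component estimates are truncated at 0.
#'
#' @param values numeric matrix with one row per subject and one column per
#'   session (2 columns), or a pair `cbind(x, y)`.
#' @param route optional label carried through to the output.
#' @return object of class `prl_varcomp`: list with `var_between`,
#'   `var_session`, `var_error`, `shares` (summing to 1) and `route`.
#' @export
variance_partition <- function(values, route = NULL) {
  values <- as.matrix(values)
  .assert(ncol(values) == 2, "expected a subject x 2-session matrix")
  .assert(nrow(values) >= 3, "need at least 3 subjects")
  .assert(all(is.finite(values)), "values must be finite")
  ms <- .icc_ms(values[, 1], values[, 2])
  v_b <- max((ms$msr - ms$mse) / ms$k, 0)
  v_s <- max((ms$msc - ms$mse) / ms$n, 0)
  v_e <- ms$mse
  tot <- v_b + v_s + v_e
  shares <- if (tot > 0) c(between = v_b, session = v_s, error = v_e) / tot
            else c(between = NA_real_, session = NA_real_, error = NA_real_)
  structure(list(var_between = v_b, var_session = v_s, var_error = v_e,
                 shares = shares, route = route), class = "prl_varcomp")
}

#' @export
print.prl_varcomp <- function(x, ...) {
  cat("variance components", if (!is.null(x$route))
    paste0(" (", x$route, ")"), ":\n", sep = "")
  cat(sprintf("  between-subject %.4g (%.1f%%)\n", x$var_between,
              100 * x$shares[["between"]]))
  cat(sprintf("  session within  %.4g (%.1f%%)\n", x$var_session,
              100 * x$shares[["session"]]))
  cat(sprintf("  error           %.4g (%.1f%%)\n", x$var_error,
              100 * x$shares[["error"]]))
  invisible(x)
}

#' Assemble a reliability report for one metric
#'
#' Bundles ICC(A,1), ICC(1) and Pearson (with confidence intervals) for a
#' pair of session vectors, plus optional model-calculated statistics.
#'
#' @param x,y paired per-subject session values.
#' @param metric metric label.
#' @param route estimation route label (e.g. "means", "joint").
#' @param model_icc_1 optional model-calculated ICC(1).
#' @param model_pearson optional model-calculated Pearson correlation.
#' @return one-row data.frame.
#' @export
reliability_report <- function(x, y, metric = "", route = "",
                               model_icc_1 = NA_real_,
                               model_pearson = NA_real_) {
  a1 <- icc_a1(x, y)
  i1 <- icc_1(x, y)
  ct <- suppressWarnings(cor.test(x, y))
  data.frame(metric = metric, route = route,
             icc_a1 = a1$estimate, icc_a1_lwr = a1$lower,
             icc_a1_upr = a1$upper,
             icc_1 = i1$estimate, icc_1_lwr = i1$lower,
             icc_1_upr = i1$upper,
             pearson = unname(ct$estimate),
             pearson_lwr = ct$conf.int[1], pearson_upr = ct$conf.int[2],
             model_icc_1 = model_icc_1, model_pearson = model_pearson,
             n = length(x))
}
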