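#' Build a probabilistic reversal learning task schedule
#'
#' A PRLT schedule specifies, for every trial, which of the two options is
#' currently the "good" (more lucrative) one and with what probability a
#' choice of the good/bad option is rewarded. In the default design the two
#' options carry 80%/20% win probabilities that are perfectly anti-correlated
#' and swap five times, after trials 55, 70, 90, 105 and 125 (1-based), over
#' a run of 160 trials.
#'
#' @param n_trials number of trials (default 160).
#' @param reversal_after 1-based trial indices after which the contingencies
#'   reverse; must be strictly increasing and `< n_trials`. An empty vector
#'   yields a schedule without reversals.
#' @param p_win_good win probability of the currently better option.
#' @param p_win_bad win probability of the currently worse option.
#' @param version_id label of the task version. Version `"A"` starts with
#'   option 0 as the good option, any other label with option 1; two
#'   counterbalanced versions differ only in this starting assignment.
#'
#' @return An object of class `prl_schedule`: a list with the arguments plus
#'   `good_option`, an integer vector of length `n_trials` giving the good
#'   option (0 or 1) at every trial.
#' @examples
#' sched <- build_schedule()
#' which(diff(sched$good_option) != 0) + 1L  # flips begin at 56,71,91,106,126
#' @export
build_schedule <- function(n_trials = 160L,
                           reversal_after = c(55L, 70L, 90L, 105L, 125L),
                           p_win_good = 0.8, p_win_bad = 0.2,
                           version_id = "A") {
  n_trials <- as.integer(n_trials)
  reversal_after <- as.integer(reversal_after)
  .assert(n_trials >= 1, "n_trials must be >= 1")
  if (length(reversal_after)) {
    .assert(all(diff(reversal_after) > 0),
            "reversal_after must be strictly increasing")
    .assert(all(reversal_after >= 1 & reversal_after < n_trials),
            "reversal_after indices must lie in [1, n_trials)")
  }
  .assert(p_win_good >= 0 && p_win_good <= 1, "p_win_good must be in [0,1]")
  .assert(p_win_bad >= 0 && p_win_bad <= 1, "p_win_bad must be in [0,1]")

  start <- if (identical(version_id, "A")) 0L else 1L
  flips <- integer(n_trials)          # number of reversals before each trial
  if (length(reversal_after)) {
    for (r in reversal_after) flips[(r + 1L):n_trials] <-
        flips[(r + 1L):n_trials] + 1L
  }
  good <- (start + flips) %% 2L

  structure(list(n_trials = n_trials, reversal_after = reversal_after,
                 p_win_good = p_win_good, p_win_bad = p_win_bad,
                 version_id = version_id, good_option = good),
            class = "prl_schedule")
}

#' Good option at given trials
#'
#' @param schedule a `prl_schedule`.
#' @param trials 1-based trial indices (default: all trials).
#' @return integer vector of option indices (0/1).
#' @export
good_option <- function(schedule, trials = seq_len(schedule$n_trials)) {
  .assert(inherits(schedule, "prl_schedule"), "not a prl_schedule")
  .assert(all(trials >= 1 & trials <= schedule$n_trials),
          "trial index out of schedule range")
  schedule$good_option[trials]
}

#' Sample probabilistic feedback for a choice
#'
#' Draws a uniform number and compares it to the chosen option's current win
#' probability, exactly mirroring the task's feedback rule: draws are
#' independent across trials ("with replacement"), so the realized win rate
#' varies around the nominal contingency.
#'
#' @param schedule a `prl_schedule`.
#' @param trial_index 1-based trial index.
#' @param choice chosen option, 0 or 1 (vectorized over trials/choices).
#' @return reward coded `+1` (win) or `-1` (loss).
#' @export
sample_feedback <- function(schedule, trial_index, choice) {
  .assert(inherits(schedule, "prl_schedule"), "not a prl_schedule")
  .assert(all(choice %in% c(0L, 1L)), "choice must be 0 or 1")
  good <- good_option(schedule, trial_index)
  p_win <- ifelse(choice == good, schedule$p_win_good, schedule$p_win_bad)
  ifelse(runif(length(p_win)) < p_win, 1, -1)
}

#' @export
print.prl_schedule <- function(x, ...) {
  cat("PRLT schedule (version ", x$version_id, "): ", x$n_trials,
      " trials, contingencies ", x$p_win_good, "/", x$p_win_bad, "\n",
      sep = "")
  if (length(x$reversal_after))
    cat("reversals after trials:", paste(x$reversal_after, collapse = ", "),
        "\n")
  else cat("no reversals\n")
  invisible(x)
}

#' Serialize / deserialize a schedule as JSON
#'
#' @param schedule a `prl_schedule`.
#' @param path optional file path; if `NULL`, the JSON string is returned.
#' @return `schedule_to_json` returns the path (invisibly) or a JSON string;
#'   `schedule_from_json` returns a `prl_schedule`.
#' @export
schedule_to_json <- function(schedule, path = NULL) {
  .assert(inherits(schedule, "prl_schedule"), "not a prl_schedule")
  x <- unclass(schedule)[c("n_trials", "reversal_after", "p_win_good",
                           "p_win_bad", "version_id")]
  if (is.null(path)) {
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' @rdname schedule_to_json
#' @param json a JSON string or file path produced by [schedule_to_json()].
#' @export
schedule_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  build_schedule(n_trials = x$n_trials,
                 reversal_after = x$reversal_after %||% integer(),
                 p_win_good = x$p_win_good, p_win_bad = x$p_win_bad,
                 version_id = x$version_id)
}
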