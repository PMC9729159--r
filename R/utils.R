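`%||%` <- function(a, b) if (is.null(a)) b else a

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Derive a stage seed from a master seed; kept inside 32-bit integer range.
.split_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(offset)) %% 2147483645 + 1)
}

.set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Columns mandatory for cohort trial tables (long format).
.trial_cols <- c("subject_id", "session", "trial", "choice",
                 "correct_option", "feedback")

.check_cohort <- function(data) {
  .assert(is.data.frame(data), "trial data must be a data.frame")
  missing <- setdiff(.trial_cols, names(data))
  .assert(length(missing) == 0,
          paste0("missing mandatory column(s): ",
                 paste(missing, collapse = ", ")))
  .assert(all(data$choice %in% c(0L, 1L)), "choice must be coded 0/1")
  .assert(all(data$feedback %in% c(-1, 1)), "feedback must be coded +1/-1")
  invisible(data)
}
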