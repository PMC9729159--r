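# Orchestration: readers/writers for the long-format trial schema, seeded
# end-to-end analysis runs, and report assembly.

#' Read a cohort trial table from CSV
#'
#' The long-format schema has mandatory columns `subject_id`, `session`,
#' `trial`, `choice` (0/1), `correct_option` (0/1), `feedback` (+1/-1) and
#' optional `rt_ms`, `version_id`; unknown columns are preserved. A
#' `feedback_coding = "binary"` dialect maps win/loss codes {1, 0} onto
#' {+1, -1} on read.
#'
#' @param path CSV file path.
#' @param feedback_coding `"pm1"` (native +1/-1) or `"binary"` (1 = win,
#'   0 = loss).
#' @return cohort trial data.frame.
#' @export
read_trials <- function(path, feedback_coding = c("pm1", "binary")) {
  feedback_coding <- match.arg(feedback_coding)
  data <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.trial_cols, names(data))
  if (length(missing))
    stop("file ", path, ": missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (feedback_coding == "binary") {
    bad <- which(!(data$feedback %in% c(0, 1)))
    if (length(bad))
      stop("file ", path, ": line(s) ", paste(utils::head(bad + 1, 5),
           collapse = ", "), ": feedback not in {0, 1}", call. = FALSE)
    data$feedback <- ifelse(data$feedback == 1, 1, -1)
  }
  bad <- which(!(data$feedback %in% c(-1, 1)))
  if (length(bad))
    stop("file ", path, ": line(s) ", paste(utils::head(bad + 1, 5),
         collapse = ", "), ": feedback not in {+1, -1}", call. = FALSE)
  bad <- which(!(data$choice %in% c(0, 1)))
  if (length(bad))
    stop("file ", path, ": line(s) ", paste(utils::head(bad + 1, 5),
         collapse = ", "), ": choice not in {0, 1}", call. = FALSE)
  data
}

#' Write a cohort trial table to CSV
#'
#' Inverse of [read_trials()]: `read_trials(write_trials(x, path))`
#' round-trips the trial schema.
#'
#' @param data cohort trial table.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_trials <- function(data, path) {
  .check_cohort(data)
  write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' Configuration for a full analysis run
#'
#' @param input path to a trial CSV, or `NULL` to generate a synthetic
#'   study from `population`.
#' @param population a `prl_population` (used when `input` is `NULL`).
#' @param models character vector of canonical model names to fit.
#' @param methods estimation methods, subset of `c("ml", "map0", "em")`.
#' @param session_modes subset of `c("separate", "joint")`.
#' @param metrics behavioral metrics to analyze.
#' @param schedules optional list of two `prl_schedule`s handed to
#'   [generate_study()] (defaults to the standard 160-trial versions).
#' @param seed master seed; all stage seeds are derived from it.
#' @param n_restarts,n_repeats,em_max_iter,em_tol,ibic_K scale factors for
#'   the fitting stages.
#' @param out_dir optional output directory for [write_report()].
#' @return a `prl_config` list.
#' @export
prl_config <- function(input = NULL, population = population_spec(),
                       models = "DU-2rho-alpha",
                       methods = c("ml", "map0", "em"),
                       session_modes = c("separate", "joint"),
                       metrics = c("accuracy", "stay", "stay_win",
                                   "stay_loss", "perseveration", "rt",
                                   "rt_win", "rt_loss", "delta_rt"),
                       schedules = NULL,
                       seed = 1, n_restarts = 10, n_repeats = 10,
                       em_max_iter = 100, em_tol = 1e-3, ibic_K = 2000,
                       out_dir = NULL) {
  .assert(!is.null(seed), "a master seed is mandatory")
  all_models <- vapply(enumerate_models(), `[[`, "", "name")
  unknown <- setdiff(models, all_models)
  .assert(length(unknown) == 0,
          paste0("unknown model(s): ", paste(unknown, collapse = ", ")))
  structure(list(input = input, population = population, models = models,
                 methods = match.arg(methods, c("ml", "map0", "em"),
                                     several.ok = TRUE),
                 session_modes = match.arg(session_modes,
                                           c("separate", "joint"),
                                           several.ok = TRUE),
                 metrics = metrics, schedules = schedules,
                 seed = as.integer(seed),
                 n_restarts = n_restarts, n_repeats = n_repeats,
                 em_max_iter = em_max_iter, em_tol = em_tol,
                 ibic_K = ibic_K, out_dir = out_dir),
            class = "prl_config")
}

#' Run the full reliability analysis
#'
#' Executes the analysis flow end to end: data acquisition (synthetic
#' generation or CSV input), chance-level exclusion, behavioral metrics by
#' the three routes (raw means, separate hierarchical models, joint
#' hierarchical models) with reliability reports and variance partitions,
#' split-half internal consistency, model fitting for every configured
#' model x method x session mode with per-parameter reliability, iBIC model
#' comparison across the configured models (EM fits), and a manifest of
#' stages, seeds and timings. All randomness derives from the master seed.
#'
#' @param config a `prl_config`.
#' @return a report bundle (list) with elements `data`, `exclusion`,
#'   `behavior` (per-metric reliability and variance components),
#'   `consistency`, `fits`, `parameter_reliability`, `model_comparison`,
#'   and `manifest`.
#' @export
run_full_analysis <- function(config) {
  .assert(inherits(config, "prl_config"), "config must be a prl_config")
  t0 <- Sys.time()
  stages <- character(0)
  stage <- function(s) stages <<- c(stages, s)

  # -- data
  data <- if (is.null(config$input)) {
    generate_study(config$population, schedules = config$schedules,
                   seed = .split_seed(config$seed, 1))
  } else read_trials(config$input)
  stage("data")

  # -- exclusion
  excl <- exclude_chance_performers(data)
  data <- excl$data
  stage("exclusion")

  # -- behavioral metrics: raw + hierarchical, reliability per route
  raw <- cohort_metrics(data)
  sessions <- sort(unique(data$session))
  two_sessions <- length(sessions) == 2
  behavior <- list()
  for (met in config$metrics) {
    entry <- list(metric = met)
    routes <- list()
    if (two_sessions) {
      x <- raw[raw$session == sessions[1], met]
      y <- raw[raw$session == sessions[2], met]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) >= 3)
        routes[["means"]] <- reliability_report(x[ok], y[ok], met, "means")
    }
    for (mode in c("separate", "joint")) {
      if (!two_sessions) next
      h <- tryCatch(fit_hierarchical_metric(data, met, mode),
                    error = function(e) NULL)
      if (is.null(h)) next
      p <- h$predicted
      x <- p$value[p$session == as.character(sessions[1])]
      y <- p$value[p$session == as.character(sessions[2])]
      if (length(x) == length(y) && length(x) >= 3) {
        micc <- NA_real_
        if (mode == "joint" &&
            (h$varcomp$var_between + h$varcomp$var_session) > 0)
          micc <- icc_from_variance_components(h$varcomp$var_between,
                                               h$varcomp$var_session)
        routes[[mode]] <- reliability_report(x, y, met, mode,
                                             model_icc_1 = micc)
        entry[[paste0("varcomp_", mode)]] <- h$varcomp
        entry[[paste0("variance_partition_", mode)]] <-
          variance_partition(cbind(x, y), mode)
      }
    }
    if (two_sessions && "means" %in% names(routes)) {
      x <- raw[raw$session == sessions[1], met]
      y <- raw[raw$session == sessions[2], met]
      ok <- is.finite(x) & is.finite(y)
      entry$variance_partition_means <-
        variance_partition(cbind(x[ok], y[ok]), "means")
    }
    entry$reliability <- do.call(rbind, unname(routes))
    behavior[[met]] <- entry
  }
  stage("behavior")

  consistency <- tryCatch(internal_consistency(data),
                          error = function(e) NULL)
  stage("consistency")

  # -- model fitting
  fits <- list()
  par_rel <- list()
  ibic_tab <- c()
  fit_seed <- 0L
  for (mn in config$models) {
    spec <- get_model(mn)
    for (method in config$methods) {
      for (mode in config$session_modes) {
        if (mode == "joint" && !two_sessions) next
        fit_seed <- fit_seed + 1L
        s <- .split_seed(config$seed, 100 + fit_seed)
        fit <- switch(method,
          ml = fit_ml(data, spec, mode, n_restarts = config$n_restarts,
                      n_repeats = config$n_repeats, seed = s),
          map0 = fit_map0(data, spec, mode,
                          n_restarts = config$n_restarts,
                          n_repeats = config$n_repeats, seed = s),
          em = fit_em(data, spec, mode, max_iter = config$em_max_iter,
                      tol = config$em_tol,
                      n_restarts = config$n_restarts,
                      n_repeats = config$n_repeats, seed = s))
        key <- paste(mn, method, mode, sep = ".")
        fits[[key]] <- fit
        if (two_sessions) {
          rel <- fit_reliability(fit)
          rel$model <- mn; rel$method <- method; rel$sessions <- mode
          par_rel[[key]] <- rel
        }
        if (method == "em" && mode == "joint")
          ibic_tab[mn] <- ibic(fit, data, K = config$ibic_K,
                               seed = .split_seed(config$seed, 7))
      }
    }
  }
  stage("fits")
  model_comparison <- if (length(ibic_tab) >= 1) select_model(ibic_tab)
  stage("model_selection")

  manifest <- list(package_version =
                     as.character(utils::packageVersion("prlrel")),
                   seed = config$seed, stages = stages,
                   n_subjects = length(unique(data$subject_id)),
                   n_excluded = length(excl$excluded),
                   models = config$models, methods = config$methods,
                   session_modes = config$session_modes,
                   elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                   units = "secs")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  structure(list(data = data, exclusion = excl$report, behavior = behavior,
                 consistency = consistency, fits = fits,
                 parameter_reliability = do.call(rbind,
                                                 unname(par_rel)),
                 model_comparison = model_comparison,
                 manifest = manifest),
            class = "prl_report")
}

#' Write a report bundle to disk
#'
#' Emits tidy CSVs (metrics, reliability tables, model comparison) and a
#' JSON manifest under `dir`.
#'
#' @param bundle a `prl_report` from [run_full_analysis()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_report <- function(bundle, dir) {
  .assert(inherits(bundle, "prl_report"), "bundle must be a prl_report")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rel <- do.call(rbind, unname(lapply(bundle$behavior,
                                      function(e) e$reliability)))
  if (!is.null(rel))
    write.csv(rel, file.path(dir, "behavior_reliability.csv"),
              row.names = FALSE)
  if (!is.null(bundle$parameter_reliability))
    write.csv(bundle$parameter_reliability,
              file.path(dir, "parameter_reliability.csv"),
              row.names = FALSE)
  if (!is.null(bundle$model_comparison))
    write.csv(bundle$model_comparison,
              file.path(dir, "model_comparison.csv"), row.names = FALSE)
  if (!is.null(bundle$consistency))
    write.csv(bundle$consistency,
              file.path(dir, "internal_consistency.csv"),
              row.names = FALSE)
  write.csv(bundle$exclusion, file.path(dir, "exclusion.csv"),
            row.names = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.prl_report <- function(x, ...) {
  cat("PRLT analysis report:", x$manifest$n_subjects, "subjects,",
      length(x$fits), "model fits, stages:",
      paste(x$manifest$stages, collapse = " -> "), "\n")
  invisible(x)
}
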