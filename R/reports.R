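# Run configuration, pipeline entry points and report bundles.

#' Run configuration
#'
#' Bundles everything a full pipeline run needs: where sessions come from
#' (paths or simulate-on-the-fly), augmentation parameters, the classifier
#' roster, repetition count, significance level and seed.
#'
#' @param sessions Optional list of [session()] objects (takes precedence).
#' @param samples_path,reports_path,metadata_path Session CSV paths (used
#'   when `sessions` is `NULL` and `simulate` is `FALSE`).
#' @param simulate If `TRUE`, simulate a cohort via `cohort` instead of
#'   reading files.
#' @param cohort A [cohort_config()] used when `simulate = TRUE`.
#' @param augmentation [augmentation_params()].
#' @param classifiers Character vector of classifier names to evaluate.
#' @param n_repetitions Odd number of CV repetitions.
#' @param n_search_iter Random-search draws per test fold.
#' @param window_stride Window-start stride (1 = every possible window;
#'   larger values thin the window set for cheaper fitting).
#' @param search_spaces Optional named list of per-classifier search-space
#'   overrides (see [default_search_space()]); a single-point space pins
#'   the hyperparameters and skips the inner search.
#' @param alpha Significance level for the McNemar comparisons.
#' @param seed Integer seed (required; drives every random stage).
#' @param out_dir Output directory for report files, or `NULL` to skip
#'   writing.
#' @return Object of class `"exertr_run_config"`.
#' @export
run_config <- function(sessions = NULL, samples_path = NULL,
                       reports_path = NULL, metadata_path = NULL,
                       simulate = is.null(sessions) && is.null(samples_path),
                       cohort = cohort_config(seed = seed),
                       augmentation = augmentation_params(),
                       classifiers = c("majority", "borg", "knn_dtw"),
                       n_repetitions = 15L, n_search_iter = 10L,
                       window_stride = 1L, search_spaces = list(),
                       alpha = 0.05, seed, out_dir = NULL) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(n_repetitions %% 2L == 1L, alpha > 0, alpha < 1)
  structure(list(sessions = sessions, samples_path = samples_path,
                 reports_path = reports_path, metadata_path = metadata_path,
                 simulate = simulate, cohort = cohort,
                 augmentation = augmentation, classifiers = classifiers,
                 n_repetitions = as.integer(n_repetitions),
                 n_search_iter = as.integer(n_search_iter),
                 window_stride = as.integer(window_stride),
                 search_spaces = search_spaces,
                 alpha = alpha, seed = as.integer(seed), out_dir = out_dir),
            class = "exertr_run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Recognized top-level keys mirror the [run_config()] arguments; group
#' parameter overrides live under `cohort$trained` / `cohort$untrained`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `"exertr_run_config"`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  seed <- raw$seed
  if (is.null(seed)) stop("config must provide a seed", call. = FALSE)
  cohort_raw <- raw$cohort
  cohort <- cohort_config(
    n_trained = cohort_raw$n_trained %||% 6,
    n_untrained = cohort_raw$n_untrained %||% 6,
    seed = cohort_raw$seed %||% seed,
    trained = merge_group_params(default_group_params("trained"), cohort_raw$trained),
    untrained = merge_group_params(default_group_params("untrained"), cohort_raw$untrained)
  )
  aug <- augmentation_params(mo = raw$mo %||% 180, L = raw$L %||% 60)
  run_config(samples_path = raw$samples_path, reports_path = raw$reports_path,
             metadata_path = raw$metadata_path,
             simulate = raw$simulate %||% is.null(raw$samples_path),
             cohort = cohort, augmentation = aug,
             classifiers = raw$classifiers %||% c("majority", "borg", "knn_dtw"),
             n_repetitions = raw$n_repetitions %||% 15L,
             n_search_iter = raw$n_search_iter %||% 10L,
             window_stride = raw$window_stride %||% 1L,
             alpha = raw$alpha %||% 0.05, seed = seed,
             out_dir = raw$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

merge_group_params <- function(defaults, overrides) {
  if (is.null(overrides)) return(defaults)
  do.call(group_params, utils::modifyList(unclass(defaults), overrides))
}

#' Simulate a cohort and write its session CSVs
#'
#' Writes the three session CSVs and a cohort summary (per-group label
#' counts per class, distances, inter-report times) as JSON. Byte-identical
#' output for identical config.
#'
#' @param config An `"exertr_run_config"` with `out_dir` set, or a
#'   [cohort_config()] plus `out_dir`.
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return Invisibly, a list with the sessions and the summary.
#' @export
cmd_simulate <- function(config, out_dir = NULL) {
  cohort_cfg <- if (inherits(config, "exertr_cohort_config")) config else config$cohort
  out_dir <- out_dir %||% if (inherits(config, "exertr_run_config")) config$out_dir else NULL
  sessions <- simulate_cohort(cohort_cfg)
  summary <- cohort_summary(sessions)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_sessions(sessions,
                   file.path(out_dir, "samples.csv"),
                   file.path(out_dir, "reports.csv"),
                   file.path(out_dir, "metadata.csv"))
    jsonlite::write_json(summary, file.path(out_dir, "cohort_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(sessions = sessions, summary = summary))
}

#' Cohort summary in the shape of the study's dataset-statistics table
#'
#' @param sessions List of [session()] objects.
#' @return Nested list: per group and overall, the number of RPE reports,
#'   counts per exertion class, mean covered distance (km), mean running
#'   time (min) and mean inter-report time (min).
#' @export
cohort_summary <- function(sessions) {
  by_group <- function(grp) {
    ss <- Filter(function(s) s$group == grp, sessions)
    if (length(ss) == 0L) return(NULL)
    rpes <- unlist(lapply(ss, function(s) s$reports$rpe))
    labels <- binarize_rpe(rpes)
    inter <- unlist(lapply(ss, function(s) diff(c(0, s$reports$t))))
    dists <- vapply(ss, function(s) sum(s$velocity) / 1000, numeric(1))
    durs <- vapply(ss, function(s) session_duration(s) / 60, numeric(1))
    list(n_runners = length(ss),
         n_rpe_values = length(rpes),
         n_non_exerted = sum(labels == "non_exerted"),
         n_exerted = sum(labels == "exerted"),
         mean_distance_km = mean(dists),
         mean_running_time_min = mean(durs),
         mean_inter_report_time_min = mean(inter) / 60)
  }
  groups <- list(untrained = by_group("untrained"), trained = by_group("trained"))
  all_rpe <- unlist(lapply(sessions, function(s) s$reports$rpe))
  all_lab <- binarize_rpe(all_rpe)
  groups$overall <- list(n_rpe_values = length(all_rpe),
                         n_non_exerted = sum(all_lab == "non_exerted"),
                         n_exerted = sum(all_lab == "exerted"))
  groups
}

#' Run the full evaluation pipeline
#'
#' Sessions are obtained (simulated or read), windows extracted, each
#' classifier in the roster evaluated by [run_repeated_cv()], per-label
#' predictions aggregated into consensus predictions, metrics computed
#' overall and per runner group, and all classifier pairs compared with
#' the corrected McNemar test. Fully seeded and deterministic.
#'
#' @param config An `"exertr_run_config"`.
#' @return A report bundle: list with `config_echo`, `predictions`,
#'   `consensus`, `metrics` (per classifier: overall/untrained/trained),
#'   `mcnemar` (data frame of pairwise results).
#' @export
cmd_evaluate <- function(config) {
  stopifnot(inherits(config, "exertr_run_config"))
  sessions <- if (!is.null(config$sessions)) config$sessions
    else if (config$simulate) simulate_cohort(config$cohort)
    else read_sessions(config$samples_path, config$reports_path,
                       config$metadata_path)
  message(sprintf("[exertr] %d sessions; extracting windows (mo=%d, L=%d, stride=%d)",
                  length(sessions), config$augmentation$mo,
                  config$augmentation$L, config$window_stride))
  windows <- build_window_set(sessions, config$augmentation,
                              stride = config$window_stride)
  message(sprintf("[exertr] %d windows over %d labels", n_windows(windows),
                  nrow(unique(windows$meta[, c("runner_id", "marker_t")]))))
  preds <- list(); consensus <- list(); metrics <- list()
  for (name in config$classifiers) {
    message(sprintf("[exertr] evaluating %s (%d repetitions)", name,
                    config$n_repetitions))
    t0 <- Sys.time()
    space <- config$search_spaces[[name]] %||% default_search_space(name)
    p <- run_repeated_cv(windows, name,
                         n_repetitions = config$n_repetitions,
                         seed = config$seed, space = space,
                         n_iter = config$n_search_iter)
    cons <- aggregate_votes(p)
    preds[[name]] <- p
    consensus[[name]] <- cons
    metrics[[name]] <- list(
      overall = compute_metrics(cons),
      untrained = compute_metrics(cons[cons$group == "untrained", ]),
      trained = compute_metrics(cons[cons$group == "trained", ]),
      per_repetition_accuracy = tapply(
        p$predicted_class == p$true_class, p$repetition, mean))
    message(sprintf("[exertr]   %s consensus accuracy %.1f%% (%.1fs)", name,
                    100 * metrics[[name]]$overall$accuracy,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  mcn <- list()
  nms <- names(consensus)
  if (length(nms) >= 2L) {
    for (i in seq_along(nms)) for (j in seq_along(nms)) {
      if (i >= j) next
      tab <- mcnemar_table(consensus[[nms[i]]], consensus[[nms[j]]])
      res <- suppressWarnings(mcnemar_test(tab, alpha = config$alpha))
      mcn[[length(mcn) + 1L]] <- data.frame(
        classifier_1 = nms[i], classifier_2 = nms[j],
        C00 = tab[["C00"]], C01 = tab[["C01"]], C10 = tab[["C10"]],
        C11 = tab[["C11"]], Z = res$Z, critical = res$critical,
        reject = res$reject)
    }
  }
  bundle <- list(config_echo = config_echo(config), predictions = preds,
                 consensus = consensus, metrics = metrics,
                 mcnemar = if (length(mcn)) do.call(rbind, mcn) else NULL)
  if (!is.null(config$out_dir)) write_report_bundle(bundle, config$out_dir)
  bundle
}

config_echo <- function(config) {
  list(seed = config$seed, n_repetitions = config$n_repetitions,
       n_search_iter = config$n_search_iter,
       window_stride = config$window_stride, alpha = config$alpha,
       mo = config$augmentation$mo, L = config$augmentation$L,
       classifiers = config$classifiers, simulate = config$simulate)
}

#' Write a report bundle to disk
#'
#' Emits `summary.json` (all metrics, confusion matrices, McNemar results
#' and the echoed configuration), one predictions CSV per classifier, and
#' a metrics CSV shaped like the study's summary tables (one row per
#' classifier; support-weighted percentages rounded to one decimal, half
#' away from zero).
#'
#' @param bundle Result of [cmd_evaluate()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, `out_dir`.
#' @export
write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- metrics_table(bundle$metrics)
  utils::write.csv(tab, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  for (name in names(bundle$predictions)) {
    p <- bundle$predictions[[name]]
    write_predictions(
      data.frame(runner_id = p$runner_id, marker_t = p$marker_t,
                 repetition = p$repetition, classifier = p$classifier,
                 true_class = p$true_class, predicted_class = p$predicted_class),
      file.path(out_dir, paste0("predictions_", name, ".csv")))
  }
  json <- list(config = bundle$config_echo,
               metrics = lapply(bundle$metrics, function(m) {
                 lapply(m[c("overall", "untrained", "trained")], function(x) {
                   list(accuracy = x$accuracy,
                        weighted = as.list(x$weighted),
                        confusion = unname(apply(x$confusion, 1, as.list)))
                 })
               }),
               mcnemar = bundle$mcnemar)
  jsonlite::write_json(json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(bundle$mcnemar)) {
    utils::write.csv(bundle$mcnemar, file.path(out_dir, "mcnemar.csv"),
                     row.names = FALSE)
  }
  invisible(out_dir)
}

#' Summary metrics table across classifiers
#'
#' @param metrics The `metrics` element of a report bundle.
#' @return Data frame, one row per classifier, with support-weighted
#'   percentages (1 decimal) overall and per group.
#' @export
metrics_table <- function(metrics) {
  do.call(rbind, lapply(names(metrics), function(name) {
    m <- metrics[[name]]
    data.frame(
      classifier = name,
      accuracy = round_half_away(100 * m$overall$accuracy),
      precision = round_half_away(100 * m$overall$weighted[["precision"]]),
      recall = round_half_away(100 * m$overall$weighted[["recall"]]),
      f1 = round_half_away(100 * m$overall$weighted[["f1"]]),
      untrained_accuracy = round_half_away(100 * m$untrained$accuracy),
      untrained_f1 = round_half_away(100 * m$untrained$weighted[["f1"]]),
      trained_accuracy = round_half_away(100 * m$trained$accuracy),
      trained_f1 = round_half_away(100 * m$trained$weighted[["f1"]]))
  }))
}
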