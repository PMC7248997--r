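# Domain types and I/O for runner sessions, RPE reports and predictions.

#' Exertion class levels
#'
#' The two-class target used throughout the package, derived from the Borg
#' 6--20 RPE scale: `"non_exerted"` ("Somewhat hard to hard", RPE <= 15) and
#' `"exerted"` ("Hard to very hard", RPE > 15). The vector is ordered so that
#' `non_exerted < exerted`, which fixes deterministic tie handling: every
#' tie-break in the package resolves towards the first level.
#'
#' @return Character vector of the two class labels, in order.
#' @export
exertion_levels <- function() c("non_exerted", "exerted")

#' Binarize a Borg RPE score into an exertion class
#'
#' Scores of 15 or below map to `"non_exerted"`, scores above 15 to
#' `"exerted"`. The mapping is monotone in the score.
#'
#' @param rpe Integer vector of Borg scores in `[6, 20]`.
#' @return Character vector of exertion classes (see [exertion_levels()]).
#' @examples
#' binarize_rpe(c(6, 15, 16, 20))
#' @export
binarize_rpe <- function(rpe) {
  if (length(rpe) == 0L) return(character(0))
  if (any(!is.finite(rpe)) || any(rpe != round(rpe)) || any(rpe < 6) || any(rpe > 20)) {
    stop("RPE must be an integer Borg score in [6, 20]", call. = FALSE)
  }
  ifelse(rpe <= 15, "non_exerted", "exerted")
}

#' Construct a runner session
#'
#' A session is one runner's 1 Hz multichannel telemetry together with the
#' sparse RPE reports given during the run. Channels are heart rate (bpm),
#' cadence (steps/min) and velocity (m/s) on a strictly increasing integer
#' time grid with 1 s steps; gaps are rejected rather than interpolated.
#'
#' @param runner_id Character scalar identifying the runner.
#' @param group `"trained"` or `"untrained"`.
#' @param time Integer seconds from session start (0-based, step 1).
#' @param heart_rate Numeric bpm, one value per sample, in (0, 260).
#' @param cadence Numeric steps/min, nonnegative.
#' @param velocity Numeric m/s, nonnegative.
#' @param reports Data frame with columns `t` (seconds, strictly increasing,
#'   within the session) and `rpe` (integer Borg score in `[6, 20]`).
#' @param hr_max Maximal heart rate (bpm) metadata, or `NA`.
#' @return An object of class `"exertr_session"`.
#' @export
session <- function(runner_id, group, time, heart_rate, cadence, velocity,
                    reports, hr_max = NA_real_) {
  stopifnot(is.character(runner_id), length(runner_id) == 1L)
  group <- match.arg(group, c("trained", "untrained"))
  n <- length(time)
  if (length(heart_rate) != n || length(cadence) != n || length(velocity) != n) {
    stop("all three channels must have the same length as the time grid", call. = FALSE)
  }
  if (n == 0L) stop("session must contain at least one sample", call. = FALSE)
  if (any(diff(time) != 1)) {
    stop("time must be strictly increasing with step 1 s (no gaps)", call. = FALSE)
  }
  if (any(heart_rate <= 0 | heart_rate >= 260)) {
    stop("heart_rate samples must lie in (0, 260) bpm", call. = FALSE)
  }
  if (any(cadence < 0)) stop("cadence must be nonnegative", call. = FALSE)
  if (any(velocity < 0)) stop("velocity must be nonnegative", call. = FALSE)
  reports <- as.data.frame(reports)
  if (!all(c("t", "rpe") %in% names(reports))) {
    stop("reports must have columns t and rpe", call. = FALSE)
  }
  if (nrow(reports) > 0L) {
    if (any(diff(reports$t) <= 0)) {
      stop("report times must be strictly increasing", call. = FALSE)
    }
    if (any(reports$t < min(time)) || any(reports$t > max(time))) {
      stop("every report time must lie within the session", call. = FALSE)
    }
    invisible(binarize_rpe(reports$rpe))  # validates the RPE range
  }
  structure(
    list(runner_id = runner_id, group = group, sample_rate = 1,
         time = as.integer(time), heart_rate = as.numeric(heart_rate),
         cadence = as.numeric(cadence), velocity = as.numeric(velocity),
         reports = reports[, c("t", "rpe")], hr_max = as.numeric(hr_max)),
    class = "exertr_session"
  )
}

#' @export
print.exertr_session <- function(x, ...) {
  cat(sprintf("<exertr_session> runner %s (%s): %d samples (%.1f min), %d RPE reports\n",
              x$runner_id, x$group, length(x$time), length(x$time) / 60,
              nrow(x$reports)))
  invisible(x)
}

session_duration <- function(s) max(s$time)

#' Read runner sessions from CSV files
#'
#' Reads the three-file session layout: a samples file with columns
#' `runner_id, group, t_s, hr_bpm, cadence_spm, velocity_ms`, a reports file
#' with `runner_id, t_s, rpe`, and an optional metadata file with
#' `runner_id, hr_max`. All files are comma-separated UTF-8 with a header
#' row. Sessions violating the invariants (gap in the grid, RPE out of
#' range, report outside the session) are rejected with an error naming the
#' offending runner.
#'
#' @param samples_path Path to the samples CSV.
#' @param reports_path Path to the reports CSV.
#' @param metadata_path Optional path to the metadata CSV.
#' @return List of [session()] objects, one per `runner_id`, in order of
#'   first appearance.
#' @export
read_sessions <- function(samples_path, reports_path, metadata_path = NULL) {
  samp <- utils::read.csv(samples_path, stringsAsFactors = FALSE)
  need <- c("runner_id", "group", "t_s", "hr_bpm", "cadence_spm", "velocity_ms")
  miss <- setdiff(need, names(samp))
  if (length(miss)) stop("samples CSV missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  reps <- utils::read.csv(reports_path, stringsAsFactors = FALSE)
  missr <- setdiff(c("runner_id", "t_s", "rpe"), names(reps))
  if (length(missr)) stop("reports CSV missing column(s): ", paste(missr, collapse = ", "), call. = FALSE)
  meta <- NULL
  if (!is.null(metadata_path)) {
    meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
    if (!all(c("runner_id", "hr_max") %in% names(meta))) {
      stop("metadata CSV must have columns runner_id, hr_max", call. = FALSE)
    }
  }
  ids <- unique(samp$runner_id)
  lapply(ids, function(id) {
    rows <- samp[samp$runner_id == id, , drop = FALSE]
    rrows <- reps[reps$runner_id == id, , drop = FALSE]
    hrm <- NA_real_
    if (!is.null(meta) && id %in% meta$runner_id) {
      hrm <- meta$hr_max[match(id, meta$runner_id)]
    }
    grp <- unique(rows$group)
    if (length(grp) != 1L) stop("runner ", id, ": inconsistent group labels", call. = FALSE)
    tryCatch(
      session(runner_id = as.character(id), group = grp, time = rows$t_s,
              heart_rate = rows$hr_bpm, cadence = rows$cadence_spm,
              velocity = rows$velocity_ms,
              reports = data.frame(t = rrows$t_s, rpe = rrows$rpe),
              hr_max = hrm),
      error = function(e) stop("runner ", id, ": ", conditionMessage(e), call. = FALSE)
    )
  })
}

#' Write runner sessions to CSV files
#'
#' Inverse of [read_sessions()]; the round trip is lossless for the integer
#' time grid and numeric channels (channels are written with full precision).
#'
#' @param sessions List of [session()] objects.
#' @param samples_path,reports_path,metadata_path Output paths.
#' @return Invisibly, the three paths.
#' @export
write_sessions <- function(sessions, samples_path, reports_path, metadata_path) {
  samp <- do.call(rbind, lapply(sessions, function(s) {
    data.frame(runner_id = s$runner_id, group = s$group, t_s = s$time,
               hr_bpm = s$heart_rate, cadence_spm = s$cadence,
               velocity_ms = s$velocity)
  }))
  reps <- do.call(rbind, lapply(sessions, function(s) {
    if (nrow(s$reports) == 0L) return(NULL)
    data.frame(runner_id = s$runner_id, t_s = s$reports$t, rpe = s$reports$rpe)
  }))
  if (is.null(reps)) reps <- data.frame(runner_id = character(), t_s = integer(), rpe = integer())
  meta <- do.call(rbind, lapply(sessions, function(s) {
    data.frame(runner_id = s$runner_id, hr_max = s$hr_max)
  }))
  utils::write.csv(samp, samples_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(reps, reports_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(meta, metadata_path, row.names = FALSE, quote = FALSE)
  invisible(c(samples_path, reports_path, metadata_path))
}

#' Write per-label predictions to CSV
#'
#' @param preds Data frame with columns `runner_id`, `marker_t`,
#'   `repetition`, `classifier`, `true_class`, `predicted_class`. The key
#'   `(runner_id, marker_t, repetition, classifier)` must be unique.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_predictions <- function(preds, path) {
  cols <- c("runner_id", "marker_t", "repetition", "classifier",
            "true_class", "predicted_class")
  preds <- as.data.frame(preds)
  if (nrow(preds) == 0L && !all(cols %in% names(preds))) {
    preds <- data.frame(runner_id = character(), marker_t = integer(),
                        repetition = integer(), classifier = character(),
                        true_class = character(), predicted_class = character())
  }
  miss <- setdiff(cols, names(preds))
  if (length(miss)) stop("predictions missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  key <- do.call(paste, c(preds[c("runner_id", "marker_t", "repetition", "classifier")], sep = "\r"))
  if (anyDuplicated(key)) {
    stop("duplicate prediction key (runner_id, marker_t, repetition, classifier)", call. = FALSE)
  }
  bad <- !(c(preds$true_class, preds$predicted_class) %in% exertion_levels())
  if (any(bad)) stop("classes must be one of: ", paste(exertion_levels(), collapse = ", "), call. = FALSE)
  utils::write.csv(preds[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-label predictions from CSV
#'
#' @param path Path written by [write_predictions()].
#' @return Data frame with the prediction columns.
#' @export
read_predictions <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(runner_id = "character", classifier = "character"))
}
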