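# Label propagation, sliding-window extraction and per-runner scaling.

#' Augmentation parameters
#'
#' `mo` is the maximal temporal offset (s) within which a reported RPE is
#' considered constant, so every sample within `mo` of a report inherits its
#' binarized label; `L` is the window length (s) handed to the classifiers.
#'
#' @param mo Maximal temporal offset in seconds (default 180).
#' @param L Window length in seconds (default 60).
#' @return A list of class `"exertr_augmentation_params"`.
#' @export
augmentation_params <- function(mo = 180, L = 60) {
  stopifnot(mo > 0, L > 0)
  structure(list(mo = as.integer(mo), L = as.integer(L)),
            class = "exertr_augmentation_params")
}

#' Per-runner channel standardization
#'
#' Computes per-channel mean and (population) standard deviation over the
#' full session and returns both the statistics and the z-normalized
#' channels. Channels with zero variance are mapped to all zeros rather
#' than producing NaNs, since a constant-velocity run can legitimately have
#' near-zero spread.
#'
#' @param session A [session()] object.
#' @return List with `stats` (data frame: channel, mean, sd) and `values`
#'   (length-of-session x 3 matrix, columns heart_rate, cadence, velocity).
#' @export
zscore_per_runner <- function(session) {
  raw <- cbind(heart_rate = session$heart_rate,
               cadence = session$cadence,
               velocity = session$velocity)
  mu <- colMeans(raw)
  n <- nrow(raw)
  sdv <- sqrt(colMeans(raw^2) - mu^2)
  sdv[sdv < 1e-12] <- 0
  z <- sweep(raw, 2, mu, "-")
  z <- sweep(z, 2, ifelse(sdv > 0, sdv, 1), "/")
  z[, sdv == 0] <- 0
  list(stats = data.frame(channel = colnames(raw), mean = mu, sd = sdv,
                          row.names = NULL),
       values = z)
}

#' Propagate sparse RPE labels to sample resolution
#'
#' Every sample time within `mo` seconds of some report receives that
#' report's binarized label. Where the propagation ranges of two reports
#' overlap, each timestamp is assigned to the nearest marker, with ties
#' going to the earlier marker; a conflict (overlap of two different-label
#' ranges) is resolved the same way and signalled as a warning.
#'
#' @param session A [session()] object.
#' @param mo Maximal temporal offset in seconds.
#' @return Data frame with columns `t`, `label`, `marker_t`, ordered by `t`.
#' @export
propagate_labels <- function(session, mo) {
  reps <- session$reports
  if (nrow(reps) == 0L) {
    return(data.frame(t = integer(), label = character(), marker_t = integer()))
  }
  tmin <- min(session$time); tmax <- max(session$time)
  labels <- binarize_rpe(reps$rpe)
  # distance of every sample to every marker; nearest wins, ties -> earlier
  tt <- session$time
  d <- abs(outer(tt, reps$t, "-"))
  nearest <- apply(d, 1L, which.min)          # which.min takes the first = earlier
  nearest_d <- d[cbind(seq_along(tt), nearest)]
  covered <- nearest_d <= mo
  # detect genuine conflicts: a sample within mo of two different-label markers
  in_range <- d <= mo
  if (any(covered)) {
    multi <- which(covered & rowSums(in_range) > 1L)
    if (length(multi)) {
      conflicting <- vapply(multi, function(i) {
        length(unique(labels[in_range[i, ]])) > 1L
      }, logical(1))
      if (any(conflicting)) {
        warning(sprintf("%d timestamp(s) lie within mo of reports with different labels; assigned to the nearest marker", sum(conflicting)), call. = FALSE)
      }
    }
  }
  out <- data.frame(t = tt[covered],
                    label = labels[nearest[covered]],
                    marker_t = reps$t[nearest[covered]])
  out[order(out$t), , drop = FALSE]
}

#' Extract labeled sliding windows from a session
#'
#' For each RPE marker, every contiguous length-`L` subsequence (stride 1,
#' half-open `[start, start + L)` on the 1 Hz grid) lying wholly inside
#' both the session and the marker's propagated label range becomes one
#' training window. Channels are z-normalized with the runner's session
#' statistics; the raw heart-rate segment is kept alongside because the
#' Borg baseline needs un-normalized bpm. An interior marker whose range is
#' not truncated yields exactly `2 * mo + 2 - L` windows.
#'
#' @param session A [session()] object.
#' @param params [augmentation_params()].
#' @param scaling Optional result of [zscore_per_runner()] for this runner;
#'   computed if missing.
#' @param stride Sampling stride over window start positions (default 1 =
#'   every possible window). Larger values thin the window set
#'   deterministically for cheaper model fitting.
#' @return A window set (see [window_set()]).
#' @export
extract_windows <- function(session, params = augmentation_params(),
                            scaling = NULL, stride = 1L) {
  L <- params$L
  if (length(session$time) < L) {
    warning("session shorter than window length L; no windows extracted", call. = FALSE)
    return(empty_window_set(L))
  }
  if (is.null(scaling)) scaling <- zscore_per_runner(session)
  lab <- propagate_labels(session, params$mo)
  if (nrow(lab) == 0L) return(empty_window_set(L))
  t0 <- min(session$time)
  vals <- list(); raw_hr <- list(); meta <- list()
  k <- 0L
  for (m in unique(lab$marker_t)) {
    sub <- lab[lab$marker_t == m, , drop = FALSE]
    runs <- split(sub$t, cumsum(c(1L, diff(sub$t) != 1L)))
    for (run in runs) {
      lo <- run[1]; hi <- run[length(run)]
      if (hi - lo + 1L < L) next
      starts <- seq.int(lo, hi - L + 1L)
      starts <- starts[seq.int(1L, length(starts), by = max(1L, stride))]
      for (s in starts) {
        idx <- (s - t0 + 1L):(s - t0 + L)
        k <- k + 1L
        vals[[k]] <- scaling$values[idx, , drop = FALSE]
        raw_hr[[k]] <- session$heart_rate[idx]
        meta[[k]] <- data.frame(runner_id = session$runner_id,
                                group = session$group,
                                marker_t = m, window_start = s,
                                label = sub$label[1])
      }
    }
  }
  if (k == 0L) return(empty_window_set(L))
  values <- array(0, dim = c(k, L, 3),
                  dimnames = list(NULL, NULL, c("heart_rate", "cadence", "velocity")))
  for (i in seq_len(k)) values[i, , ] <- vals[[i]]
  window_set(values = values,
             raw_hr = do.call(rbind, raw_hr),
             meta = do.call(rbind, meta))
}

#' Construct a window set
#'
#' The container passed between the windowing stage and the classifiers: a
#' stack of z-normalized L x 3 windows with per-window provenance
#' (runner, originating marker, start time) and the binary exertion label.
#'
#' @param values Numeric array `n x L x 3`, channel order heart_rate,
#'   cadence, velocity, z-normalized per runner.
#' @param raw_hr Numeric matrix `n x L` of un-normalized heart rate (bpm).
#' @param meta Data frame with columns runner_id, group, marker_t,
#'   window_start, label.
#' @return Object of class `"exertr_window_set"`.
#' @export
window_set <- function(values, raw_hr, meta) {
  stopifnot(length(dim(values)) == 3L, dim(values)[3] == 3L,
            nrow(raw_hr) == dim(values)[1], nrow(meta) == dim(values)[1],
            all(c("runner_id", "group", "marker_t", "window_start", "label") %in% names(meta)),
            all(meta$label %in% exertion_levels()))
  rownames(meta) <- NULL
  structure(list(values = values, raw_hr = raw_hr, meta = meta),
            class = "exertr_window_set")
}

empty_window_set <- function(L) {
  window_set(values = array(0, dim = c(0, L, 3)),
             raw_hr = matrix(0, 0, L),
             meta = data.frame(runner_id = character(), group = character(),
                               marker_t = integer(), window_start = integer(),
                               label = character()))
}

#' @export
print.exertr_window_set <- function(x, ...) {
  cat(sprintf("<exertr_window_set> %d windows of length %d, %d runners, labels: %s\n",
              nrow(x$meta), dim(x$values)[2], length(unique(x$meta$runner_id)),
              paste(sprintf("%s=%d", names(table(x$meta$label)), table(x$meta$label)),
                    collapse = ", ")))
  invisible(x)
}

n_windows <- function(ws) nrow(ws$meta)

subset_windows <- function(ws, idx) {
  window_set(values = ws$values[idx, , , drop = FALSE],
             raw_hr = ws$raw_hr[idx, , drop = FALSE],
             meta = ws$meta[idx, , drop = FALSE])
}

bind_window_sets <- function(sets) {
  sets <- Filter(function(s) n_windows(s) > 0L, sets)
  if (length(sets) == 0L) stop("no windows to bind", call. = FALSE)
  L <- dim(sets[[1]]$values)[2]
  n <- sum(vapply(sets, n_windows, integer(1)))
  values <- array(0, dim = c(n, L, 3),
                  dimnames = dimnames(sets[[1]]$values))
  at <- 0L
  for (s in sets) {
    k <- n_windows(s)
    values[(at + 1L):(at + k), , ] <- s$values
    at <- at + k
  }
  window_set(values = values,
             raw_hr = do.call(rbind, lapply(sets, `[[`, "raw_hr")),
             meta = do.call(rbind, lapply(sets, `[[`, "meta")))
}

#' Build a window set for a whole cohort
#'
#' Convenience wrapper applying [zscore_per_runner()] and
#' [extract_windows()] to each session and stacking the results.
#'
#' @param sessions List of [session()] objects.
#' @param params [augmentation_params()].
#' @param stride Window-start stride passed to [extract_windows()].
#' @return A window set.
#' @export
build_window_set <- function(sessions, params = augmentation_params(), stride = 1L) {
  bind_window_sets(lapply(sessions, extract_windows, params = params, stride = stride))
}
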