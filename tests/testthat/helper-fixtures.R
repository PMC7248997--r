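# Shared fixtures and independent oracles, all built in code.

# A small handmade session: 1000 s, linear HR ramp, one report per 300 s.
tiny_session <- function(runner_id = "R1", group = "untrained",
                         duration = 1000, reports = data.frame(t = 300, rpe = 12)) {
  tt <- 0:duration
  session(runner_id = runner_id, group = group, time = tt,
          heart_rate = 120 + 40 * tt / duration,
          cadence = rep(160, length(tt)),
          velocity = rep(3, length(tt)),
          reports = reports, hr_max = 195)
}

# Build a window set directly from a list of L x 3 matrices.
toy_window_set <- function(mats, labels, raw_hr = NULL,
                           runner_id = NULL, marker_t = NULL) {
  n <- length(mats)
  L <- nrow(mats[[1]])
  values <- array(0, dim = c(n, L, 3),
                  dimnames = list(NULL, NULL, c("heart_rate", "cadence", "velocity")))
  for (i in seq_len(n)) values[i, , ] <- mats[[i]]
  if (is.null(raw_hr)) raw_hr <- t(vapply(mats, function(m) m[, 1], numeric(L)))
  if (is.null(runner_id)) runner_id <- rep(c("A", "B"), length.out = n)
  if (is.null(marker_t)) marker_t <- seq_len(n) * 100
  window_set(values = values, raw_hr = raw_hr,
             meta = data.frame(runner_id = runner_id,
                               group = ifelse(runner_id %in% c("A", "C"),
                                              "trained", "untrained"),
                               marker_t = marker_t,
                               window_start = marker_t - 30,
                               label = labels))
}

# Brute-force DTW oracle: minimum over all monotone alignment paths,
# implemented as plain recursion (exponential, for short series only).
dtw_brute <- function(a, b) {
  if (is.vector(a)) a <- matrix(a, ncol = 1)
  if (is.vector(b)) b <- matrix(b, ncol = 1)
  rec <- function(i, j) {
    cost <- sum((a[i, ] - b[j, ])^2)
    if (i == 1 && j == 1) return(cost)
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    cost + best
  }
  rec(nrow(a), nrow(b))
}

# Enumerate all constrained fold plans for small groups (a plan is a
# bijection trained -> untrained), via full permutation enumeration.
enumerate_fold_plans <- function(n) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  perms(seq_len(n))
}

# Cached medium fixtures so several test files can share one simulation.
.fixture_env <- new.env()

default_cohort_windows <- function(seed = 11, stride = 40) {
  key <- sprintf("def_%d_%d", seed, stride)
  if (is.null(.fixture_env[[key]])) {
    co <- simulate_cohort(cohort_config(seed = seed))
    .fixture_env[[key]] <- suppressWarnings(build_window_set(co, stride = stride))
  }
  .fixture_env[[key]]
}

borg_exact_windows <- function(seed = 7, stride = 30) {
  key <- sprintf("be_%d_%d", seed, stride)
  if (is.null(.fixture_env[[key]])) {
    co <- simulate_cohort(borg_exact_config(seed = seed))
    .fixture_env[[key]] <- suppressWarnings(build_window_set(co, stride = stride))
  }
  .fixture_env[[key]]
}

mk_roster <- function(n) data.frame(
  runner_id = c(sprintf("T%02d", seq_len(n)), sprintf("U%02d", seq_len(n))),
  group = rep(c("trained", "untrained"), each = n))
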