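# Synthetic runner-cohort generator.
#
# Emulates the study protocol the pipeline assumes: constant self-selected
# velocity to volitional exhaustion, cardiovascular drift (HR rising at
# constant workload), and sparse Borg-RPE reports at fixed distance
# intervals (every 1 km for untrained, every 5 km for trained runners).

#' Group-level simulation parameters
#'
#' Parameters describing one fitness group of the synthetic cohort. The
#' defaults for the two groups are available via [default_group_params()].
#'
#' @param velocity_mean,velocity_sd_between_runners Group mean and
#'   between-runner SD of running velocity (m/s).
#' @param velocity_noise_sd Within-run GPS jitter SD (m/s).
#' @param duration_mean,duration_sd Run duration mean and SD (s).
#' @param hr_start_frac,hr_end_frac Heart rate at the start/end of the run
#'   as a fraction of `hr_max`; drift rises linearly in elapsed-run fraction
#'   and saturates at `hr_sat_frac` of the run.
#' @param hr_sat_frac Fraction of the run at which the HR ramp saturates.
#' @param hr_noise_sd Within-run HR noise SD (bpm).
#' @param hr_max_mean,hr_max_sd Between-runner distribution of maximal heart
#'   rate (bpm).
#' @param cadence_mean,cadence_sd Group mean and between-runner SD of step
#'   cadence (steps/min).
#' @param cadence_noise_sd Within-run cadence noise SD (steps/min).
#' @param report_interval_m Distance between RPE reports (m).
#' @param rpe_start,rpe_end Borg score at the start and at exhaustion.
#' @param rpe_noise_sd SD of the Gaussian noise added to the latent RPE
#'   before rounding (Borg units).
#' @return A list of class `"exertr_group_params"`.
#' @export
group_params <- function(velocity_mean, velocity_sd_between_runners = 0.3,
                         velocity_noise_sd = 0.15,
                         duration_mean, duration_sd,
                         hr_start_frac, hr_end_frac, hr_sat_frac = 0.9,
                         hr_noise_sd = 2,
                         hr_max_mean, hr_max_sd = 8,
                         cadence_mean, cadence_sd = 8, cadence_noise_sd = 3,
                         report_interval_m,
                         rpe_start = 9, rpe_end = 19, rpe_noise_sd = 0.5) {
  p <- as.list(environment())
  stopifnot(p$hr_start_frac > 0, p$hr_start_frac < p$hr_end_frac,
            p$hr_end_frac <= 1, p$hr_sat_frac > 0, p$hr_sat_frac <= 1,
            p$report_interval_m > 0,
            p$rpe_start >= 6, p$rpe_end <= 20, p$rpe_start < p$rpe_end)
  class(p) <- "exertr_group_params"
  p
}

#' Default group parameters for the synthetic cohort
#'
#' Trained runners: ~4.2 m/s for ~110 min, reporting every 5 km; untrained:
#' ~2.9 m/s for ~75 min, reporting every 1 km. HR drifts from about 70% to
#' about 92--95% of HRmax over the run. These defaults reproduce the study
#' cohort's aggregate structure (about 112 RPE reports in total, short
#' ~6 min inter-report cadence for untrained versus ~20+ min for trained,
#' and a mixed class balance after binarization).
#'
#' @param group `"trained"` or `"untrained"`.
#' @return A [group_params()] object.
#' @export
default_group_params <- function(group = c("trained", "untrained")) {
  group <- match.arg(group)
  if (group == "trained") {
    group_params(velocity_mean = 4.2, duration_mean = 6600, duration_sd = 780,
                 hr_start_frac = 0.70, hr_end_frac = 0.92,
                 hr_max_mean = 190, cadence_mean = 172,
                 report_interval_m = 5000)
  } else {
    group_params(velocity_mean = 2.9, duration_mean = 4500, duration_sd = 830,
                 hr_start_frac = 0.74, hr_end_frac = 0.95,
                 hr_max_mean = 195, cadence_mean = 160,
                 report_interval_m = 1000)
  }
}

#' Cohort configuration
#'
#' @param n_trained,n_untrained Number of runners per group (default 6 + 6).
#' @param seed Integer seed; the same seed yields a bit-identical cohort.
#'   Per-runner random sub-streams are derived from it by counter, so adding
#'   a runner does not perturb the others.
#' @param trained,untrained [group_params()] for each group.
#' @return A list of class `"exertr_cohort_config"`.
#' @export
cohort_config <- function(n_trained = 6, n_untrained = 6, seed = 1,
                          trained = default_group_params("trained"),
                          untrained = default_group_params("untrained")) {
  stopifnot(n_trained >= 1, n_untrained >= 1, is.finite(seed))
  structure(list(n_trained = n_trained, n_untrained = n_untrained,
                 seed = as.integer(seed), trained = trained,
                 untrained = untrained),
            class = "exertr_cohort_config")
}

#' Latent RPE trajectory evaluated at a run fraction
#'
#' The reported Borg score is modelled as a linear rise from `rpe_start` at
#' the start of the run to `rpe_end` at exhaustion, plus Gaussian noise,
#' rounded to the nearest integer and clipped to the Borg range `[6, 20]`.
#' With zero noise the sequence is non-decreasing in `t_frac`.
#'
#' @param t_frac Fraction of the run completed, in `[0, 1]`.
#' @param params A [group_params()] object.
#' @param noise Noise draw(s) in Borg units (default 0).
#' @return Integer Borg score(s).
#' @export
rpe_at <- function(t_frac, params, noise = 0) {
  stopifnot(all(t_frac >= 0 & t_frac <= 1))
  latent <- params$rpe_start + (params$rpe_end - params$rpe_start) * t_frac + noise
  pmin(20L, pmax(6L, as.integer(round(latent))))
}

runner_substream_seed <- function(seed, counter) {
  as.integer((as.double(seed) + 104729 * counter) %% (2^31 - 1))
}

simulate_runner <- function(id, group, p, stream_seed) {
  set.seed(stream_seed)
  for (try in 1:100) {
    duration <- round(stats::rnorm(1, p$duration_mean, p$duration_sd))
    if (duration >= 600) break
    if (try == 100) stop("could not draw a positive run duration", call. = FALSE)
  }
  hr_max <- stats::rnorm(1, p$hr_max_mean, p$hr_max_sd)
  v_runner <- max(0.5, stats::rnorm(1, p$velocity_mean, p$velocity_sd_between_runners))
  cad_runner <- max(60, stats::rnorm(1, p$cadence_mean, p$cadence_sd))
  tt <- 0:duration
  n <- length(tt)
  velocity <- pmax(0, v_runner + stats::rnorm(n, 0, p$velocity_noise_sd))
  cadence <- pmax(0, cad_runner + stats::rnorm(n, 0, p$cadence_noise_sd))
  t_frac <- tt / duration
  ramp <- pmin(t_frac / p$hr_sat_frac, 1)
  hr <- hr_max * (p$hr_start_frac + (p$hr_end_frac - p$hr_start_frac) * ramp) +
    stats::rnorm(n, 0, p$hr_noise_sd)
  hr <- pmin(pmax(hr, 40 + 1e-6), hr_max - 1e-6)
  hr <- pmin(hr, 259.999)
  # RPE reports at each completed report interval of cumulative distance
  dist <- cumsum(velocity)
  n_reports <- floor(dist[n] / p$report_interval_m)
  if (n_reports >= 1) {
    marker_t <- vapply(seq_len(n_reports), function(k) {
      tt[which(dist >= k * p$report_interval_m)[1]]
    }, numeric(1))
    noise <- stats::rnorm(n_reports, 0, p$rpe_noise_sd)
    rpe <- rpe_at(marker_t / duration, p, noise)
    reports <- data.frame(t = marker_t, rpe = rpe)
  } else {
    reports <- data.frame(t = integer(), rpe = integer())
  }
  session(runner_id = id, group = group, time = tt, heart_rate = hr,
          cadence = cadence, velocity = velocity, reports = reports,
          hr_max = hr_max)
}

#' Simulate a synthetic runner cohort
#'
#' Generates one [session()] per runner: a duration drawn from the group
#' distribution, constant velocity plus GPS jitter, constant cadence plus
#' noise, a saturating heart-rate ramp between `hr_start_frac` and
#' `hr_end_frac` of the runner's HRmax (clipped to physiological range), and
#' RPE reports at each completed `report_interval_m` of cumulative distance
#' via [rpe_at()].
#'
#' @param config A [cohort_config()].
#' @return List of [session()] objects (trained runners first).
#' @examples
#' cohort <- simulate_cohort(cohort_config(seed = 42))
#' length(cohort)
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "exertr_cohort_config"))
  counter <- 0L
  sims <- list()
  for (i in seq_len(config$n_trained)) {
    counter <- counter + 1L
    sims[[counter]] <- simulate_runner(sprintf("T%02d", i), "trained",
                                       config$trained,
                                       runner_substream_seed(config$seed, counter))
  }
  for (i in seq_len(config$n_untrained)) {
    counter <- counter + 1L
    sims[[counter]] <- simulate_runner(sprintf("U%02d", i), "untrained",
                                       config$untrained,
                                       runner_substream_seed(config$seed, counter))
  }
  sims
}

#' Cohort where the Borg heart-rate rule is exact
#'
#' A noiseless cohort configuration constructed so that the heart-rate ramp
#' crosses 150 bpm at exactly the run fraction where the latent RPE
#' trajectory crosses the 15/16 class boundary, with enough slack between
#' consecutive reports that no 60 s window within 180 s of a marker
#' straddles the crossing. On such a cohort the Borg rule
#' (mean HR / 10 > 15) classifies every window, hence every label,
#' correctly -- a signal-recovery fixture for end-to-end checks.
#'
#' @param seed Integer seed (the cohort is deterministic anyway; the seed
#'   only fixes the substreams).
#' @return A [cohort_config()].
#' @export
borg_exact_config <- function(seed = 1) {
  # rpe: 9 -> 19 crosses 15.5 at t_frac = 0.65; solve
  # hr_start + (hr_end - hr_start) * 0.65 / 0.9 = 150 / hr_max per group
  frac <- 0.65 / 0.9
  tr_start <- 0.62; tr_max <- 190
  un_start <- 0.60; un_max <- 195
  tr <- default_group_params("trained")
  tr$hr_max_mean <- tr_max
  tr$hr_start_frac <- tr_start
  tr$hr_end_frac <- tr_start + (150 / tr_max - tr_start) / frac
  un <- default_group_params("untrained")
  un$hr_max_mean <- un_max
  un$hr_start_frac <- un_start
  un$hr_end_frac <- un_start + (150 / un_max - un_start) / frac
  noiseless_config(cohort_config(seed = seed, trained = tr, untrained = un))
}

#' Noise-free cohort configuration
#'
#' Returns `config` with every noise source and between-runner spread set to
#' zero. Useful for constructing cohorts with exactly known signal, e.g. a
#' heart-rate ramp crossing 150 bpm precisely when the latent RPE crosses
#' the class boundary.
#'
#' @param config A [cohort_config()].
#' @return A modified [cohort_config()].
#' @export
noiseless_config <- function(config = cohort_config()) {
  zero <- function(p) {
    p$velocity_sd_between_runners <- 0
    p$velocity_noise_sd <- 0
    p$duration_sd <- 0
    p$hr_noise_sd <- 0
    p$hr_max_sd <- 0
    p$cadence_sd <- 0
    p$cadence_noise_sd <- 0
    p$rpe_noise_sd <- 0
    p
  }
  config$trained <- zero(config$trained)
  config$untrained <- zero(config$untrained)
  config
}
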