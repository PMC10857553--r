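#' Configuration of the synthetic vitals simulator
#'
#' Parameters of a seedable generator of ambulatory 1 Hz SpO2/heart-rate
#' traces. The generator emulates the statistical structure the forecasting
#' pipeline assumes in pulse-oximetry data from patients on long-term
#' oxygen therapy: a stable baseline saturation, activity-driven
#' desaturation episodes with a lagged, gradual recovery, measurement noise
#' with integer quantization, heart rate rising with desaturation, and
#' random sample dropouts (the oximeter discards readings whose signal
#' quality it distrusts, leaving timestamp gaps).
#'
#' @param duration trace length in seconds (samples at 1 Hz).
#' @param baseline_spo2 resting saturation, percent.
#' @param episode_rate desaturation episodes per hour (Poisson).
#' @param episode_depth_mean,episode_depth_sd episode depth, percent drop.
#' @param onset_seconds linear descent time from baseline to the trough.
#' @param recovery_tau exponential recovery time constant, seconds.
#' @param dropout_prob per-sample probability a reading is discarded.
#' @param hr_baseline resting heart rate, bpm.
#' @param hr_coupling heart-rate rise per percent of desaturation, bpm.
#' @param hr_noise_sd heart-rate measurement noise, bpm.
#' @param noise_sd SpO2 measurement noise, percent.
#' @param quantize round SpO2 (and hr) to integers, as consumer oximeters
#'   report; disable for noise-free recovery experiments.
#' @param seed integer seed making the trace fully reproducible.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(duration = 3600,
                       baseline_spo2 = 95,
                       episode_rate = 6,
                       episode_depth_mean = 8,
                       episode_depth_sd = 2,
                       onset_seconds = 30,
                       recovery_tau = 45,
                       dropout_prob = 0.02,
                       hr_baseline = 72,
                       hr_coupling = 1.5,
                       hr_noise_sd = 2,
                       noise_sd = 0.4,
                       quantize = TRUE,
                       seed = 1L) {
  if (!is.numeric(duration) || duration <= 0) {
    stop("'duration' must be positive", call. = FALSE)
  }
  if (dropout_prob < 0 || dropout_prob > 1) {
    stop("'dropout_prob' must lie in [0, 1]", call. = FALSE)
  }
  if (recovery_tau <= 0) stop("'recovery_tau' must be positive", call. = FALSE)
  if (episode_rate < 0) stop("'episode_rate' must be non-negative", call. = FALSE)
  if (noise_sd < 0 || hr_noise_sd < 0) stop("noise sds must be non-negative", call. = FALSE)
  if (baseline_spo2 < 50 || baseline_spo2 > 100) {
    stop("'baseline_spo2' must lie in [50, 100]", call. = FALSE)
  }
  structure(list(duration = as.integer(duration),
                 baseline_spo2 = baseline_spo2,
                 episode_rate = episode_rate,
                 episode_depth_mean = episode_depth_mean,
                 episode_depth_sd = episode_depth_sd,
                 onset_seconds = onset_seconds,
                 recovery_tau = recovery_tau,
                 dropout_prob = dropout_prob,
                 hr_baseline = hr_baseline,
                 hr_coupling = hr_coupling,
                 hr_noise_sd = hr_noise_sd,
                 noise_sd = noise_sd,
                 quantize = isTRUE(quantize),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic desaturation profile: linear onset, exponential recovery
episode_effect <- function(t, onset, depth, onset_seconds, tau) {
  dt <- t - onset
  eff <- numeric(length(t))
  rising <- dt >= 0 & dt < onset_seconds
  eff[rising] <- -depth * dt[rising] / onset_seconds
  after <- dt >= onset_seconds
  eff[after] <- -depth * exp(-(dt[after] - onset_seconds) / tau)
  eff
}

#' Simulate a 1 Hz vital-sign trace
#'
#' Draws desaturation episodes as a Poisson process over the trace
#' duration; each episode descends linearly from baseline over
#' `onset_seconds` to a Gaussian-depth trough and recovers exponentially
#' with time constant `recovery_tau` (overlapping episodes add). Gaussian
#' measurement noise is applied, values are clamped to \[50, 100\] and
#' optionally quantized to integer percent. Heart rate follows
#' `hr_baseline + hr_coupling * desaturation` plus noise. Finally each
#' sample is independently discarded with probability `dropout_prob`,
#' producing the timestamp-gap structure [segment_continuous()] handles.
#'
#' @param config a [sim_config()].
#' @return a [vital_trace()] with attribute `"episodes"` (data frame of
#'   drawn onsets and depths, for diagnostics).
#' @export
simulate_trace <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$duration
  t <- seq_len(n) - 1

  n_ep <- rpois(1, config$episode_rate * n / 3600)
  onsets <- sort(runif(n_ep, 0, n))
  depths <- pmax(0, rnorm(n_ep, config$episode_depth_mean, config$episode_depth_sd))

  clean <- rep(config$baseline_spo2, n)
  for (k in seq_len(n_ep)) {
    clean <- clean + episode_effect(t, onsets[k], depths[k],
                                    config$onset_seconds, config$recovery_tau)
  }
  clean <- pmin(100, pmax(50, clean))

  spo2 <- clean + rnorm(n, 0, config$noise_sd)
  spo2 <- pmin(100, pmax(50, spo2))
  desat <- config$baseline_spo2 - clean
  hr <- config$hr_baseline + config$hr_coupling * desat +
    rnorm(n, 0, config$hr_noise_sd)
  hr <- pmin(220, pmax(30, hr))
  if (config$quantize) {
    spo2 <- round(spo2)
    hr <- round(hr)
  }

  keep <- runif(n) >= config$dropout_prob
  out <- vital_trace(t[keep], spo2[keep], hr = hr[keep])
  attr(out, "episodes") <- data.frame(onset = onsets, depth = depths)
  attr(out, "config") <- config
  out
}

patient_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + 7919 * i) %% (2^31 - 1))
}

#' Simulate one patient of a heterogeneous cohort
#'
#' Patient-level physiology (baseline saturation, episode rate and depth,
#' recovery speed, resting heart rate) is perturbed deterministically from
#' the cohort master seed, so any single patient can be regenerated in
#' isolation and exactly matches the cohort call.
#'
#' @param i patient index (1-based).
#' @param base_config cohort-level [sim_config()]; per-patient seeds are
#'   derived from `seed`, ignoring `base_config$seed`.
#' @param seed cohort master seed.
#' @return a [vital_trace()] with `patient_id` `"P<i>"`.
#' @export
simulate_patient <- function(i, base_config = sim_config(), seed = 1L) {
  ps <- patient_seed(seed, i)
  set.seed(ps)
  cfg <- base_config
  cfg$baseline_spo2 <- min(99, max(85, base_config$baseline_spo2 + runif(1, -5, 1)))
  cfg$episode_rate <- base_config$episode_rate * runif(1, 0.5, 2)
  cfg$episode_depth_mean <- max(1, base_config$episode_depth_mean + runif(1, -3, 3))
  cfg$recovery_tau <- base_config$recovery_tau * runif(1, 0.6, 1.6)
  cfg$hr_baseline <- base_config$hr_baseline + runif(1, -10, 10)
  cfg$seed <- patient_seed(ps, 1L)
  out <- simulate_trace(cfg)
  attr(out, "patient_id") <- paste0("P", i)
  out
}

#' Simulate a cohort of heterogeneous patients
#'
#' @param n_patients number of patients (>= 1).
#' @inheritParams simulate_patient
#' @return a list of [vital_trace()] objects, one per patient.
#' @export
simulate_cohort <- function(n_patients, base_config = sim_config(), seed = 1L) {
  stopifnot(n_patients >= 1)
  lapply(seq_len(n_patients), simulate_patient,
         base_config = base_config, seed = seed)
}
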