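#' Ground-truth parameters for a synthetic study
#'
#' Bundles everything the generator controls so downstream recovery can be
#' asserted: per-subject latent exertion in each work period, the
#' heart-rate gain translating exertion to beats per minute, the EMG
#' spectral-compression (fatigue) parameters, the rating--exertion rank
#' correlation, and noise scales.
#'
#' Latent exertion is drawn per subject and period on `[0, 1]`. Defaults
#' emulate the orchard-harvesting cohort the package targets: ladder work
#' is the most strenuous, the post-break period is near-rest, and the
#' afternoon bout is slightly harder than the morning one. Exertion at T0
#' (pre-shift) is 0 by construction.
#'
#' @param roster data.frame from [simulate_cohort()].
#' @param hr_gain bpm of heart-rate elevation per unit latent exertion.
#' @param hr_baseline_mean,hr_baseline_sd sitting heart-rate distribution
#'   across subjects (bpm).
#' @param hr_noise_sd additive Gaussian noise on the 1-Hz series (bpm).
#' @param hr_spike_rate per-sample probability of an isolated spike
#'   artifact (for median-filter testing).
#' @param group_exertion named mean latent exertion per group (work bouts).
#' @param exertion_sd between-subject exertion SD within group.
#' @param exertion_t2 mean latent exertion during the break-recovery
#'   period (surveyed at T2).
#' @param emg_mdf_intercept population median-power-frequency at work
#'   start (Hz).
#' @param emg_mdf_slope_true programmed MDF drift in Hz per work minute
#'   (negative = fatigue).
#' @param emg_slope_sd between-subject SD of the true slope (Hz/min);
#'   gives subjects distinct fatigue rates so cross-subject associations
#'   are estimable.
#' @param emg_intercept_sd between-subject SD of the MDF intercept (Hz).
#' @param emg_side_offset Hz added to the non-dominant side's intercept
#'   (the bilateral asymmetry that makes pooled MDF distributions bimodal).
#' @param emg_band_width width of the EMG spectral envelope (Hz); the
#'   generator's "spectral noise" scale.
#' @param emg_amp_rms RMS amplitude of the simulated EMG (mV).
#' @param emg_contam_windows number of 10-min windows per recording to
#'   contaminate (clipping or in-band interference) for anomaly-screen
#'   testing; 0 = clean.
#' @param emg_stochastic if `FALSE`, generate a deterministic
#'   constant-amplitude tone tracking the programmed MDF instead of random
#'   band-limited noise (the generator's zero-noise limit).
#' @param rating_rank_correlation target population Spearman correlation
#'   between each rating scale and latent exertion, in `[-1, 1]`.
#' @param seed integer; per-subject streams are derived from it.
#' @return an object of class `ground_truth`: the parameters above plus
#'   `exertion`, a subjects x periods (T1, T2, T3) matrix, and per-subject
#'   vectors `hr_baseline`, `emg_intercept` (per side) and `emg_slope`.
#' @export
ground_truth <- function(roster,
                         hr_gain = 60,
                         hr_baseline_mean = 72, hr_baseline_sd = 5,
                         hr_noise_sd = 3,
                         hr_spike_rate = 0.002,
                         group_exertion = c(Ground = 0.45, Ladder = 0.60,
                                            Platform = 0.40),
                         exertion_sd = 0.10,
                         exertion_t2 = 0.10,
                         emg_mdf_intercept = 80,
                         emg_mdf_slope_true = -0.01,
                         emg_slope_sd = 0.004,
                         emg_intercept_sd = 5,
                         emg_side_offset = 8,
                         emg_band_width = 40,
                         emg_amp_rms = 0.1,
                         emg_contam_windows = 0,
                         emg_stochastic = TRUE,
                         rating_rank_correlation = 0.6,
                         seed = 1L) {
  stopifnot(is.data.frame(roster), all(c("subject_id", "group") %in% names(roster)))
  if (abs(rating_rank_correlation) > 1)
    stop_param("|rating_rank_correlation| must be <= 1")
  if (hr_noise_sd < 0 || emg_band_width <= 0)
    stop_param("noise scales must be non-negative")
  n <- nrow(roster)
  with_seed(derive_seed(seed, "truth"), {
    gmean <- group_exertion[roster$group]
    gmean[is.na(gmean)] <- mean(group_exertion)
    clamp01 <- function(x) pmin(1, pmax(0, x))
    e1 <- clamp01(stats::rnorm(n, gmean, exertion_sd))
    e2 <- clamp01(stats::rnorm(n, exertion_t2, exertion_sd / 2))
    e3 <- clamp01(stats::rnorm(n, gmean + 0.05, exertion_sd))
    exertion <- cbind(T1 = e1, T2 = e2, T3 = e3)
    rownames(exertion) <- roster$subject_id
    hr_baseline <- stats::rnorm(n, hr_baseline_mean, hr_baseline_sd)
    emg_slope <- stats::rnorm(n, emg_mdf_slope_true, emg_slope_sd)
    base_int <- stats::rnorm(n, emg_mdf_intercept, emg_intercept_sd)
    dom <- roster$dominant_side %||% rep("right", n)
    emg_intercept <- cbind(
      left  = base_int + ifelse(dom == "left", 0, emg_side_offset),
      right = base_int + ifelse(dom == "right", 0, emg_side_offset))
    rownames(emg_intercept) <- roster$subject_id
    names(hr_baseline) <- names(emg_slope) <- roster$subject_id
    structure(list(
      exertion = exertion, hr_gain = hr_gain,
      hr_baseline = hr_baseline, hr_noise_sd = hr_noise_sd,
      hr_spike_rate = hr_spike_rate,
      emg_mdf_intercept = emg_mdf_intercept,
      emg_mdf_slope_true = emg_mdf_slope_true,
      emg_intercept = emg_intercept, emg_slope = emg_slope,
      emg_band_width = emg_band_width, emg_amp_rms = emg_amp_rms,
      emg_contam_windows = emg_contam_windows,
      emg_stochastic = emg_stochastic,
      rating_rank_correlation = rating_rank_correlation,
      seed = as.integer(seed)), class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "Ground truth: %d subjects | hr_gain %.0f bpm/unit | MDF slope %.4f Hz/min | rating rank-cor %.2f\n",
    nrow(x$exertion), x$hr_gain, x$emg_mdf_slope_true, x$rating_rank_correlation))
  invisible(x)
}
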