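test_that("cohort generation matches the requested design", {
  roster <- simulate_cohort(cohort_spec(8, seed = 4))
  expect_equal(nrow(roster), 24)
  expect_equal(as.vector(table(roster$group)), rep(8L, 3))
  expect_true(all(roster$age >= 18 & roster$age <= 47))
  expect_equal(nrow(simulate_cohort(cohort_spec(1, "Solo"))), 1)
  expect_error(cohort_spec(0), "positive")
  expect_error(cohort_spec(8, age_range = c(10, 40)), "age_range")
})

test_that("generators are bit-reproducible under a fixed seed", {
  sch <- short_schedule()
  roster <- tiny_roster(seed = 9)
  tr <- ground_truth(roster, seed = 9, emg_contam_windows = 1)
  a <- simulate_heart_rate(roster[1, ], sch, tr)
  b <- simulate_heart_rate(roster[1, ], sch, tr)
  expect_identical(a, b)
  e1 <- simulate_emg(roster[1, ], sch, tr)
  e2 <- simulate_emg(roster[1, ], sch, tr)
  expect_identical(e1, e2)
  expect_identical(simulate_surveys(roster, tr), simulate_surveys(roster, tr))
  expect_identical(simulate_cohort(cohort_spec(2, seed = 5)),
                   simulate_cohort(cohort_spec(2, seed = 5)))
})

test_that("all generated samples lie inside the declared recording intervals", {
  sch <- demo_schedule()
  roster <- tiny_roster(seed = 2)
  tr <- ground_truth(roster, seed = 2)
  hr <- simulate_heart_rate(roster[1, ], sch, tr)
  expect_true(all(hr$time >= sch$hr_windows$T0[1] & hr$time < sch$shift_end))
  emg <- simulate_emg(roster[1, ], sch, tr, sides = "left")$left
  expect_equal(length(emg$samples),
               (sch$shift_end - sch$shift_start) * emg$sampling_rate)
  expect_equal(emg$start_time, sch$shift_start)
})

test_that("heart-rate generator hits its closed-form work-period mean", {
  sch <- short_schedule()
  roster <- tiny_roster(seed = 21)
  # null workload: work mean equals sitting mean within noise
  tr0 <- ground_truth(roster, seed = 21, hr_spike_rate = 0,
                      group_exertion = c(Ground = 0), exertion_sd = 0,
                      exertion_t2 = 0)
  hr0 <- simulate_heart_rate(roster[1, ], sch, tr0)
  f0 <- moving_median_filter(hr0)
  sit <- period_mean(f0, sch$hr_windows$T0)
  wrk <- period_mean(f0, sch$hr_windows$T1)
  sem <- tr0$hr_noise_sd * sqrt(1 / sit$n + 1 / wrk$n)
  expect_lt(abs(wrk$mean_bpm - sit$mean_bpm), 3 * sem)
  # programmed gain: hr_gain = 60 at exertion 0.5 raises the mean 30 bpm
  tr <- ground_truth(roster, seed = 21, hr_gain = 60, hr_spike_rate = 0,
                     group_exertion = c(Ground = 0.5), exertion_sd = 0,
                     exertion_t2 = 0.5)
  hr <- simulate_heart_rate(roster[1, ], sch, tr)
  raw_sit <- mean(hr$bpm[hr$time < sch$shift_start])
  raw_t1 <- mean(hr$bpm[hr$time >= sch$hr_windows$T1[1] &
                          hr$time < sch$hr_windows$T1[2]])
  sem <- tr$hr_noise_sd * sqrt(1 / 900 + 1 / 600)
  expect_lt(abs((raw_t1 - raw_sit) - 30), 2 * sem + 0.5)
})

test_that("spike-free series is the piecewise profile plus Gaussian noise", {
  sch <- short_schedule()
  roster <- tiny_roster(seed = 5)
  tr <- ground_truth(roster, seed = 5, hr_spike_rate = 0)
  hr <- simulate_heart_rate(roster[1, ], sch, tr)
  base <- tr$hr_baseline[[1]]
  pre <- hr$bpm[hr$time < sch$shift_start] - base
  expect_lt(abs(mean(pre)), 4 * tr$hr_noise_sd / sqrt(length(pre)))
  expect_lt(abs(sd(pre) - tr$hr_noise_sd), 0.5)
  expect_lt(max(abs(pre)), 6 * tr$hr_noise_sd)  # no spikes present
})

test_that("EMG generator enforces the analysis band and controls the spectrum", {
  sch <- short_schedule()
  roster <- tiny_roster(seed = 6)
  tr_bad <- ground_truth(roster, seed = 6, emg_mdf_intercept = 30,
                         emg_slope_sd = 0, emg_intercept_sd = 0,
                         emg_side_offset = 0)
  expect_error(simulate_emg(roster[1, ], sch, tr_bad, sides = "left"),
               "20, 450")
  tr <- ground_truth(roster, seed = 6, emg_mdf_intercept = 90,
                     emg_mdf_slope_true = 0, emg_slope_sd = 0,
                     emg_intercept_sd = 0, emg_side_offset = 0)
  rec <- simulate_emg(roster[1, ], sch, tr, sides = "left")$left
  expect_lt(abs(sqrt(mean(rec$samples^2)) - tr$emg_amp_rms),
            0.05 * tr$emg_amp_rms)
  psd <- welch_psd(rec$samples[1:600000], rec$sampling_rate)
  expect_lt(abs(median_power_frequency(psd) - 90), 1.5)
})

test_that("null-fatigue EMG has a flat windowed MDF profile", {
  sch <- short_schedule()
  roster <- tiny_roster(seed = 31)
  tr <- ground_truth(roster, seed = 31, emg_mdf_slope_true = 0,
                     emg_slope_sd = 0)
  rec <- simulate_emg(roster[1, ], sch, tr, sides = "left")$left
  f <- emg_window_features(emg_bandpass(rec), sch)
  sl <- fit_fatigue_slope(f)
  # slope indistinguishable from zero at the estimator's own scale
  expect_lt(abs(sl$b_time), 3 * sl$stderr + 0.005)
})

test_that("programmed spectral compression reaches the final window", {
  # intercept 80 Hz, slope -0.05 Hz/min: after the 40 work minutes of the
  # short day the last work window (mid at 35 min) is centred near 78.25 Hz
  sch <- short_schedule()
  roster <- tiny_roster(seed = 41)
  tr <- ground_truth(roster, seed = 41, emg_mdf_intercept = 80,
                     emg_mdf_slope_true = -0.05, emg_slope_sd = 0,
                     emg_intercept_sd = 0, emg_side_offset = 0)
  rec <- simulate_emg(roster[1, ], sch, tr, sides = "left")$left
  f <- emg_window_features(emg_bandpass(rec), sch)
  last <- f[!f$in_break & f$window_index == max(f$window_index[!f$in_break]), ]
  expect_lt(abs(last$mdf - (80 - 0.05 * last$t_mid)), 1.5)
})

test_that("survey ratings respect scale ranges and follow exertion when noiseless", {
  roster <- simulate_cohort(cohort_spec(2, seed = 13))
  tr <- ground_truth(roster, seed = 13, rating_rank_correlation = 1)
  sv <- simulate_surveys(roster, tr)
  borg <- sv[sv$scale == "BorgRPE", ]
  omni <- sv[sv$scale == "OmniRPE", ]
  cr <- sv[sv$scale == "BorgCR10", ]
  expect_true(all(borg$value >= 6 & borg$value <= 20))
  expect_true(all(omni$value >= 0 & omni$value <= 10))
  expect_true(all(cr$value >= 0 & cr$value <= 10))
  expect_true(all(cr$value * 2 == round(cr$value * 2)))  # half steps
  # with weight 1 the rating is a monotone function of latent exertion
  ex <- cbind(T0 = 0, tr$exertion)
  ev <- mapply(function(s, t) ex[s, t], borg$subject_id, borg$timepoint)
  ord <- order(ev)
  expect_true(all(diff(borg$value[ord]) >= 0))
  # where the map is injective the sample Spearman is exactly 1
  keep <- !duplicated(ev) & !duplicated(borg$value) & ev > 0
  expect_equal(suppressWarnings(
    cor(borg$value[keep], ev[keep], method = "spearman")), 1)
})

test_that("zero rank-correlation surveys are uncorrelated with exertion on average", {
  roster <- simulate_cohort(cohort_spec(8, seed = 17))
  rhos <- replicate(200, NA_real_)
  for (i in seq_len(200)) {
    tr <- ground_truth(roster, seed = 1000 + i, rating_rank_correlation = 0)
    sv <- simulate_surveys(roster, tr)
    om <- sv[sv$scale == "OmniRPE" & sv$timepoint != "T0", ]
    ex <- tr$exertion
    ev <- mapply(function(s, t) ex[s, t], om$subject_id, om$timepoint)
    rhos[i] <- suppressWarnings(cor(om$value, ev, method = "spearman"))
  }
  se <- sd(rhos) / sqrt(length(rhos))
  expect_lt(abs(mean(rhos)), 2.5 * se + 0.005)
})

test_that("equal exertion everywhere gives symmetric zero-median deltas", {
  roster <- simulate_cohort(cohort_spec(60, seed = 19))
  tr <- ground_truth(roster, seed = 19, rating_rank_correlation = 0.6,
                     group_exertion = c(Ground = 0, Ladder = 0,
                                        Platform = 0),
                     exertion_sd = 0, exertion_t2 = 0)
  tr$exertion[] <- 0  # flatten the afternoon uptick too
  sv <- simulate_surveys(roster, tr)
  d <- delta_from_baseline(sv)
  # all latent exertion tied: ratings are exchangeable noise, so deltas
  # from baseline are symmetric about zero
  expect_lte(abs(median(d$delta[d$scale == "BorgRPE"])), 1)
})
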