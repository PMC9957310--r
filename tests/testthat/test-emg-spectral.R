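fs <- 1000

test_that("band-pass meets stop-band and pass-band specs on sine probes", {
  t <- seq_len(20 * fs) / fs
  rms <- function(x) sqrt(mean(x^2))
  x5 <- sin(2 * pi * 5 * t)
  expect_lt(rms(emg_bandpass(x5)) / rms(x5), 0.01)
  x100 <- sin(2 * pi * 100 * t)
  expect_gt(rms(emg_bandpass(x100)) / rms(x100), 0.95)
  # >= 40 dB one octave beyond each cutoff (10 Hz and 900 -> use 450*2 alias-free probe at 900/2)
  x10 <- sin(2 * pi * 10 * t)
  expect_lt(20 * log10(rms(emg_bandpass(x10)) / rms(x10)), -40)
  expect_error(emg_bandpass(x5, low = 500, high = 100), "band")
})

test_that("frequency-domain band-pass matches signal::filtfilt away from edges", {
  set.seed(3)
  x <- rnorm(20000)
  ba <- signal::butter(4, c(20, 450) / (fs / 2), type = "pass")
  ours <- emg_bandpass(x)
  ref <- signal::filtfilt(ba, x)
  expect_lt(max(abs(ours - ref)[5000:15000]), 1e-9)
})

test_that("white noise keeps a flat pass-band PSD after filtering", {
  set.seed(8)
  x <- emg_bandpass(rnorm(120 * fs))
  p <- welch_psd(x, fs)
  inband <- p$freq >= 60 & p$freq <= 350   # well inside the 20-450 band
  # flat: deciles of the in-band PSD within 15% of its median
  expect_lt(abs(quantile(p$power[inband], 0.1) / median(p$power[inband]) - 1), 0.2)
  expect_lt(abs(quantile(p$power[inband], 0.9) / median(p$power[inband]) - 1), 0.2)
  # density level: Parseval, total band power equals the signal variance
  df <- p$freq[2] - p$freq[1]
  expect_lt(abs(sum(p$power) * df / mean(x^2) - 1), 0.02)
  # and the in-band shape agrees with an independent periodogram oracle
  pg <- spec.pgram(ts(x, frequency = fs), plot = FALSE, taper = 0,
                   spans = 51)
  oband <- pg$freq >= 60 & pg$freq <= 350
  ratio <- median(p$power[inband]) / (2 * median(pg$spec[oband]))
  expect_lt(abs(ratio - 1), 0.1)
})

test_that("median power frequency follows its cumulative-interpolation rule", {
  expect_equal(median_power_frequency(list(freq = c(100, 150, 200),
                                           power = c(0, 1, 0))), 150)
  # equal mass at 100 and 200 Hz: crossing interpolates to the midpoint
  expect_equal(median_power_frequency(list(freq = c(100, 200),
                                           power = c(1, 1))), 150)
  expect_equal(median_power_frequency(list(freq = 20:450,
                                           power = rep(1, 431))), 235)
  expect_error(median_power_frequency(list(freq = 20:450,
                                           power = rep(0, 431))),
               "zero total")
  # hand-computed asymmetric case: power 1,2,1 at 100,110,120
  # cumulative-at-centre: 0.5, 2, 3.5; target 2 -> exactly 110
  expect_equal(median_power_frequency(list(freq = c(100, 110, 120),
                                           power = c(1, 2, 1))), 110)
})

test_that("mean power frequency is the power-weighted band average", {
  expect_equal(mean_power_frequency(list(freq = c(100, 200),
                                         power = c(1, 3))), 175)
  expect_equal(mean_power_frequency(list(freq = 20:450,
                                         power = rep(1, 431))), 235)
})

test_that("a pure tone lands in its own frequency bin", {
  t <- seq_len(60 * fs) / fs
  p <- welch_psd(sin(2 * pi * 100 * t), fs)
  expect_lt(abs(median_power_frequency(p) - 100), 1)  # one 1-Hz bin
  expect_lt(abs(mean_power_frequency(p) - 100), 1)
})

test_that("MDF scales with time compression and ignores amplitude scaling", {
  set.seed(12)
  # confine the signal to 30-110 Hz so doubling stays inside the band
  x <- emg_bandpass(rnorm(60 * fs), low = 30, high = 110)
  mdf1 <- median_power_frequency(welch_psd(x, fs))
  # decimation by 2 at unchanged nominal fs compresses time by factor 2
  mdf2 <- median_power_frequency(welch_psd(x[seq(1, length(x), 2)], fs))
  expect_lt(abs(mdf2 / mdf1 - 2), 0.05)
  mdf_scaled <- median_power_frequency(welch_psd(7.3 * x, fs))
  expect_equal(mdf_scaled, mdf1, tolerance = 1e-12)
})
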