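test_that("moving median removes isolated spikes and keeps constants", {
  expect_equal(moving_median_filter(c(60, 60, 200, 60, 60), 5),
               c(60, 60, 60, 60, 60))
  expect_equal(moving_median_filter(rep(72, 10)), rep(72, 10))
  expect_error(moving_median_filter(1:10, 4), "odd")
})

test_that("moving median equals the brute-force sorted median everywhere", {
  set.seed(42)
  for (window in c(3, 5, 7)) {
    x <- rnorm(100, 80, 10)
    expect_equal(moving_median_filter(x, window),
                 brute_moving_median(x, window))
  }
  # series shorter than the window still works via shrunken windows
  x <- c(5, 1, 9)
  expect_equal(moving_median_filter(x, 5), brute_moving_median(x, 5))
})

test_that("filter is idempotent on monotone segments longer than the window", {
  x <- sort(rnorm(50))
  once <- moving_median_filter(x, 5)
  expect_equal(moving_median_filter(once, 5), once)
  expect_equal(once[3:48], x[3:48])  # interior of a monotone series unchanged
})

test_that("period means average the window and report coverage", {
  ser <- structure(list(subject_id = "a", time = 0:99,
                        bpm = c(rep(70, 50), rep(90, 50))),
                   class = "hr_series")
  expect_equal(period_mean(ser, c(0, 100))$mean_bpm, 80)
  expect_equal(period_mean(ser, c(0, 50))$mean_bpm, 70)
  pm <- period_mean(ser, c(50, 200))
  expect_equal(pm$coverage, 50 / 150)
  expect_true(pm$low_coverage)
  expect_error(period_mean(ser, c(200, 260)), "no heart-rate samples")
})

test_that("percent heart-rate reserve evaluates the age-predicted formulas", {
  r <- compute_hrr(130, 70, 20)
  expect_equal(r$hr_rest, 60)
  expect_equal(r$hr_max, 200)
  expect_equal(r$hrr, 0.5)
  expect_equal(r$hrr_sqrt, sqrt(0.5))
  expect_false(r$out_of_range)
  expect_equal(compute_hrr(60, 70, 20)$hrr, 0)   # hr_work = hr_rest
  expect_equal(compute_hrr(200, 70, 20)$hrr, 1)  # hr_work = hr_max
  over <- compute_hrr(210, 70, 20)
  expect_gt(over$hrr, 1)          # flagged, never clipped
  expect_true(over$out_of_range)
  under <- compute_hrr(50, 70, 20)
  expect_lt(under$hrr, 0)
  expect_true(is.na(under$hrr_sqrt))
  expect_error(compute_hrr(100, 230, 20), "degenerate")
})

test_that("reserve is monotone in working and sitting heart rate", {
  hw <- seq(80, 180, by = 10)
  vals <- vapply(hw, function(h) compute_hrr(h, 70, 30)$hrr, numeric(1))
  expect_true(all(diff(vals) > 0))
  hs <- seq(60, 90, by = 5)
  vals <- vapply(hs, function(s) compute_hrr(120, s, 30)$hrr, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("square-root transform reports honest normality diagnostics", {
  r <- sqrt_transform_with_normality(c(0, 1, 0.25))
  expect_equal(r$transformed, c(0, 1, 0.5))
  r2 <- sqrt_transform_with_normality(c(-0.1, 0.25, 0.16, 0.09, 0.5))
  expect_equal(r2$n_excluded_negative, 1)
  expect_equal(length(r2$transformed), 4)
  tiny <- sqrt_transform_with_normality(c(0.2, 0.3))
  expect_true(is.na(tiny$shapiro_before$p_value))
  expect_equal(tiny$transformed, sqrt(c(0.2, 0.3)))
})

test_that("transform typically improves normality of squared-normal data", {
  set.seed(7)
  wins <- replicate(200, {
    x <- rnorm(30)^2  # right-skewed, sqrt brings it to |N(0,1)|
    r <- sqrt_transform_with_normality(x)
    r$shapiro_after$p_value > r$shapiro_before$p_value
  })
  expect_gt(mean(wins), 0.9)
})

test_that("hrr table recovers the generator's closed-form reserve as noise -> 0", {
  sch <- short_schedule()
  roster <- tiny_roster(seed = 23)
  tr <- ground_truth(roster, seed = 23, hr_noise_sd = 1e-6,
                     hr_spike_rate = 0)
  hr <- simulate_heart_rate(roster[1, ], sch, tr)
  tab <- hrr_table(stats::setNames(list(hr), roster$subject_id),
                   roster, sch)
  base <- tr$hr_baseline[[1]]
  expected <- (tr$hr_gain * tr$exertion[1, ] + 10) /
    (220 - roster$age[1] - base + 10)
  expect_equal(tab$hrr, unname(expected), tolerance = 1e-4)
  expect_equal(tab$hrr_sqrt, unname(sqrt(expected)), tolerance = 1e-4)
})
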