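# Shared fixtures: compressed schedules and tiny cohorts keep the signal
# tests fast; full-day defaults are exercised in the acceptance suite.

# 50-minute day: one 30-min work bout, 10-min break, 10-min closing bout.
short_schedule <- function() {
  shift_schedule(shift_start = "7:30", break_start = "8:00",
                 break_end = "8:10", shift_end = "8:20")
}

demo_schedule <- function() shift_schedule(preset = "demo")

tiny_roster <- function(n_per_group = 1, groups = "Ground", seed = 1) {
  simulate_cohort(cohort_spec(n_per_group, groups, c(18, 47), seed))
}

# Brute-force centred moving median; edge windows shrink symmetrically
# (always odd), so the median is a sorted middle element.
brute_moving_median <- function(x, window) {
  h <- (window - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    hh <- min(h, i - 1, n - i)
    w <- sort(x[(i - hh):(i + hh)])
    w[hh + 1]
  }, numeric(1))
}

# Normal-equations least squares, the regression oracle.
brute_ols <- function(X, y) solve(t(X) %*% X, t(X) %*% y)

# Brute-force Kruskal-Wallis H with tie correction.
brute_kw_H <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(g) length(g) * mean(g)^2)) -
    3 * (N + 1)
  tie <- table(values)
  H / (1 - sum(tie^3 - tie) / (N^3 - N))
}
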