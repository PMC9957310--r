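test_that("Pearson correlation matches its closed form and catches degeneracy", {
  x <- c(1.2, 3.4, 2.2, 5.6, 4.1, 0.3)
  y <- c(2.0, 3.1, 2.8, 6.0, 3.9, 1.1)
  pc <- pearson_correlation(x, y)
  r_brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pc$r, r_brute, tolerance = 1e-12)
  expect_equal(pc$n, 6)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_error(pearson_correlation(x, rep(1, 6)), "zero variance")
  expect_error(pearson_correlation(x[1:2], y[1:2]), "at least 3")
})

test_that("Spearman correlation is the mid-rank Pearson, ties included", {
  x <- c(1, 2, 2, 3, 5, 5, 5)
  y <- c(2, 1, 4, 4, 6, 7, 7)
  sc <- spearman_correlation(x, y)
  rx <- rank(x); ry <- rank(y)
  brute <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(sc$rho, brute, tolerance = 1e-12)
  expect_equal(spearman_correlation(1:8, exp(1:8))$rho, 1)
  expect_equal(spearman_correlation(1:8, -(1:8)^3)$rho, -1)
})

test_that("adjusted regression reduces to unadjusted when covariates are constant", {
  set.seed(2)
  d <- data.frame(y = rnorm(20), x = rnorm(20), period = "T1",
                  group = "Ground", stringsAsFactors = FALSE)
  adj <- adjusted_regression(d, "y", "x")
  un <- stats::lm(y ~ x, data = d)
  expect_equal(adj$estimate, unname(coef(un)[2]), tolerance = 1e-12)
  expect_equal(adj$covariates, "")
})

test_that("adjustment reproduces a Simpson-style sign reversal exactly", {
  # two periods; within each, y falls with x; across periods both rise
  d <- expand.grid(i = 1:10, period = c("T1", "T3"),
                   stringsAsFactors = FALSE)
  d$x <- d$i + ifelse(d$period == "T3", 10, 0)
  d$y <- -0.5 * d$i + ifelse(d$period == "T3", 10, 0)
  d$group <- "Ground"
  un <- pearson_correlation(d$x, d$y)
  expect_gt(un$r, 0)                      # confounded: positive
  adj <- suppressWarnings(adjusted_regression(d, "y", "x"))
  expect_lt(adj$estimate, 0)              # adjusted: negative
  X <- stats::model.matrix(~ x + factor(period), data = d)
  beta <- brute_ols(X, d$y)
  expect_equal(adj$estimate, beta[2], tolerance = 1e-10)
})

test_that("estimates are invariant to affine predictor rescaling", {
  set.seed(9)
  d <- data.frame(y = rnorm(30), x = rnorm(30),
                  period = rep(c("T1", "T2", "T3"), 10),
                  group = rep(c("a", "b"), 15), stringsAsFactors = FALSE)
  a1 <- adjusted_regression(d, "y", "x")
  d2 <- d; d2$x <- 10 * d$x + 4
  a2 <- adjusted_regression(d2, "y", "x")
  expect_equal(a2$estimate, a1$estimate / 10, tolerance = 1e-10)
  expect_equal(a2$p_value, a1$p_value, tolerance = 1e-10)
  expect_equal(pearson_correlation(d2$x, d$y)$r,
               pearson_correlation(d$x, d$y)$r, tolerance = 1e-12)
})

test_that("stratified association handles single strata and small strata", {
  set.seed(4)
  d <- data.frame(y = rnorm(24), x = rnorm(24),
                  period = rep(c("T1", "T2", "T3"), 8),
                  group = "Ground", stringsAsFactors = FALSE)
  s <- stratified_association(d, "y", "x", by = "group")
  a <- adjusted_regression(d, "y", "x", covariates = "period")
  expect_equal(nrow(s), 1)
  expect_equal(s$estimate, a$estimate)
  tiny <- d[1:2, ]
  s2 <- stratified_association(tiny, "y", "x", by = "group")
  expect_true(is.na(s2$estimate))  # reported missing, not dropped
})

test_that("two-way ANOVA with Tukey flags a shifted group", {
  set.seed(6)
  d <- expand.grid(subject = 1:8, group = c("Ground", "Ladder", "Platform"),
                   period = c("T1", "T2", "T3"), stringsAsFactors = FALSE)
  d$hrr_sqrt <- rnorm(nrow(d), 0.6, 0.05) +
    ifelse(d$group == "Ladder", 0.2, 0)
  r <- group_time_effects_hrr(d)
  expect_equal(nrow(r$tukey_group), 3)
  expect_lt(r$anova$p_value[r$anova$factor == "group"], 1e-6)
  lad <- grepl("Ladder", r$tukey_group$pair)
  expect_true(all(r$tukey_group$p_adj[lad] < 0.001))
  expect_true(all(r$tukey_group$p_adj[!lad] > 0.05))
  # two groups reduce Tukey to a single pair
  r2 <- group_time_effects_hrr(d[d$group != "Platform", ])
  expect_equal(nrow(r2$tukey_group), 1)
})

test_that("Kruskal-Wallis H and Dunn z match brute-force rank computation", {
  values <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8)
  groups <- rep(c("a", "b", "c"), each = 4)
  r <- group_effects_nonparametric(values, groups)
  expect_equal(r$omnibus$H, brute_kw_H(values, groups), tolerance = 1e-12)
  expect_equal(r$omnibus$H,
               unname(kruskal.test(values, factor(groups))$statistic),
               tolerance = 1e-12)
  # brute-force Dunn z for pair a-b
  rk <- rank(values)
  N <- length(values)
  tie <- table(values)
  sigma2 <- (N * (N + 1) / 12 - sum(tie^3 - tie) / (12 * (N - 1))) *
    (1 / 4 + 1 / 4)
  z_ab <- (mean(rk[groups == "a"]) - mean(rk[groups == "b"])) / sqrt(sigma2)
  expect_equal(r$pairwise$z[r$pairwise$pair == "a-b"], z_ab,
               tolerance = 1e-12)
  expect_equal(r$pairwise$p_value,
               2 * pnorm(-abs(r$pairwise$z)), tolerance = 1e-12)
  # all-tied data: omnibus statistic is zero
  r0 <- group_effects_nonparametric(rep(2, 9), rep(c("a", "b", "c"), 3))
  expect_equal(r0$omnibus$H, 0)
})

test_that("a location-shifted group dominates the Dunn comparisons", {
  set.seed(13)
  hits <- replicate(60, {
    v <- c(rnorm(8), rnorm(8), rnorm(8, 2))
    g <- rep(c("a", "b", "c"), each = 8)
    r <- group_effects_nonparametric(v, g)
    pc <- r$pairwise
    min(pc$p_value[grepl("c", pc$pair)]) <= min(pc$p_value)
  })
  expect_gt(mean(hits), 0.9)
})

test_that("Holm adjustment is available for Dunn p-values", {
  set.seed(3)
  v <- rnorm(30); g <- rep(letters[1:3], 10)
  r <- group_effects_nonparametric(v, g, p_adjust = "holm")
  expect_equal(r$pairwise$p_adjusted,
               p.adjust(r$pairwise$p_value, "holm"))
  expect_true(all(r$pairwise$p_adjusted >= r$pairwise$p_value))
})
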