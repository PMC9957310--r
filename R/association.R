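#' Pearson correlation with two-sided t test
#'
#' @param x,y paired numeric vectors (pairs with missing values dropped).
#' @return list `r`, `p_value`, `n`, `ci_low`, `ci_high` (95% Fisher CI).
#' @export
pearson_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop_param("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       ci_low = ct$conf.int[1], ci_high = ct$conf.int[2])
}

#' Spearman rank correlation (mid-ranks for ties)
#'
#' @inheritParams pearson_correlation
#' @return list `rho`, `p_value`, `n`.
#' @export
spearman_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop_param("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("rank correlation undefined: zero rank variance", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Confounder-adjusted association between an outcome and a rating delta
#'
#' Least-squares regression of the direct measure on the subjective
#' predictor plus categorical confounders (default: work period and
#' harvesting method), treatment-coded with the alphabetically first
#' level as reference. Reports the predictor coefficient with its 95%
#' confidence interval and p-value.
#'
#' @param data data.frame holding the columns below, one row per
#'   observation unit (typically subject x period).
#' @param outcome,predictor column names (numeric).
#' @param covariates character vector of categorical covariate columns
#'   (may be empty).
#' @param stratum label stored in the result row.
#' @return one-row data.frame: `outcome`, `predictor`, `covariates`,
#'   `stratum`, `estimate`, `ci_low`, `ci_high`, `p_value`, `n`.
#' @export
adjusted_regression <- function(data, outcome, predictor,
                                covariates = c("period", "group"),
                                stratum = "all") {
  cols <- c(outcome, predictor, covariates)
  dat <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
              drop = FALSE]
  miss <- data.frame(outcome = outcome, predictor = predictor,
                     covariates = paste(covariates, collapse = "+"),
                     stratum = stratum, estimate = NA_real_,
                     ci_low = NA_real_, ci_high = NA_real_,
                     p_value = NA_real_, n = nrow(dat),
                     stringsAsFactors = FALSE)
  if (nrow(dat) < 3L || stats::var(dat[[predictor]]) == 0) return(miss)
  keep_cov <- covariates[vapply(covariates, function(cc)
    length(unique(dat[[cc]])) > 1L, logical(1))]
  for (cc in keep_cov) dat[[cc]] <- factor(dat[[cc]])
  fit <- stats::lm(stats::reformulate(c(predictor, keep_cov), outcome),
                   data = dat)
  co <- summary(fit)$coefficients
  if (!(predictor %in% rownames(co))) {
    warning("predictor aliased in adjusted regression", call. = FALSE)
    return(miss)
  }
  ci <- stats::confint(fit, predictor, level = 0.95)
  data.frame(outcome = outcome, predictor = predictor,
             covariates = paste(keep_cov, collapse = "+"),
             stratum = stratum,
             estimate = co[predictor, 1],
             ci_low = ci[1], ci_high = ci[2],
             p_value = co[predictor, 4],
             n = nrow(dat), stringsAsFactors = FALSE)
}

#' Stratified association battery
#'
#' Re-runs [adjusted_regression()] within each level of a stratifying
#' column: by harvesting method (adjusting for period) or by work period
#' (pooling methods). Strata below 3 complete cases are reported as
#' missing rows, not silently dropped.
#'
#' @inheritParams adjusted_regression
#' @param by column to stratify on (e.g. `"group"` or `"period"`).
#' @param covariates confounders adjusted within each stratum (the `by`
#'   column is removed from it automatically).
#' @return data.frame with one row per stratum.
#' @export
stratified_association <- function(data, outcome, predictor, by,
                                   covariates = c("period", "group")) {
  covariates <- setdiff(covariates, by)
  out <- lapply(sort(unique(data[[by]])), function(lv)
    adjusted_regression(data[data[[by]] == lv, , drop = FALSE],
                        outcome, predictor, covariates,
                        stratum = paste0(by, "=", lv)))
  do.call(rbind, out)
}

#' Group and period effects on percent heart-rate reserve
#'
#' Two-way fixed-effects ANOVA (sequential sums of squares) of the
#' square-root-transformed reserve on harvesting group and work period,
#' followed by Tukey honest-significant-difference pairwise comparisons
#' for the group factor.
#'
#' @param hrr data.frame from [hrr_table()] (columns `group`, `period`
#'   and the outcome).
#' @param outcome outcome column, default `"hrr_sqrt"`.
#' @return list with `anova` (data.frame: factor, df, F, p) and
#'   `tukey_group` (data.frame: pair, diff, ci_low, ci_high, p_adj).
#' @export
group_time_effects_hrr <- function(hrr, outcome = "hrr_sqrt") {
  dat <- data.frame(y = hrr[[outcome]], group = factor(hrr$group),
                    period = factor(hrr$period))
  dat <- dat[stats::complete.cases(dat), ]
  if (nlevels(droplevels(dat$group)) < 2L ||
      nlevels(droplevels(dat$period)) < 2L)
    warning("fewer than 2 groups or periods; reduced model", call. = FALSE)
  dat$group <- droplevels(dat$group); dat$period <- droplevels(dat$period)
  terms <- c(if (nlevels(dat$group) > 1L) "group",
             if (nlevels(dat$period) > 1L) "period")
  fit <- stats::aov(stats::reformulate(terms, "y"), data = dat)
  at <- stats::anova(fit)
  an <- data.frame(factor = rownames(at)[-nrow(at)],
                   df = at$Df[-nrow(at)],
                   F_value = at$`F value`[-nrow(at)],
                   p_value = at$`Pr(>F)`[-nrow(at)],
                   stringsAsFactors = FALSE)
  tk <- NULL
  if (nlevels(dat$group) > 1L) {
    t0 <- stats::TukeyHSD(fit, "group")$group
    tk <- data.frame(pair = rownames(t0), diff = t0[, "diff"],
                     ci_low = t0[, "lwr"], ci_high = t0[, "upr"],
                     p_adj = t0[, "p adj"], stringsAsFactors = FALSE)
    rownames(tk) <- NULL
  }
  list(anova = an, tukey_group = tk)
}

#' Kruskal-Wallis omnibus test with Dunn post hoc comparisons
#'
#' Nonparametric factor-effect test for the rating scales: tie-corrected
#' Kruskal-Wallis H, followed by Dunn's pairwise z tests on mean rank
#' sums. Dunn p-values are reported unadjusted by default (a Holm option
#' is provided); empty groups are excluded with a warning.
#'
#' @param values numeric outcome (e.g. rating deltas).
#' @param factor_ grouping vector.
#' @param p_adjust `"none"` (default) or any [stats::p.adjust()] method.
#' @return list with `omnibus` (list `H`, `df`, `p_value`) and `pairwise`
#'   (data.frame: pair, z, p_value, p_adjusted).
#' @export
group_effects_nonparametric <- function(values, factor_,
                                        p_adjust = "none") {
  ok <- is.finite(values) & !is.na(factor_)
  values <- values[ok]
  factor_ <- droplevels(factor(factor_[ok]))
  if (nlevels(factor_) < 2L) stop_param("need at least 2 non-empty groups")
  kw <- if (stats::var(values) == 0)
    list(statistic = c(H = 0), parameter = nlevels(factor_) - 1L,
         p.value = 1)
  else stats::kruskal.test(values, factor_)
  pw <- dunn_test(values, factor_, p_adjust)
  list(omnibus = list(H = unname(kw$statistic),
                      df = unname(kw$parameter),
                      p_value = kw$p.value),
       pairwise = pw)
}

#' Dunn's rank-sum pairwise post hoc test
#'
#' Standard Dunn z statistics on mean ranks with the usual tie
#' correction: for groups i, j,
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))`
#' where `T = sum(t^3 - t) / (12 (N - 1))` over tie groups. Two-sided
#' normal p-values.
#'
#' @inheritParams group_effects_nonparametric
#' @return data.frame with `pair`, `z`, `p_value`, `p_adjusted`.
#' @export
dunn_test <- function(values, factor_, p_adjust = "none") {
  factor_ <- droplevels(factor(factor_))
  r <- rank(values)
  N <- length(values)
  tie <- table(values)
  Tcorr <- sum(tie^3 - tie) / (12 * (N - 1))
  rbar <- tapply(r, factor_, mean)
  nn <- tapply(r, factor_, length)
  lv <- levels(factor_)
  pairs <- utils::combn(lv, 2)
  z <- apply(pairs, 2, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - Tcorr) *
                 (1 / nn[[pr[1]]] + 1 / nn[[pr[2]]]))
    if (se == 0) return(0)
    (rbar[[pr[1]]] - rbar[[pr[2]]]) / se
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(pair = paste(pairs[1, ], pairs[2, ], sep = "-"),
             z = z, p_value = p,
             p_adjusted = stats::p.adjust(p, method = p_adjust),
             stringsAsFactors = FALSE)
}
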