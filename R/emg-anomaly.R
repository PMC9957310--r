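#' PCA-based screening of anomalous EMG windows
#'
#' Field EMG suffers electrode saturation, strap interference and contact
#' loss; affected 10-minute windows distort the fatigue regression and
#' must be removed. Per subject-side, the window feature matrix
#' (amplitude percentiles, mean and median power frequency, total power)
#' is robustly standardized (median/MAD), a principal component analysis
#' is fitted, and each window's robust squared distance in the space of
#' the components covering at least `var_retained` of the variance is
#' compared with a chi-square quantile (`threshold`, default 0.999).
#' Windows beyond the threshold are flagged `anomalous`; windows already
#' pre-flagged (zero spectral power) stay flagged. Constant feature
#' columns are dropped with a warning; groups with fewer than
#' `min_windows` windows pass through unflagged with a warning.
#'
#' @param features data.frame from [emg_window_features()] (may hold many
#'   subject-sides).
#' @param threshold chi-square quantile for the flagging distance.
#' @param var_retained minimum fraction of variance the retained
#'   components must cover.
#' @param min_windows minimum windows per subject-side for screening.
#' @return `features` with the `anomalous` column updated.
#' @export
detect_anomalous_windows <- function(features, threshold = 0.999,
                                     var_retained = 0.9,
                                     min_windows = 10L) {
  if (!nrow(features)) return(features)
  cols <- c("amp_p10", "amp_p50", "amp_p90", "mnf", "mdf", "total_power")
  key <- interaction(features$subject_id, features$side, drop = TRUE)
  for (g in levels(key)) {
    rows <- which(key == g)
    ok <- rows[!features$anomalous[rows] &
               stats::complete.cases(features[rows, cols])]
    if (length(ok) < min_windows) {
      warning("subject-side ", g, ": only ", length(ok),
              " usable windows; anomaly screen skipped", call. = FALSE)
      next
    }
    M <- as.matrix(features[ok, cols])
    med <- apply(M, 2, stats::median)
    madv <- apply(M, 2, stats::mad)
    keep <- madv > 0
    if (!all(keep))
      warning("subject-side ", g, ": constant feature column(s) ",
              paste(cols[!keep], collapse = ", "), " dropped from PCA",
              call. = FALSE)
    if (sum(keep) < 2L) next  # nothing to screen on
    Z <- sweep(sweep(M[, keep, drop = FALSE], 2, med[keep]), 2,
               madv[keep], "/")
    pc <- stats::prcomp(Z, center = TRUE, scale. = FALSE)
    v <- pc$sdev^2
    ncomp <- which(cumsum(v) / sum(v) >= var_retained)[1L]
    S <- pc$x[, seq_len(ncomp), drop = FALSE]
    # robust per-component scale, so outliers do not mask themselves
    sc <- apply(S, 2, stats::mad)
    ctr <- apply(S, 2, stats::median)
    sc[sc == 0] <- pc$sdev[seq_len(ncomp)][sc == 0]
    if (any(sc == 0)) { ncomp <- sum(sc > 0); if (!ncomp) next }
    d2 <- rowSums(sweep(sweep(S[, sc > 0, drop = FALSE], 2, ctr[sc > 0]),
                        2, sc[sc > 0], "/")^2)
    cut <- stats::qchisq(threshold, df = sum(sc > 0))
    features$anomalous[ok[d2 > cut]] <- TRUE
  }
  features
}
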