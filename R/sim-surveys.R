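#' Simulate Borg RPE, Omni RPE and Borg CR10 survey responses
#'
#' Ratings are generated through a Gaussian copula on the ranks of latent
#' exertion: each subject-period exertion value is mapped to a normal
#' score, mixed with independent Gaussian noise using copula weight `w`,
#' and the resulting latent percentile is discretized onto each scale
#' (Borg RPE 6--20 integers, Omni RPE 0--10 integers, Borg CR10 0--10 in
#' half steps, one response per shoulder). The weight `w` is calibrated by
#' the generator's own large-sample simulation (see
#' [calibrate_rating_weight()]) so the population Spearman correlation
#' between a discretized rating and exertion equals
#' `truth$rating_rank_correlation`.
#'
#' Exertion at T0 is 0 for everyone (pre-shift); tied exertions share a
#' mid-rank, so T0 ratings concentrate at the low end of each scale.
#'
#' @param roster data.frame from [simulate_cohort()].
#' @param truth a [ground_truth()].
#' @param seed optional integer; defaults to a stream derived from
#'   `truth$seed`.
#' @return data.frame with columns `subject_id`, `timepoint` (T0--T3),
#'   `scale` (`BorgRPE`, `OmniRPE`, `BorgCR10`), `body_site` (`overall`
#'   or `left_shoulder`/`right_shoulder`) and `value`.
#' @export
simulate_surveys <- function(roster, truth, seed = NULL) {
  seed <- seed %||% derive_seed(truth$seed, "surveys")
  w <- calibrate_rating_weight(truth$rating_rank_correlation)
  n <- nrow(roster)
  periods <- c("T0", "T1", "T2", "T3")
  e <- cbind(T0 = rep(0, n), truth$exertion)  # subjects x 4
  with_seed(seed, {
    ev <- as.vector(e)
    z <- stats::qnorm((rank(ev, ties.method = "average") - 0.5) / length(ev))
    draw <- function() {
      y <- w * z + sqrt(max(0, 1 - w^2)) * stats::rnorm(length(z))
      stats::pnorm(y)  # latent percentile, uniform-ish marginal
    }
    rows <- list(
      data.frame(subject_id = rep(roster$subject_id, 4),
                 timepoint = rep(periods, each = n),
                 scale = "BorgRPE", body_site = "overall",
                 value = round(6 + 14 * draw()),
                 stringsAsFactors = FALSE),
      data.frame(subject_id = rep(roster$subject_id, 4),
                 timepoint = rep(periods, each = n),
                 scale = "OmniRPE", body_site = "overall",
                 value = round(10 * draw()),
                 stringsAsFactors = FALSE))
    for (site in c("left_shoulder", "right_shoulder")) {
      rows[[length(rows) + 1L]] <-
        data.frame(subject_id = rep(roster$subject_id, 4),
                   timepoint = rep(periods, each = n),
                   scale = "BorgCR10", body_site = site,
                   value = round(2 * 10 * draw()) / 2,
                   stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out[order(out$subject_id, out$timepoint, out$scale, out$body_site), ,
        drop = FALSE]
  })
}

#' Calibrate the copula weight behind a target rating rank-correlation
#'
#' The survey generator mixes exertion normal-scores with noise using a
#' weight `w`; discretization onto the rating scales attenuates the
#' resulting Spearman correlation below the continuous-copula value
#' `(6 / pi) * asin(w / 2)`. This function inverts the full generative map
#' by simulation: it draws a large latent sample under the generator's
#' default exertion distribution, discretizes onto the Borg RPE grid (the
#' coarsest relevant scale behaves almost identically), and bisects on `w`
#' until the simulated population Spearman matches `target`. The
#' simulation uses a fixed internal seed, so the calibration is
#' deterministic; results are memoized per session.
#'
#' @param target desired population Spearman correlation between rating
#'   and latent exertion, in `[-1, 1]`.
#' @param n_sim latent sample size for the calibration simulation.
#' @return the copula weight `w` in `[-1, 1]`.
#' @export
calibrate_rating_weight <- function(target, n_sim = 20000L) {
  if (abs(target) > 1) stop_param("target rank correlation must be in [-1, 1]")
  if (target == 0) return(0)
  key <- sprintf("%.6f", target)
  hit <- .calibration_cache[[key]]
  if (!is.null(hit)) return(hit)
  sgn <- sign(target)
  tgt <- abs(target)
  sim_rho <- function(w, z, eps) {
    y <- w * z + sqrt(max(0, 1 - w^2)) * eps
    ratings <- round(6 + 14 * stats::pnorm(y))
    stats::cor(ratings, z, method = "spearman")
  }
  w <- with_seed(912703L, {
    # latent scores mimic the generator: a tied block at zero exertion
    # (T0) plus continuous work-period exertion
    e <- c(rep(0, n_sim %/% 4),
           stats::runif(n_sim - n_sim %/% 4, 0.05, 0.85))
    z <- stats::qnorm((rank(e, ties.method = "average") - 0.5) / length(e))
    eps <- stats::rnorm(length(z))
    if (sim_rho(1, z, eps) <= tgt) 1 else {
      lo <- 0; hi <- 1
      for (i in 1:25) {
        mid <- (lo + hi) / 2
        if (sim_rho(mid, z, eps) < tgt) lo <- mid else hi <- mid
      }
      (lo + hi) / 2
    }
  })
  .calibration_cache[[key]] <- sgn * w
  sgn * w
}

.calibration_cache <- new.env(parent = emptyenv())
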