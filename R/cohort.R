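#' Cohort specification for the synthetic-study generator
#'
#' @param n_per_group workers per harvesting group (>= 1). The study design
#'   the package emulates used 8 per group.
#' @param groups character vector of harvesting-method labels.
#' @param age_range integer `c(min, max)` in years, within `[18, 65]`.
#' @param seed integer seed making the cohort reproducible.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 8,
                        groups = c("Ground", "Ladder", "Platform"),
                        age_range = c(18, 47),
                        seed = 1L) {
  if (length(n_per_group) != 1L || is.na(n_per_group) || n_per_group < 1)
    stop_param("n_per_group must be a positive integer")
  if (length(groups) < 1L) stop_param("at least one group label required")
  if (length(age_range) != 2L || age_range[1] > age_range[2] ||
      age_range[1] < 18 || age_range[2] > 65)
    stop_param("age_range must be (min, max) within [18, 65]")
  structure(list(n_per_group = as.integer(n_per_group),
                 groups = as.character(groups),
                 age_range = as.integer(age_range),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a subject roster
#'
#' Draws `n_per_group` male workers per harvesting group with integer ages
#' uniform over `age_range` and a dominant side (right with probability
#' 0.9, reflecting population handedness).
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with columns `subject_id`, `age`, `group`,
#'   `dominant_side`.
#' @examples
#' roster <- simulate_cohort(cohort_spec(n_per_group = 8))
#' nrow(roster)  # 24
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_per_group * length(spec$groups)
  with_seed(derive_seed(spec$seed, "cohort"), {
    data.frame(
      subject_id = sprintf("S%02d", seq_len(n)),
      age = sample(seq(spec$age_range[1], spec$age_range[2]), n, replace = TRUE),
      group = rep(spec$groups, each = spec$n_per_group),
      dominant_side = ifelse(stats::runif(n) < 0.9, "right", "left"),
      stringsAsFactors = FALSE)
  })
}
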