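#' Run configuration for the end-to-end pipeline
#'
#' Collects every tunable the pipeline exposes. Serializes losslessly to
#' YAML via [write_run_config()] / [read_run_config()].
#'
#' @param schedule_preset `"rest30"`, `"fullbreak"` or `"demo"` (see
#'   [shift_schedule()]).
#' @param n_per_group,groups,age_range cohort structure (see
#'   [cohort_spec()]).
#' @param hr_filter_window moving-median window (odd samples).
#' @param emg_band analysis band `c(low, high)` in Hz.
#' @param emg_filter_order Butterworth order.
#' @param emg_window_minutes feature window length.
#' @param anomaly_threshold chi-square quantile of the PCA screen.
#' @param anomaly_var_retained variance fraction retained in the screen.
#' @param outcome_scale `"hrr_sqrt"` (default; the normality-transformed
#'   reserve) or `"hrr"` for association outcomes.
#' @param mpf_metric `"mdf"` (median power frequency, default) or
#'   `"mnf"`.
#' @param min_coverage heart-rate window coverage threshold.
#' @param seed integer master seed.
#' @param truth named list of [ground_truth()] parameter overrides.
#' @return object of class `run_config` (a named list).
#' @export
run_config <- function(schedule_preset = "rest30",
                       n_per_group = 8,
                       groups = c("Ground", "Ladder", "Platform"),
                       age_range = c(18, 47),
                       hr_filter_window = 5L,
                       emg_band = c(20, 450),
                       emg_filter_order = 4L,
                       emg_window_minutes = 10,
                       anomaly_threshold = 0.999,
                       anomaly_var_retained = 0.9,
                       outcome_scale = c("hrr_sqrt", "hrr"),
                       mpf_metric = c("mdf", "mnf"),
                       min_coverage = 0.5,
                       seed = 1L,
                       truth = list()) {
  cfg <- list(schedule_preset = schedule_preset,
              n_per_group = as.integer(n_per_group),
              groups = groups, age_range = as.integer(age_range),
              hr_filter_window = as.integer(hr_filter_window),
              emg_band = as.numeric(emg_band),
              emg_filter_order = as.integer(emg_filter_order),
              emg_window_minutes = as.numeric(emg_window_minutes),
              anomaly_threshold = anomaly_threshold,
              anomaly_var_retained = anomaly_var_retained,
              outcome_scale = match.arg(outcome_scale),
              mpf_metric = match.arg(mpf_metric),
              min_coverage = min_coverage,
              seed = as.integer(seed),
              truth = truth)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

config_schedule <- function(config) shift_schedule(preset = config$schedule_preset)

config_truth <- function(config, roster) {
  do.call(ground_truth,
          c(list(roster = roster, seed = config$seed), config$truth))
}

#' Generate a complete synthetic study dataset on disk
#'
#' Writes roster, per-subject heart-rate CSVs, per-subject-side EMG
#' CSVs, the survey table, the run configuration, and a ground-truth
#' JSON (the generator's parameters and latent exertion) into
#' `out_dir`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "hr"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "emg"), showWarnings = FALSE)
  schedule <- config_schedule(config)
  spec <- cohort_spec(config$n_per_group, config$groups, config$age_range,
                      config$seed)
  roster <- simulate_cohort(spec)
  truth <- config_truth(config, roster)
  write_roster_csv(roster, file.path(out_dir, "roster.csv"))
  contam <- list()
  for (i in seq_len(nrow(roster))) {
    sid <- roster$subject_id[i]
    hr <- simulate_heart_rate(roster[i, ], schedule, truth)
    write_hr_csv(hr, file.path(out_dir, "hr", paste0(sid, ".csv")))
    emg <- simulate_emg(roster[i, ], schedule, truth)
    for (side in names(emg)) {
      write_emg_csv(emg[[side]],
                    file.path(out_dir, "emg", paste0(sid, "_", side, ".csv")))
      cw <- attr(emg[[side]], "contaminated_windows")
      if (!is.null(cw)) contam[[paste0(sid, "_", side)]] <- cw
    }
  }
  surveys <- simulate_surveys(roster, truth)
  write_survey_csv(surveys, file.path(out_dir, "surveys.csv"))
  write_run_config(config, file.path(out_dir, "config.yaml"))
  gt <- list(exertion = as.data.frame(truth$exertion),
             subject_id = rownames(truth$exertion),
             hr_gain = truth$hr_gain,
             hr_baseline = as.list(truth$hr_baseline),
             emg_mdf_intercept = truth$emg_mdf_intercept,
             emg_mdf_slope_true = truth$emg_mdf_slope_true,
             emg_slope = as.list(truth$emg_slope),
             rating_rank_correlation = truth$rating_rank_correlation,
             contaminated_windows = contam)
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Full association battery between direct and subjective measures
#'
#' Joins the percent-heart-rate-reserve table with the Borg/Omni rating
#' deltas on subject and period and runs: unadjusted Pearson
#' correlations, confounder-adjusted regressions (period + harvesting
#' method), stratification by method and by period, the between-scale
#' Spearman correlation, CR10-change versus fatigue slope (unadjusted
#' and adjusted for harvesting method and side dominance), the two-way
#' ANOVA with Tukey HSD on the reserve, and Kruskal-Wallis/Dunn tests of
#' method and period effects on each rating scale.
#'
#' @param hrr data.frame from [hrr_table()].
#' @param deltas data.frame from [delta_from_baseline()].
#' @param cr10 data.frame from [cr10_shift_change()].
#' @param slopes data.frame from [fit_all_slopes()] (or the `slopes`
#'   element of [pooled_slope_model()]).
#' @param roster roster data.frame.
#' @param outcome `"hrr_sqrt"` or `"hrr"`.
#' @return list with `associations` (data.frame of estimate rows),
#'   `scale_spearman` (Borg vs Omni deltas), `group_effects` (list of
#'   Kruskal-Wallis/Dunn results), `hrr_anova`
#'   (see [group_time_effects_hrr()]), and `cr10_vs_slope` join table.
#' @export
association_battery <- function(hrr, deltas, cr10, slopes, roster,
                                outcome = "hrr_sqrt") {
  dsub <- function(scale) {
    d <- deltas[deltas$scale == scale, c("subject_id", "timepoint", "delta")]
    names(d)[3] <- paste0(scale, "_delta")
    d
  }
  joined <- merge(hrr, dsub("BorgRPE"),
                  by.x = c("subject_id", "period"),
                  by.y = c("subject_id", "timepoint"))
  joined <- merge(joined, dsub("OmniRPE"),
                  by.x = c("subject_id", "period"),
                  by.y = c("subject_id", "timepoint"))
  assoc <- list()
  for (pred in c("BorgRPE_delta", "OmniRPE_delta")) {
    pc <- pearson_correlation(joined[[pred]], joined[[outcome]])
    assoc[[length(assoc) + 1L]] <- data.frame(
      outcome = outcome, predictor = pred, covariates = "",
      stratum = "all", estimate = pc$r, ci_low = pc$ci_low,
      ci_high = pc$ci_high, p_value = pc$p_value, n = pc$n,
      stringsAsFactors = FALSE)
    assoc[[length(assoc) + 1L]] <-
      adjusted_regression(joined, outcome, pred)
    assoc[[length(assoc) + 1L]] <-
      stratified_association(joined, outcome, pred, by = "group")
    assoc[[length(assoc) + 1L]] <-
      stratified_association(joined, outcome, pred, by = "period")
  }
  # local discomfort vs fatigue slope, per subject-side
  cs <- merge(cr10, slopes, by = c("subject_id", "side"))
  cs <- merge(cs, roster[, c("subject_id", "group")], by = "subject_id")
  if (sum(stats::complete.cases(cs[, c("cr10_change", "b_time")])) >= 3 &&
      stats::var(cs$cr10_change, na.rm = TRUE) > 0) {
    pc <- pearson_correlation(cs$cr10_change, cs$b_time)
    assoc[[length(assoc) + 1L]] <- data.frame(
      outcome = "b_time", predictor = "CR10_change", covariates = "",
      stratum = "all", estimate = pc$r, ci_low = pc$ci_low,
      ci_high = pc$ci_high, p_value = pc$p_value, n = pc$n,
      stringsAsFactors = FALSE)
    assoc[[length(assoc) + 1L]] <-
      adjusted_regression(cs, "b_time", "cr10_change",
                          covariates = c("group", "dominance"))
  }
  associations <- do.call(rbind, assoc)
  rownames(associations) <- NULL
  bo <- merge(dsub("BorgRPE"), dsub("OmniRPE"),
              by = c("subject_id", "timepoint"))
  scale_spearman <- spearman_correlation(bo$BorgRPE_delta, bo$OmniRPE_delta)
  ge <- list()
  for (scale in c("BorgRPE", "OmniRPE")) {
    d <- merge(dsub(scale), roster[, c("subject_id", "group")],
               by = "subject_id")
    ge[[paste0(scale, "_by_method")]] <-
      group_effects_nonparametric(d[[paste0(scale, "_delta")]], d$group)
    ge[[paste0(scale, "_by_period")]] <-
      group_effects_nonparametric(d[[paste0(scale, "_delta")]], d$timepoint)
  }
  cg <- merge(cr10, roster[, c("subject_id", "group")], by = "subject_id")
  ok <- is.finite(cg$cr10_change)
  if (sum(ok) >= 6) {
    ge$CR10_by_method <-
      group_effects_nonparametric(cg$cr10_change[ok], cg$group[ok])
    ge$CR10_by_side <-
      group_effects_nonparametric(cg$cr10_change[ok], cg$dominance[ok])
  }
  list(associations = associations, scale_spearman = scale_spearman,
       group_effects = ge,
       hrr_anova = group_time_effects_hrr(hrr, outcome),
       cr10_vs_slope = cs)
}

#' Analyse a dataset directory end to end
#'
#' Reads the CSV dataset written by [run_simulate()] (or assembled from
#' real exports in the same dialect), runs the heart-rate branch
#' (median filter, period means, percent heart-rate reserve), the EMG
#' branch (band-pass, 10-min window features, PCA anomaly screen,
#' per-subject-side and pooled fatigue slopes), the survey branch
#' (validation, baseline deltas, CR10 shift changes) and the
#' association battery, and writes tidy result CSVs, a JSON summary and
#' a reconciling run manifest into `out_dir`. Subjects with missing
#' files yield missing-result rows, not failures.
#'
#' @param config a [run_config()].
#' @param dataset_dir directory from [run_simulate()].
#' @param out_dir results directory (created if needed).
#' @return list with all result tables (`hrr`, `features`, `slopes`,
#'   `pooled`, `deltas`, `cr10`, `battery`, `manifest`), invisibly
#'   written to `out_dir`.
#' @export
run_analysis <- function(config, dataset_dir, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  schedule <- config_schedule(config)
  roster <- read_roster_csv(file.path(dataset_dir, "roster.csv"))
  hr_files <- file.path(dataset_dir, "hr", paste0(roster$subject_id, ".csv"))
  hr_list <- list()
  for (i in seq_along(hr_files)) {
    if (file.exists(hr_files[i]))
      hr_list[[roster$subject_id[i]]] <- read_hr_csv(hr_files[i])
  }
  hrr <- hrr_table(hr_list, roster, schedule,
                   filter_window = config$hr_filter_window,
                   min_coverage = config$min_coverage)
  feat <- list(); n_emg <- 0L
  for (sid in roster$subject_id) for (side in c("left", "right")) {
    f <- file.path(dataset_dir, "emg", paste0(sid, "_", side, ".csv"))
    if (!file.exists(f)) next
    n_emg <- n_emg + 1L
    rec <- emg_bandpass(read_emg_csv(f),
                        config$emg_band[1], config$emg_band[2],
                        config$emg_filter_order)
    feat[[length(feat) + 1L]] <-
      emg_window_features(rec, schedule, config$emg_window_minutes,
                          band = config$emg_band)
  }
  features <- if (length(feat)) do.call(rbind, feat) else empty_features()
  features <- detect_anomalous_windows(features,
                                       threshold = config$anomaly_threshold,
                                       var_retained = config$anomaly_var_retained)
  pooled <- if (nrow(features)) pooled_slope_model(features,
                                                   metric = config$mpf_metric)
            else NULL
  slopes <- if (!is.null(pooled)) pooled$slopes else NULL
  sv <- validate_responses(read_survey_csv(file.path(dataset_dir,
                                                     "surveys.csv")))
  deltas <- delta_from_baseline(sv$responses)
  cr10 <- cr10_shift_change(sv$responses, roster)
  battery <- association_battery(hrr, deltas, cr10, slopes, roster,
                                 outcome = config$outcome_scale)
  # write results
  outs <- list(hrr = hrr, emg_window_features = features,
               fatigue_slopes = slopes, survey_deltas = deltas,
               cr10_changes = cr10,
               associations = battery$associations)
  for (nm in names(outs))
    data.table::fwrite(outs[[nm]], file.path(out_dir, paste0(nm, ".csv")))
  summary_json <- list(
    pooled_b_time = pooled$b_time, pooled_b_time_p = pooled$p_value,
    scale_spearman = battery$scale_spearman,
    hrr_anova = battery$hrr_anova$anova,
    tukey_group = battery$hrr_anova$tukey_group,
    group_effects = lapply(battery$group_effects, function(g)
      list(H = g$omnibus$H, df = g$omnibus$df, p = g$omnibus$p_value,
           pairwise = g$pairwise)))
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  manifest <- list(
    config = unclass(config),
    package_version = as.character(utils::packageVersion("ergofield")),
    counts = list(
      subjects = nrow(roster),
      hr_series = length(hr_list),
      emg_recordings = n_emg,
      windows_total = nrow(features),
      windows_anomalous = sum(features$anomalous),
      windows_used = sum(!features$anomalous & !features$in_break),
      survey_rows_accepted = nrow(sv$responses),
      survey_rows_rejected = nrow(sv$rejected),
      subjects_missing_hr = nrow(roster) - length(hr_list)),
    checksums = as.list(tools::md5sum(
      list.files(out_dir, pattern = "\\.csv$", full.names = TRUE))))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(hrr = hrr, features = features, slopes = slopes,
                 pooled = pooled, deltas = deltas, cr10 = cr10,
                 battery = battery, manifest = manifest))
}

#' Compare pipeline estimates with the generator's ground truth
#'
#' For a simulated dataset (with `ground_truth.json` present), reruns
#' the analysis and reports recovery of: working heart-rate means
#' (equivalently percent heart-rate reserve), the pooled and
#' per-subject fatigue slopes, and the rating-exertion rank
#' correlation; each with a pass flag against the stated tolerance.
#'
#' @param config a [run_config()].
#' @param dataset_dir simulated dataset directory.
#' @param out_dir results directory.
#' @param tolerances named list: `hrr_abs` (absolute %HRR error per
#'   subject-period, default 0.05), `slope_abs` (Hz/min, default: 2 x
#'   the pooled-slope standard error plus 10% of the true magnitude),
#'   `spearman_abs` (default 0.15).
#' @return data.frame with `quantity`, `estimate`, `truth`, `error`,
#'   `tolerance`, `pass`; also written to `recovery.csv` in `out_dir`.
#' @export
run_recovery_report <- function(config, dataset_dir, out_dir,
                                tolerances = list()) {
  gt_path <- file.path(dataset_dir, "ground_truth.json")
  if (!file.exists(gt_path))
    stop("no ground_truth.json in ", dataset_dir,
         " (real-data mode has no recovery report)", call. = FALSE)
  gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
  res <- run_analysis(config, dataset_dir, out_dir)
  roster <- read_roster_csv(file.path(dataset_dir, "roster.csv"))
  tol_hrr <- tolerances$hrr_abs %||% 0.05
  # %HRR recovery: truth = (gain*e + 10) / (220 - age - baseline + 10)
  ex <- gt$exertion
  hrr <- res$hrr
  age <- stats::setNames(roster$age, roster$subject_id)
  base <- unlist(gt$hr_baseline)
  truth_hrr <- function(sid, period) {
    mapply(function(s, p) {
      e <- ex[[p]][match(s, gt$subject_id)]
      (gt$hr_gain * e + 10) / (220 - age[[s]] - base[[s]] + 10)
    }, sid, period, USE.NAMES = FALSE)
  }
  hrr$truth <- truth_hrr(hrr$subject_id, hrr$period)
  hrr_err <- mean(abs(hrr$hrr - hrr$truth))
  rows <- list(data.frame(
    quantity = "hrr_mean_abs_error", estimate = mean(hrr$hrr),
    truth = mean(hrr$truth), error = hrr_err, tolerance = tol_hrr,
    pass = hrr_err <= tol_hrr, stringsAsFactors = FALSE))
  if (!is.null(res$pooled)) {
    tol_slope <- tolerances$slope_abs %||%
      (2 * res$pooled$stderr + 0.1 * abs(gt$emg_mdf_slope_true))
    err <- abs(res$pooled$b_time - gt$emg_mdf_slope_true)
    rows[[length(rows) + 1L]] <- data.frame(
      quantity = "pooled_b_time", estimate = res$pooled$b_time,
      truth = gt$emg_mdf_slope_true, error = err, tolerance = tol_slope,
      pass = err <= tol_slope, stringsAsFactors = FALSE)
  }
  # rating-exertion rank correlation, pooled over scales and periods
  sv <- read_survey_csv(file.path(dataset_dir, "surveys.csv"))
  long_e <- function(sid, tp) {
    out <- numeric(length(sid))
    work <- tp != "T0"
    out[work] <- mapply(function(s, t) ex[[t]][match(s, gt$subject_id)],
                        sid[work], tp[work])
    out
  }
  ov <- sv[sv$scale == "OmniRPE", ]
  sp <- spearman_correlation(ov$value, long_e(ov$subject_id, ov$timepoint))
  tol_sp <- tolerances$spearman_abs %||% 0.15
  err <- abs(sp$rho - gt$rating_rank_correlation)
  rows[[length(rows) + 1L]] <- data.frame(
    quantity = "rating_rank_correlation", estimate = sp$rho,
    truth = gt$rating_rank_correlation, error = err, tolerance = tol_sp,
    pass = err <= tol_sp, stringsAsFactors = FALSE)
  report <- do.call(rbind, rows)
  data.table::fwrite(report, file.path(out_dir, "recovery.csv"))
  report
}
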