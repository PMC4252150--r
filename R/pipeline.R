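#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis: the zero-phase
#' Butterworth specification, the boxcar width feeding the recurrence
#' branch, the RQA parameters, and the vection latency cutoff. The
#' defaults are the published settings (order-5 filter, 10-sample boxcar,
#' m = 8 / tau = 15 / lmin = 4, 5% cutoff) except for the recurrence
#' radius, which callers analysing synthetic or re-scaled data will
#' usually switch to `fraction_of_mean_distance` mode (see
#' [rqa_params()]).
#'
#' @param filter A [filter_spec].
#' @param boxcar_width Samples per non-overlapping averaging window before
#'   RQA.
#' @param rqa An [rqa_params].
#' @param latency_cutoff Throttle onset threshold, percent.
#' @param path_on `"filtered"` (default) or `"raw"`: which trace the path
#'   length and ellipse are computed on.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(filter = filter_spec(), boxcar_width = 10,
                            rqa = rqa_params(), latency_cutoff = 5,
                            path_on = c("filtered", "raw")) {
  if (!inherits(filter, "filter_spec")) parameter_error("filter must be a filter_spec")
  if (!inherits(rqa, "rqa_params")) parameter_error("rqa must be rqa_params")
  if (!is_scalar_number(boxcar_width) || boxcar_width < 1)
    parameter_error("boxcar_width must be >= 1")
  path_on <- match.arg(path_on)
  structure(list(filter = filter, boxcar_width = as.integer(boxcar_width),
                 rqa = rqa, latency_cutoff = latency_cutoff,
                 path_on = path_on),
            class = "pipeline_config")
}

# Compute one subject's features; any NULL input leaves the corresponding
# columns NA. Returns a one-row data.frame.
subject_features <- function(sid, quiet, flow, vection, config) {
  row <- as.data.frame(as.list(stats::setNames(
    rep(NA_real_, length(feature_columns()) - 1L),
    setdiff(feature_columns(), "subject_id"))))
  row <- cbind(data.frame(subject_id = sid, stringsAsFactors = FALSE), row)
  quiet_one <- function(trace) {
    filt <- butterworth_filter(trace, config$filter)
    lin <- if (config$path_on == "filtered") filt else trace
    red <- boxcar_downsample(filt, config$boxcar_width)
    r <- rqa(red$ap, config$rqa)
    list(path = path_length(lin), area = confidence_ellipse(lin)$area, rqa = r)
  }
  rq <- list()
  if (!is.null(quiet$open)) {
    f <- quiet_one(quiet$open)
    row$path_eo <- f$path; row$area_eo <- f$area
    row$rr_eo <- f$rqa$rr; row$det_eo <- f$rqa$det; row$lam_eo <- f$rqa$lam
    rq$open <- f$rqa
  }
  if (!is.null(quiet$closed)) {
    f <- quiet_one(quiet$closed)
    row$path_ec <- f$path; row$area_ec <- f$area
    row$rr_ec <- f$rqa$rr; row$det_ec <- f$rqa$det; row$lam_ec <- f$rqa$lam
    rq$closed <- f$rqa
  }
  if (is.finite(row$path_eo) && is.finite(row$path_ec))
    row$romberg <- romberg_ratio(row$path_ec, row$path_eo)
  if (is.finite(row$area_eo) && is.finite(row$area_ec))
    row$log_area_ratio <- log_area_ratio(row$area_eo, row$area_ec)
  if (!is.null(rq$open) && !is.null(rq$closed))
    row$rr_diff <- rr_difference(rq$open, rq$closed)
  for (dirn in c("expanding", "contracting")) {
    sess <- flow[[dirn]]
    if (!is.null(sess)) {
      filt <- butterworth_filter(sess$trace, config$filter)
      row[[paste0("vepr_", dirn)]] <- compute_vepr(filt, sess$manifest)$mean_vepr
    }
    recs <- vection[[dirn]]
    if (!is.null(recs) && length(recs)) {
      vs <- aggregate_vection(recs, cutoff = config$latency_cutoff)
      row[[paste0("verbal_", dirn)]] <- vs$verbal_mean
      row[[paste0("throttle_max_", dirn)]] <- vs$throttle_max_mean
      row[[paste0("latency_", dirn)]] <- vs$latency_mean
    }
  }
  row
}

#' Compute the per-subject feature table of a cohort
#'
#' Runs the measurement pipeline over every subject of an (in-memory or
#' loaded) cohort: zero-phase filtering, linear quiet-stance measures
#' (path length, 95% ellipse area, Romberg and log-area ratios),
#' boxcar-reduced AP recurrence measures, VEPR extraction from the blocked
#' flow sessions, and vection aggregation. Subjects with missing
#' components keep `NA` in the affected columns; a warning summarises
#' them.
#'
#' @param cohort A `sway_cohort` from [simulate_cohort()] or
#'   [load_cohort()].
#' @param config A [pipeline_config].
#' @return A [feature_table].
#' @export
compute_features <- function(cohort, config = pipeline_config()) {
  stopifnot(inherits(cohort, "sway_cohort"))
  rows <- lapply(cohort$subjects$subject_id, function(sid) {
    tryCatch(
      subject_features(sid,
                       quiet = cohort$quiet[[sid]],
                       flow = cohort$flow[[sid]],
                       vection = cohort$vection[[sid]],
                       config = config),
      swayrqa_error = function(e) {
        stop_swayrqa(sprintf("feature extraction failed for subject %s: %s",
                             sid, conditionMessage(e)),
                     class(e)[1])
      })
  })
  tab <- feature_table(do.call(rbind, rows))
  n_missing <- sum(is.na(as.matrix(tab[setdiff(names(tab), "subject_id")])))
  if (n_missing > 0)
    warning(sprintf("feature table contains %d missing values", n_missing),
            call. = FALSE)
  tab
}

#' Run the full analysis pipeline on a cohort directory
#'
#' Loads a cohort from disk, computes the feature table, the two
#' correlation layouts (VEPR-by-vection and recurrence-by-vection), and
#' the quiet-stance paired contrasts (eyes-closed vs eyes-open path
#' length, contracting vs expanding verbal vection), and writes everything
#' under `output_dir`: `features.csv`, `correlations_rqa.csv`,
#' `correlations_vepr.csv`, and a `run_report.yaml` recording every
#' parameter so the run can be reproduced from the report alone.
#'
#' @param input_dir Cohort directory (layout of [gen_cohort()]).
#' @param output_dir Output directory, created if needed.
#' @param config A [pipeline_config].
#' @return Invisibly, a list with `features`, `correlations` (list of the
#'   two tables), `tests` (paired-test results) and `report` (the report
#'   list).
#' @export
run_pipeline <- function(input_dir, output_dir,
                         config = pipeline_config()) {
  cohort <- load_cohort(input_dir)
  features <- compute_features(cohort, config)
  if (!dir.exists(output_dir) && !dir.create(output_dir, recursive = TRUE))
    io_error(sprintf("cannot create %s", output_dir))
  write_feature_table(features, file.path(output_dir, "features.csv"))
  cors <- list(rqa = correlation_table(features, rqa_correlation_pairs()),
               vepr = correlation_table(features, vepr_correlation_pairs()))
  utils::write.csv(cors$rqa, file.path(output_dir, "correlations_rqa.csv"),
                   row.names = FALSE)
  utils::write.csv(cors$vepr, file.path(output_dir, "correlations_vepr.csv"),
                   row.names = FALSE)
  run_test <- function(a, b) {
    tryCatch(unclass(paired_t(a, b)), swayrqa_error = function(e) NULL)
  }
  tests <- list(
    path_closed_vs_open = run_test(features$path_ec, features$path_eo),
    verbal_contracting_vs_expanding =
      run_test(features$verbal_contracting, features$verbal_expanding),
    vepr_contracting_vs_expanding =
      run_test(features$vepr_contracting, features$vepr_expanding))
  report <- list(
    package_version = as.character(utils::packageVersion("swayrqa")),
    input_dir = normalizePath(input_dir),
    n_subjects = nrow(features),
    config = list(filter = unclass(config$filter),
                  boxcar_width = config$boxcar_width,
                  rqa = unclass(config$rqa),
                  latency_cutoff = config$latency_cutoff,
                  path_on = config$path_on),
    missing_values_per_column =
      as.list(colSums(is.na(features[setdiff(names(features), "subject_id")]))),
    paired_tests = tests,
    outputs = c("features.csv", "correlations_rqa.csv",
                "correlations_vepr.csv"))
  yaml::write_yaml(report, file.path(output_dir, "run_report.yaml"))
  invisible(list(features = features, correlations = cors, tests = tests,
                 report = report))
}
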