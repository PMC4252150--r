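# The per-subject feature table: the join surface between the sway measures
# and the vection outcomes, one row per subject.

feature_columns <- function() {
  c("subject_id",
    "path_eo", "path_ec", "romberg",
    "area_eo", "area_ec", "log_area_ratio",
    "vepr_expanding", "vepr_contracting",
    "rr_eo", "rr_ec", "rr_diff",
    "det_eo", "det_ec", "lam_eo", "lam_ec",
    "verbal_expanding", "verbal_contracting",
    "throttle_max_expanding", "throttle_max_contracting",
    "latency_expanding", "latency_contracting")
}

#' Validate a per-subject feature table
#'
#' The feature table has one row per subject and a fixed column set: quiet
#' stance path lengths (`path_eo`/`path_ec`, mm) and their Romberg ratio,
#' 95% ellipse areas (`area_eo`/`area_ec`, mm^2) and the log open/closed
#' area ratio, per-direction VEPRs (mm, forward-positive), recurrence
#' measures (`rr_*` as fractions, `det_*`, `lam_*`), and the vection
#' outcomes (verbal / throttle max in percent, latency in seconds).
#' Missing values are allowed anywhere and stay `NA`.
#'
#' @param df A data.frame with a `subject_id` column; missing feature
#'   columns are added as `NA`.
#' @return The validated data.frame with class `feature_table` prepended
#'   and columns in canonical order.
#' @export
feature_table <- function(df) {
  df <- as.data.frame(df)
  if (!"subject_id" %in% names(df)) format_error("feature table needs subject_id")
  extra <- setdiff(names(df), feature_columns())
  if (length(extra))
    format_error(sprintf("unknown feature column(s): %s", paste(extra, collapse = ", ")))
  for (col in setdiff(feature_columns(), names(df)))
    df[[col]] <- rep(NA_real_, nrow(df))
  df <- df[feature_columns()]
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id))
    data_error("subject_id must be unique in a feature table")
  positive_cols <- c("path_eo", "path_ec", "romberg", "area_eo", "area_ec")
  for (col in positive_cols) {
    v <- df[[col]]
    if (any(is.finite(v) & v <= 0))
      data_error(sprintf("column %s must be > 0 where finite", col))
  }
  for (col in c("rr_eo", "rr_ec")) {
    v <- df[[col]]
    if (any(is.finite(v) & (v <= 0 | v > 1)))
      data_error(sprintf("column %s must lie in (0, 1] where finite", col))
  }
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Read / write a feature table CSV
#'
#' Stable column order, one header row, missing values serialised as empty
#' fields. Round-trips preserve both values (to full double precision) and
#' the `NA` pattern.
#'
#' @param table A [feature_table] (or coercible data.frame).
#' @param path CSV path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns a validated [feature_table].
#' @export
write_feature_table <- function(table, path) {
  table <- feature_table(table)
  ok <- tryCatch({
    utils::write.csv(table, path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) io_error(sprintf("cannot write %s", path))
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, na.strings = "",
                        colClasses = c(subject_id = "character"))
  feature_table(df)
}
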