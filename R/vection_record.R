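#' Per-trial vection record
#'
#' One seated-vection trial: the continuous throttle trace (0--100% vection
#' strength sampled at the device rate, nominally 100 Hz, times measured
#' from stimulus onset) and the end-of-trial verbal rating (0 = no
#' self-motion, 100 = complete self-motion).
#'
#' @param subject_id Subject identifier.
#' @param condition `"expanding"` or `"contracting"` optic flow.
#' @param trial_index Trial number within the condition (>= 1).
#' @param throttle data.frame with columns `time_s` (monotone increasing)
#'   and `level_pct` in `[0, 100]`.
#' @param verbal Verbal rating in `[0, 100]`, or `NA` if not recorded.
#' @return An object of class `vection_record`.
#' @export
vection_record <- function(subject_id, condition, trial_index, throttle,
                           verbal = NA_real_) {
  if (!is_scalar_string(subject_id)) format_error("subject_id must be a non-empty string")
  if (!condition %in% c("expanding", "contracting"))
    format_error(sprintf("unknown flow condition '%s'", condition))
  trial_index <- as.integer(trial_index)
  if (is.na(trial_index) || trial_index < 1L)
    format_error("trial_index must be an integer >= 1")
  throttle <- as.data.frame(throttle)
  if (!all(c("time_s", "level_pct") %in% names(throttle)))
    format_error("throttle must have 'time_s' and 'level_pct' columns")
  if (nrow(throttle) == 0L) data_error("empty throttle trace")
  if (any(diff(throttle$time_s) <= 0))
    data_error("throttle time must be monotone increasing")
  lv <- throttle$level_pct
  if (any(!is.finite(lv)) || any(lv < 0) || any(lv > 100))
    data_error("throttle levels must lie within [0, 100]")
  verbal <- as.numeric(verbal)
  if (!is.na(verbal) && (verbal < 0 || verbal > 100))
    data_error("verbal rating must lie within [0, 100]")
  structure(list(subject_id = subject_id, condition = condition,
                 trial_index = trial_index, throttle = throttle,
                 verbal = verbal),
            class = "vection_record")
}

#' Read a throttle trace
#'
#' Reads a two-column CSV (`time_s`, `level_pct`) holding one trial's
#' continuous vection rating. Levels outside `[0, 100]` are a data error,
#' never clamped.
#'
#' @param path CSV path.
#' @inheritParams vection_record
#' @return A [vection_record] (with `verbal = NA` unless supplied).
#' @export
read_throttle <- function(path, subject_id = "unknown",
                          condition = "expanding", trial_index = 1,
                          verbal = NA_real_) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) format_error(
                   sprintf("cannot parse %s: %s", path, conditionMessage(e))))
  if (!all(c("time_s", "level_pct") %in% names(df)))
    format_error(sprintf("%s: need columns time_s, level_pct", path))
  vection_record(subject_id, condition, trial_index,
                 throttle = df[c("time_s", "level_pct")], verbal = verbal)
}

#' @rdname read_throttle
#' @param record A [vection_record] whose throttle trace to serialise.
#' @export
write_throttle <- function(record, path) {
  stopifnot(inherits(record, "vection_record"))
  utils::write.csv(record$throttle, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
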