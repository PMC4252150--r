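#' Visually evoked postural response (VEPR)
#'
#' For each flow block in a blocked standing session, the VEPR is the mean
#' anterior-posterior CoP position during the flow exposure minus the mean
#' AP position during the entire block immediately preceding it (the
#' baseline, controlling for long-term postural drift). Forward-positive:
#' a negative VEPR is backward lean, the stereotyped response to expanding
#' flow; contracting flow drives a (substantially larger) forward lean.
#'
#' @param trace A (typically filtered) [cop_trace] of the session.
#' @param manifest The [session_manifest] with the block schedule; every
#'   flow block must be preceded by a non-flow block.
#' @return An object of class `vepr`: list with `subject_id`,
#'   `flow_direction`, `per_repeat` (signed mm, one per flow block) and
#'   `mean_vepr` (their arithmetic mean).
#' @export
compute_vepr <- function(trace, manifest) {
  stopifnot(inherits(trace, "cop_trace"), inherits(manifest, "session_manifest"))
  segs <- segment_session(trace, manifest)
  flow_idx <- which(segs$label == "flow")
  if (!length(flow_idx)) consistency_error("manifest has no flow block")
  if (any(flow_idx == 1L))
    consistency_error("flow block has no preceding baseline block")
  if (any(segs$label[flow_idx - 1L] == "flow"))
    consistency_error("flow block preceded by another flow block, not a baseline")
  per_repeat <- vapply(flow_idx, function(i) {
    flow_mean <- mean(trace$ap[segs$start[i]:segs$end[i]])
    base_mean <- mean(trace$ap[segs$start[i - 1L]:segs$end[i - 1L]])
    flow_mean - base_mean
  }, numeric(1))
  direction <- if (manifest$condition == "standing_flow_contracting")
    "contracting" else "expanding"
  structure(list(subject_id = manifest$subject_id,
                 flow_direction = direction,
                 per_repeat = per_repeat,
                 mean_vepr = mean(per_repeat)),
            class = "vepr")
}

#' @export
print.vepr <- function(x, ...) {
  dir_lab <- if (x$mean_vepr >= 0) "forward" else "backward"
  cat(sprintf("<vepr> subject %s, %s flow: mean %+.2f mm (%s), repeats: %s\n",
              x$subject_id, x$flow_direction, x$mean_vepr, dir_lab,
              paste(sprintf("%+.2f", x$per_repeat), collapse = " ")))
  invisible(x)
}

#' Throttle maximum
#'
#' The maximum continuous vection rating reached during a trial.
#'
#' @param record A [vection_record].
#' @return Percent in `[0, 100]`.
#' @export
throttle_max <- function(record) {
  stopifnot(inherits(record, "vection_record"))
  if (nrow(record$throttle) == 0L) data_error("empty throttle trace")
  max(record$throttle$level_pct)
}

#' Vection onset latency
#'
#' Time from stimulus onset until the continuous throttle rating first
#' reaches the cutoff (5% in the published analysis). Trials whose rating
#' never reaches the cutoff have no onset: the latency is missing (`NA`),
#' which is a value, not an error, and is excluded pairwise downstream.
#'
#' @param record A [vection_record] whose throttle times are measured from
#'   trial onset.
#' @param cutoff Onset threshold in percent, default 5.
#' @return Latency in seconds, or `NA_real_` if never reached.
#' @export
throttle_latency <- function(record, cutoff = 5) {
  stopifnot(inherits(record, "vection_record"))
  if (!is_scalar_number(cutoff) || cutoff < 0 || cutoff > 100)
    parameter_error("cutoff must lie in [0, 100]")
  if (nrow(record$throttle) == 0L) data_error("empty throttle trace")
  hit <- which(record$throttle$level_pct >= cutoff)
  if (!length(hit)) return(NA_real_)
  record$throttle$time_s[hit[1]]
}

#' Aggregate vection trials into a subject/condition summary
#'
#' Arithmetic means across trials of the verbal rating, throttle maximum
#' and onset latency. The latency mean is taken over trials with a defined
#' onset only; the number of onset-less trials is reported.
#'
#' @param records List of [vection_record]s for one subject and condition.
#' @param cutoff Latency cutoff passed to [throttle_latency()].
#' @return An object of class `vection_summary`: list with `subject_id`,
#'   `condition`, `n_trials`, `verbal_mean`, `throttle_max_mean`,
#'   `latency_mean` (NA if no trial crossed the cutoff) and
#'   `latency_missing` (count).
#' @export
aggregate_vection <- function(records, cutoff = 5) {
  if (!length(records)) data_error("no vection records to aggregate")
  stopifnot(all(vapply(records, inherits, logical(1), "vection_record")))
  sid <- unique(vapply(records, `[[`, character(1), "subject_id"))
  cond <- unique(vapply(records, `[[`, character(1), "condition"))
  if (length(sid) != 1L || length(cond) != 1L)
    consistency_error("records span multiple subjects or conditions")
  verbal <- vapply(records, `[[`, numeric(1), "verbal")
  tmax <- vapply(records, throttle_max, numeric(1))
  lat <- vapply(records, throttle_latency, numeric(1), cutoff = cutoff)
  structure(list(subject_id = sid, condition = cond,
                 n_trials = length(records),
                 verbal_mean = mean(verbal, na.rm = TRUE),
                 throttle_max_mean = mean(tmax),
                 latency_mean = if (all(is.na(lat))) NA_real_
                                else mean(lat, na.rm = TRUE),
                 latency_missing = sum(is.na(lat))),
            class = "vection_summary")
}
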