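#' Experimental conditions and block labels
#'
#' `sway_conditions()` lists the recognised session conditions: quiet stance
#' with eyes open or closed, standing exposure to expanding or contracting
#' optic flow (the blocked sessions from which visually evoked postural
#' responses are extracted), and the seated vection rating sessions.
#' `block_labels()` lists the block types a standing-flow schedule may
#' contain.
#'
#' @return Character vector of condition (resp. block label) names.
#' @export
sway_conditions <- function() {
  c("quiet_eyes_open", "quiet_eyes_closed",
    "standing_flow_expanding", "standing_flow_contracting",
    "seated_vection_expanding", "seated_vection_contracting")
}

#' @rdname sway_conditions
#' @export
block_labels <- function() c("blank", "flow", "fixation")

#' Session manifest
#'
#' Binds a recorded trace to its experimental structure: subject, condition,
#' sampling rate, and (for blocked standing-flow sessions) the ordered block
#' schedule. The canonical schedule is 30 s blank, 30 s optic flow, 30 s
#' blank, 30 s fixation, repeated three times (a 360 s session).
#'
#' @param subject_id Subject identifier string.
#' @param condition One of [sway_conditions()].
#' @param blocks `NULL`/empty for quiet stance, otherwise a data.frame with
#'   columns `label` (one of [block_labels()]) and `duration` (seconds > 0).
#' @param rate Sampling rate of the associated trace, Hz.
#' @param trace_file Optional path of the trace CSV (relative paths are
#'   resolved against the manifest's own directory when read from disk).
#' @param ap_forward_sign `+1` or `-1`; sign convention of the stored AP
#'   channel (see [read_cop_trace()]).
#' @return An object of class `session_manifest`.
#' @export
session_manifest <- function(subject_id, condition, blocks = NULL,
                             rate = 1000, trace_file = NULL,
                             ap_forward_sign = 1) {
  if (!is_scalar_string(subject_id)) format_error("subject_id must be a non-empty string")
  if (!is_scalar_string(condition) || !condition %in% sway_conditions())
    format_error(sprintf("unknown condition '%s'", condition))
  if (!is_scalar_number(rate) || rate <= 0) format_error("rate must be > 0")
  if (!ap_forward_sign %in% c(-1, 1)) format_error("ap_forward_sign must be +1 or -1")
  if (is.null(blocks) || (is.data.frame(blocks) && nrow(blocks) == 0L)) {
    blocks <- data.frame(label = character(), duration = numeric())
  } else {
    blocks <- as.data.frame(blocks)
    if (!all(c("label", "duration") %in% names(blocks)))
      format_error("blocks must have 'label' and 'duration' columns")
    blocks$label <- as.character(blocks$label)
    blocks$duration <- as.numeric(blocks$duration)
    if (!all(blocks$label %in% block_labels()))
      format_error(sprintf("unknown block label(s): %s",
                           paste(setdiff(blocks$label, block_labels()), collapse = ", ")))
    if (any(!is.finite(blocks$duration)) || any(blocks$duration <= 0))
      format_error("block durations must be finite and > 0")
  }
  if (startsWith(condition, "standing_flow") && nrow(blocks) == 0L)
    format_error("standing_flow sessions require a non-empty block schedule")
  structure(list(subject_id = subject_id, condition = condition,
                 blocks = blocks, rate = as.numeric(rate),
                 trace_file = trace_file,
                 ap_forward_sign = as.numeric(ap_forward_sign)),
            class = "session_manifest")
}

#' @export
print.session_manifest <- function(x, ...) {
  cat(sprintf("<session_manifest> subject %s, %s @ %g Hz\n",
              x$subject_id, x$condition, x$rate))
  if (nrow(x$blocks))
    cat("  blocks:", paste(sprintf("%s(%gs)", x$blocks$label, x$blocks$duration),
                           collapse = " "), "\n")
  invisible(x)
}

# Check a manifest's schedule against an actual trace. The schedule may be
# shorter than the trace (trailing slack) but never longer.
check_manifest_trace <- function(manifest, trace) {
  if (abs(manifest$rate - trace$rate) > 1e-9)
    consistency_error(sprintf("manifest rate %g Hz != trace rate %g Hz",
                              manifest$rate, trace$rate))
  total <- sum(manifest$blocks$duration)
  if (total > trace_duration(trace) + 1e-9)
    consistency_error(sprintf(
      "block schedule (%g s) exceeds trace duration (%g s)",
      total, trace_duration(trace)))
  invisible(TRUE)
}

#' Read / write a session manifest (YAML)
#'
#' Manifests are stored as small YAML documents with keys `subject_id`,
#' `condition`, `rate`, optional `trace_file`, `ap_forward_sign`, and a
#' `blocks` list of `{label, duration}` maps. When `trace_file` is present
#' and the file exists, the block schedule is validated against the trace
#' duration.
#'
#' @param path Manifest file path.
#' @param check_trace Validate the schedule against the trace file when it
#'   is available (default `TRUE`).
#' @return A [session_manifest].
#' @export
read_manifest <- function(path, check_trace = TRUE) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  y <- tryCatch(yaml::read_yaml(path),
                error = function(e) format_error(
                  sprintf("cannot parse manifest %s: %s", path, conditionMessage(e))))
  blocks <- NULL
  if (!is.null(y$blocks) && length(y$blocks)) {
    blocks <- data.frame(
      label = vapply(y$blocks, function(b) as.character(b$label), character(1)),
      duration = vapply(y$blocks, function(b) as.numeric(b$duration), numeric(1)))
  }
  m <- session_manifest(subject_id = y$subject_id, condition = y$condition,
                        blocks = blocks, rate = y$rate,
                        trace_file = y$trace_file,
                        ap_forward_sign = if (is.null(y$ap_forward_sign)) 1
                                          else y$ap_forward_sign)
  if (!is.null(m$trace_file)) {
    resolved <- m$trace_file
    if (!file.exists(resolved))
      resolved <- file.path(dirname(path), m$trace_file)
    if (file.exists(resolved)) {
      m$trace_file <- resolved
      if (check_trace && nrow(m$blocks)) {
        trace <- read_cop_trace(resolved, rate = m$rate,
                                ap_forward_sign = m$ap_forward_sign)
        check_manifest_trace(m, trace)
      }
    }
  }
  m
}

#' @rdname read_manifest
#' @param manifest A [session_manifest] to serialise.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "session_manifest"))
  y <- list(subject_id = manifest$subject_id,
            condition = manifest$condition,
            rate = manifest$rate,
            ap_forward_sign = manifest$ap_forward_sign)
  if (!is.null(manifest$trace_file)) y$trace_file <- basename(manifest$trace_file)
  if (nrow(manifest$blocks))
    y$blocks <- lapply(seq_len(nrow(manifest$blocks)), function(i)
      list(label = manifest$blocks$label[i],
           duration = manifest$blocks$duration[i]))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' The canonical standing-flow block schedule
#'
#' 30 s blank, 30 s flow, 30 s blank, 30 s fixation, repeated `repeats`
#' times.
#'
#' @param repeats Number of repetitions of the four-block sequence.
#' @param block_s Duration of each block in seconds.
#' @return A blocks data.frame suitable for [session_manifest()].
#' @export
standard_flow_blocks <- function(repeats = 3, block_s = 30) {
  one <- data.frame(label = c("blank", "flow", "blank", "fixation"),
                    duration = rep(block_s, 4))
  do.call(rbind, replicate(repeats, one, simplify = FALSE))
}
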