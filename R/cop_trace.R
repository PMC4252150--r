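#' Centre-of-pressure trace
#'
#' A `cop_trace` holds a two-channel force-plate centre-of-pressure (CoP)
#' trajectory: anterior-posterior (AP) and medial-lateral (ML) excursions in
#' millimetres, sampled uniformly. Internally AP is always forward-positive
#' and ML rightward-positive; readers convert plotting conventions that use
#' negative-forward axes via their `ap_forward_sign` argument.
#'
#' @param time Numeric vector of sample times in seconds, strictly
#'   increasing with constant step `1/rate` (tolerance 1e-9 s).
#' @param ap Anterior-posterior CoP in millimetres, forward-positive.
#' @param ml Medial-lateral CoP in millimetres, rightward-positive.
#' @param rate Sampling rate in Hz. If `NULL`, inferred as the reciprocal of
#'   the median time step.
#'
#' @return An object of class `cop_trace`: a list with elements `time`,
#'   `ap`, `ml` (numeric vectors of equal length) and `rate` (Hz).
#' @examples
#' tr <- cop_trace(time = seq(0, 0.999, by = 1e-3),
#'                 ap = sin(seq(0, 2 * pi, length.out = 1000)),
#'                 ml = rep(0, 1000), rate = 1000)
#' tr$rate
#' @export
cop_trace <- function(time, ap, ml, rate = NULL) {
  time <- as.numeric(time)
  ap <- as.numeric(ap)
  ml <- as.numeric(ml)
  n <- length(time)
  if (n < 2L) data_error("a CoP trace needs at least 2 samples")
  if (length(ap) != n || length(ml) != n)
    data_error("time, ap and ml must have identical length")
  if (anyNA(time) || anyNA(ap) || anyNA(ml))
    data_error("CoP trace contains missing values")
  dt <- diff(time)
  if (any(dt <= 0)) data_error("time must be strictly increasing")
  if (is.null(rate)) rate <- 1 / stats::median(dt)
  if (!is_scalar_number(rate) || rate <= 0)
    parameter_error("rate must be a positive number")
  if (max(abs(dt - 1 / rate)) > 1e-9)
    data_error(sprintf(
      "non-uniform sampling: max deviation from 1/%g s step is %.3g s (tolerance 1e-9)",
      rate, max(abs(dt - 1 / rate))))
  structure(list(time = time, ap = ap, ml = ml, rate = as.numeric(rate)),
            class = "cop_trace")
}

#' @export
print.cop_trace <- function(x, ...) {
  cat(sprintf("<cop_trace> %d samples @ %g Hz (%.3f s)\n",
              length(x$time), x$rate, length(x$time) / x$rate))
  cat(sprintf("  AP [mm]: mean %.3f, sd %.3f | ML [mm]: mean %.3f, sd %.3f\n",
              mean(x$ap), stats::sd(x$ap), mean(x$ml), stats::sd(x$ml)))
  invisible(x)
}

#' @export
length.cop_trace <- function(x) length(x$time)

trace_duration <- function(trace) length(trace$time) / trace$rate

#' Read a CoP trace from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row naming the columns
#' `time_s`, `ap_mm`, `ml_mm` (the names `time`, `ap`, `ml` are also
#' accepted). Decimal separator is `.`; units are seconds and millimetres.
#' The file must be hardware-clocked: gaps or jitter beyond 1e-9 s are a
#' data error, not something to resample away.
#'
#' @param path Path to the CSV file.
#' @param rate Expected sampling rate in Hz; inferred from the time column
#'   when `NULL`.
#' @param ap_forward_sign `+1` if the file stores forward sway as positive
#'   (the package convention), `-1` if it uses the plotting convention where
#'   negative values are forward; the AP channel is flipped accordingly so
#'   the returned trace is always forward-positive.
#' @return A [cop_trace].
#' @seealso [write_cop_trace()]
#' @export
read_cop_trace <- function(path, rate = NULL, ap_forward_sign = 1) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  if (!ap_forward_sign %in% c(-1, 1))
    parameter_error("ap_forward_sign must be +1 or -1")
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) format_error(
                   sprintf("cannot parse %s as CSV: %s", path, conditionMessage(e))))
  if (nrow(df) == 0L) data_error(sprintf("empty trace file: %s", path))
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(df)) return(df[[nm]])
    format_error(sprintf("%s: missing required column (one of: %s)",
                         path, paste(c(...), collapse = ", ")))
  }
  time <- pick("time_s", "time")
  ap <- pick("ap_mm", "ap")
  ml <- pick("ml_mm", "ml")
  cop_trace(time = time, ap = ap_forward_sign * as.numeric(ap),
            ml = ml, rate = rate)
}

#' Write a CoP trace to CSV
#'
#' Writes columns `time_s`, `ap_mm`, `ml_mm` with full double precision so
#' that a read/write round-trip is lossless to well below 1e-9.
#'
#' @param trace A [cop_trace].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cop_trace <- function(trace, path) {
  stopifnot(inherits(trace, "cop_trace"))
  df <- data.frame(time_s = trace$time, ap_mm = trace$ap, ml_mm = trace$ml)
  ok <- tryCatch({
    utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) io_error(sprintf("cannot write %s", path))
  invisible(path)
}
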