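#' Butterworth filter specification
#'
#' Defaults follow posturographic convention: an order-5 low-pass applied in
#' both directions (zero phase). The cutoff is not a universal constant —
#' CoP signal energy sits below roughly 10 Hz, so 10 Hz is the default —
#' and it is always recorded alongside results.
#'
#' @param order Filter order (>= 1), default 5.
#' @param cutoff Cutoff frequency in Hz, default 10; must be below the
#'   Nyquist frequency of the trace it is applied to.
#' @param kind Only `"lowpass"` is supported.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(order = 5, cutoff = 10, kind = "lowpass") {
  if (!is_scalar_number(order) || order < 1 || order != round(order))
    parameter_error("order must be a positive integer")
  if (!is_scalar_number(cutoff) || cutoff <= 0)
    parameter_error("cutoff must be > 0")
  kind <- match.arg(kind, "lowpass")
  structure(list(order = as.integer(order), cutoff = cutoff, kind = kind),
            class = "filter_spec")
}

# Zero-phase filtering with MATLAB-style odd-reflection end padding, so a
# constant (DC) input passes through exactly and edge transients do not leak
# into the retained span.
filtfilt_padded <- function(filt, x) {
  n <- length(x)
  npad <- min(n - 1L, 3L * (length(filt$b) + length(filt$a)))
  head_pad <- 2 * x[1] - x[(npad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - npad)]
  xp <- c(head_pad, x, tail_pad)
  y <- signal::filtfilt(filt, xp)
  y[(npad + 1):(npad + n)]
}

#' Zero-phase Butterworth low-pass of a CoP trace
#'
#' Applies the filter forward and backward (squaring the magnitude
#' response, doubling the effective order, and cancelling phase) to the AP
#' and ML channels independently. Length, rate and time axis are unchanged.
#'
#' @param trace A [cop_trace].
#' @param spec A [filter_spec].
#' @return The filtered [cop_trace].
#' @examples
#' tr <- cop_trace(seq(0, 0.999, 1e-3), rnorm(1000), rnorm(1000), 1000)
#' flt <- butterworth_filter(tr, filter_spec(order = 5, cutoff = 10))
#' var(flt$ap) < var(tr$ap)
#' @export
butterworth_filter <- function(trace, spec = filter_spec()) {
  stopifnot(inherits(trace, "cop_trace"))
  if (!inherits(spec, "filter_spec")) spec <- do.call(filter_spec, as.list(spec))
  nyq <- trace$rate / 2
  if (spec$cutoff >= nyq)
    parameter_error(sprintf("cutoff %g Hz must be below Nyquist (%g Hz)",
                            spec$cutoff, nyq))
  if (length(trace$time) <= 3 * spec$order)
    data_error("trace too short to filter (need length > 3 * order)")
  bf <- signal::butter(spec$order, spec$cutoff / nyq, type = "low")
  # filter around the channel mean: numerically safer at low relative cutoffs
  ap_m <- mean(trace$ap); ml_m <- mean(trace$ml)
  cop_trace(time = trace$time,
            ap = filtfilt_padded(bf, trace$ap - ap_m) + ap_m,
            ml = filtfilt_padded(bf, trace$ml - ml_m) + ml_m,
            rate = trace$rate)
}

#' Boxcar reduction of a CoP trace
#'
#' `mode = "decimate"` (the default) averages non-overlapping windows of
#' `width` consecutive samples — true downsampling, so a 60 s trace at
#' 1000 Hz with `width = 10` becomes a 6000-sample, 100 Hz series, the form
#' the recurrence analysis consumes. A trailing remainder shorter than
#' `width` is discarded (never padded); the discard count is returned as the
#' `discarded` attribute. `mode = "moving"` instead applies a centred
#' moving average at the original rate (edges trimmed), provided as a
#' logged alternative.
#'
#' @param trace A [cop_trace].
#' @param width Window width in samples (>= 1). `width = 1` is the
#'   identity.
#' @param mode `"decimate"` or `"moving"`.
#' @return A [cop_trace]; for `"decimate"` the rate is `rate / width` and
#'   times are window centres.
#' @export
boxcar_downsample <- function(trace, width = 10, mode = c("decimate", "moving")) {
  stopifnot(inherits(trace, "cop_trace"))
  mode <- match.arg(mode)
  if (!is_scalar_number(width) || width < 1 || width != round(width))
    parameter_error("width must be an integer >= 1")
  width <- as.integer(width)
  n <- length(trace$time)
  if (n < width) data_error("trace shorter than one boxcar window")
  if (width == 1L) {
    out <- trace
    attr(out, "discarded") <- 0L
    return(out)
  }
  if (mode == "decimate") {
    k <- n %/% width
    keep <- seq_len(k * width)
    win_mean <- function(x) colMeans(matrix(x[keep], nrow = width))
    out <- cop_trace(time = win_mean(trace$time), ap = win_mean(trace$ap),
                     ml = win_mean(trace$ml), rate = trace$rate / width)
    attr(out, "discarded") <- n - k * width
    return(out)
  }
  # moving average, centred; NA edges trimmed symmetrically
  ma <- function(x) stats::filter(x, rep(1 / width, width), sides = 2)
  ap <- ma(trace$ap); ml <- ma(trace$ml)
  ok <- which(!is.na(ap))
  out <- cop_trace(time = trace$time[ok], ap = as.numeric(ap[ok]),
                   ml = as.numeric(ml[ok]), rate = trace$rate)
  attr(out, "discarded") <- n - length(ok)
  out
}

#' Cut a blocked session into per-block segments
#'
#' Converts a manifest's block schedule into sample-index segments of the
#' trace. Segment `i` covers rows `start[i]:end[i]` (1-based, inclusive);
#' consecutive segments tile the scheduled span with no gap and no overlap.
#'
#' @param trace A [cop_trace].
#' @param manifest A [session_manifest] whose schedule fits within the
#'   trace.
#' @return data.frame with columns `label`, `start`, `end`, `n`.
#' @export
segment_session <- function(trace, manifest) {
  stopifnot(inherits(trace, "cop_trace"), inherits(manifest, "session_manifest"))
  if (nrow(manifest$blocks) == 0L) {
    # unscheduled (quiet stance): the whole trace is one blank block
    return(data.frame(label = "blank", start = 1L, end = length(trace$time),
                      n = length(trace$time)))
  }
  check_manifest_trace(manifest, trace)
  n_samp <- round(manifest$blocks$duration * trace$rate)
  ends <- cumsum(n_samp)
  starts <- c(1, head(ends, -1) + 1)
  if (ends[length(ends)] > length(trace$time))
    consistency_error("block schedule exceeds trace length")
  data.frame(label = manifest$blocks$label,
             start = as.integer(starts), end = as.integer(ends),
             n = as.integer(n_samp))
}
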