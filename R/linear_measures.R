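#' Total sway path length
#'
#' The distance travelled by the CoP over the trace: the sum of Euclidean
#' distances between consecutive (AP, ML) points,
#' \deqn{L = \sum_{i=1}^{N-1} \sqrt{(x_{i+1}-x_i)^2 + (y_{i+1}-y_i)^2}.}
#' Units follow the trace (millimetres). Computed on the filtered — not
#' boxcar-reduced — trace in the standard pipeline, since downsampling
#' shortens paths.
#'
#' @param trace A [cop_trace] with at least 2 samples.
#' @return Path length in mm.
#' @examples
#' tr <- cop_trace(c(0, 1e-3), ap = c(0, 3), ml = c(0, 4), rate = 1000)
#' path_length(tr)  # 5
#' @export
path_length <- function(trace) {
  stopifnot(inherits(trace, "cop_trace"))
  if (length(trace$time) < 2L) data_error("path length needs >= 2 samples")
  sum(sqrt(diff(trace$ap)^2 + diff(trace$ml)^2))
}

#' 95% confidence-ellipse sway area
#'
#' Fits the prediction ellipse of the (AP, ML) point cloud from the
#' eigen-decomposition of its 2x2 sample covariance matrix (the principal
#' axes of the sway scatter). Semi-axes are `sqrt(q * lambda_k)` where
#' `lambda_k` are the eigenvalues and `q` the coverage quantile —
#' `qchisq(coverage, df = 2)` (5.991 at 95%) by default, or the
#' small-sample F-corrected quantile `2 (n-1)/(n-2) qf(coverage, 2, n-2)`
#' when `small_sample = TRUE`. The area is
#' `pi * q * sqrt(lambda1 * lambda2)`.
#'
#' @param trace A [cop_trace] with at least 3 non-collinear points.
#' @param coverage Coverage probability, default 0.95.
#' @param small_sample Use the F-based quantile instead of the chi-square
#'   one (matters at small n).
#' @return An object of class `ellipse_fit`: list with `center` (mm),
#'   `semi_axes` (a >= b, mm), `orientation` (radians, angle of the major
#'   axis in the (AP, ML) plane), `area` (mm^2), `lambda` (eigenvalues,
#'   mm^2), `coverage_quantile` and `n`.
#' @export
confidence_ellipse <- function(trace, coverage = 0.95, small_sample = FALSE) {
  stopifnot(inherits(trace, "cop_trace"))
  if (!is_scalar_number(coverage) || coverage <= 0 || coverage >= 1)
    parameter_error("coverage must lie in (0, 1)")
  n <- length(trace$ap)
  if (n < 3L) data_error("ellipse fit needs >= 3 points")
  pts <- cbind(trace$ap, trace$ml)
  S <- stats::cov(pts)  # n - 1 denominator
  eg <- eigen(S, symmetric = TRUE)
  lambda <- eg$values
  if (lambda[1] <= 0 || lambda[2] <= 0 || lambda[1] / lambda[2] > 1e12)
    degenerate_error("degenerate (collinear or constant) CoP cloud")
  q <- if (small_sample) {
    if (n < 4L) data_error("F-corrected quantile needs n >= 4")
    2 * (n - 1) / (n - 2) * stats::qf(coverage, 2, n - 2)
  } else {
    stats::qchisq(coverage, df = 2)
  }
  structure(list(center = c(ap = mean(trace$ap), ml = mean(trace$ml)),
                 semi_axes = sqrt(q * lambda),
                 orientation = atan2(eg$vectors[2, 1], eg$vectors[1, 1]),
                 area = pi * q * sqrt(lambda[1] * lambda[2]),
                 lambda = lambda,
                 coverage_quantile = q,
                 coverage = coverage,
                 n = n),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("<ellipse_fit> %.0f%% coverage: area %.3f mm^2, semi-axes %.3f x %.3f mm, %.1f deg\n",
              100 * x$coverage, x$area, x$semi_axes[1], x$semi_axes[2],
              x$orientation * 180 / pi))
  invisible(x)
}

#' Romberg ratio
#'
#' Eyes-closed sway path divided by eyes-open sway path; values above 1
#' index reliance on vision for postural stability.
#'
#' @param path_closed,path_open Positive path lengths (same units).
#' @return The unitless ratio `path_closed / path_open`.
#' @examples
#' romberg_ratio(1.23, 0.68)  # ~1.809
#' @export
romberg_ratio <- function(path_closed, path_open) {
  if (!is_scalar_number(path_closed) || path_closed <= 0 ||
      !is_scalar_number(path_open) || path_open <= 0)
    parameter_error("path lengths must be positive")
  path_closed / path_open
}

#' Log sway-area ratio
#'
#' Natural log of the eyes-open to eyes-closed 95% ellipse area ratio.
#' Zero means equal areas; the log transform symmetrises the ratio for
#' correlation analyses (any other base would only rescale it).
#'
#' @param area_open,area_closed Positive areas (same units).
#' @return `log(area_open / area_closed)`.
#' @export
log_area_ratio <- function(area_open, area_closed) {
  if (!is_scalar_number(area_open) || area_open <= 0 ||
      !is_scalar_number(area_closed) || area_closed <= 0)
    parameter_error("areas must be positive")
  log(area_open / area_closed)
}

#' Linear sway summary of a quiet-stance trace
#'
#' @param trace A [cop_trace].
#' @param coverage Ellipse coverage probability.
#' @return List with `path_length` (mm), `area` (mm^2), `ap_mean`, `ap_sd`
#'   and `ap_range` (mm).
#' @export
sway_summary <- function(trace, coverage = 0.95) {
  stopifnot(inherits(trace, "cop_trace"))
  list(path_length = path_length(trace),
       area = confidence_ellipse(trace, coverage)$area,
       ap_mean = mean(trace$ap),
       ap_sd = stats::sd(trace$ap),
       ap_range = diff(range(trace$ap)))
}
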