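#' Recurrence quantification parameters
#'
#' Defaults reproduce the published centre-of-pressure analysis this
#' package implements: embedding dimension 8, delay 15 samples, recurrence
#' radius 30 in absolute signal units, minimum line length 4, Euclidean
#' phase-space norm, and no Theiler exclusion band (so the identity line is
#' part of the recurrence rate, as in the plain definition
#' `RR = N^-2 sum R_ij`). The radius can instead be expressed as a fraction
#' of the mean pairwise phase-space distance (`radius_mode =
#' "fraction_of_mean_distance"`), which makes analyses portable across
#' signals of different amplitude or hardware units; that reference
#' distance is computed over at most 1024 evenly spaced embedded vectors
#' (exact for shorter series, deterministic always).
#'
#' @param m Embedding dimension (>= 1).
#' @param tau Embedding delay in samples (>= 1).
#' @param radius Recurrence threshold: absolute distance in signal units,
#'   or a fraction of the mean pairwise distance depending on
#'   `radius_mode`. Must be > 0.
#' @param lmin Minimum diagonal/vertical line length for the line-based
#'   measures (>= 2).
#' @param norm Phase-space norm, `"euclidean"` or `"maximum"`.
#' @param theiler Half-width of the excluded band around the identity
#'   line; 0 keeps the identity line (the published convention here).
#' @param radius_mode `"absolute"` or `"fraction_of_mean_distance"`.
#' @return An object of class `rqa_params`.
#' @export
rqa_params <- function(m = 8, tau = 15, radius = 30, lmin = 4,
                       norm = c("euclidean", "maximum"), theiler = 0,
                       radius_mode = c("absolute", "fraction_of_mean_distance")) {
  norm <- match.arg(norm)
  radius_mode <- match.arg(radius_mode)
  if (!is_scalar_number(m) || m < 1 || m != round(m))
    parameter_error("m must be an integer >= 1")
  if (!is_scalar_number(tau) || tau < 1 || tau != round(tau))
    parameter_error("tau must be an integer >= 1")
  if (!is_scalar_number(radius) || radius <= 0)
    parameter_error("radius must be > 0")
  if (!is_scalar_number(lmin) || lmin < 2 || lmin != round(lmin))
    parameter_error("lmin must be an integer >= 2")
  if (!is_scalar_number(theiler) || theiler < 0 || theiler != round(theiler))
    parameter_error("theiler must be an integer >= 0")
  structure(list(m = as.integer(m), tau = as.integer(tau), radius = radius,
                 lmin = as.integer(lmin), norm = norm,
                 theiler = as.integer(theiler), radius_mode = radius_mode),
            class = "rqa_params")
}

#' Time-delay embedding
#'
#' Reconstructs the phase space of a scalar series: embedded vector `i` is
#' `(x_i, x_{i+tau}, ..., x_{i+(m-1)tau})`, giving `N - (m-1) tau` vectors
#' from an `N`-sample series.
#'
#' @param x Numeric series of length at least `(m-1) * tau + 1`.
#' @param m Embedding dimension.
#' @param tau Delay in samples.
#' @return A numeric matrix with one embedded vector per row (`m`
#'   columns). For `m = 1` this is the series itself as a column.
#' @examples
#' embed_series(1:5, m = 2, tau = 2)  # rows (1,3), (2,4), (3,5)
#' @export
embed_series <- function(x, m, tau) {
  x <- as.numeric(x)
  m <- as.integer(m); tau <- as.integer(tau)
  if (m < 1L || tau < 1L) parameter_error("m and tau must be >= 1")
  n <- length(x)
  n_emb <- n - (m - 1L) * tau
  if (n_emb < 1L)
    data_error(sprintf("series too short to embed: N = %d < (m-1)*tau + 1 = %d",
                       n, (m - 1L) * tau + 1L))
  out <- vapply(seq_len(m) - 1L, function(k) x[seq_len(n_emb) + k * tau],
                numeric(n_emb))
  if (n_emb == 1L) out <- matrix(out, nrow = 1L)
  out
}

#' Recurrence matrix of an embedded series
#'
#' `R[i, j] = 1` iff the phase-space distance between embedded vectors `i`
#' and `j` is at most the radius (a distance exactly equal to the radius
#' counts as recurrent). The matrix is symmetric; the identity line is all
#' ones when `theiler = 0` and the whole band `|i - j| <= theiler` is
#' forced to zero when `theiler > 0`.
#'
#' @param emb Embedding matrix from [embed_series()] (rows = vectors), or a
#'   numeric vector (treated as an `m = 1` embedding).
#' @param params An [rqa_params]. Under
#'   `radius_mode = "fraction_of_mean_distance"` the threshold is resolved
#'   to `radius * mean pairwise distance` of this embedding.
#' @return Integer 0/1 matrix with attributes `radius_used` (the resolved
#'   absolute threshold) and `params`.
#' @export
recurrence_matrix <- function(emb, params = rqa_params()) {
  if (is.null(dim(emb))) emb <- matrix(as.numeric(emb), ncol = 1L)
  storage.mode(emb) <- "double"
  if (nrow(emb) < 2L) data_error("need at least 2 embedded vectors")
  if (params$radius <= 0) parameter_error("radius must be > 0")
  euclid <- params$norm == "euclidean"
  eps <- params$radius
  if (params$radius_mode == "fraction_of_mean_distance")
    eps <- params$radius * .cpp_mean_pairwise_distance(emb, euclid)
  R <- .cpp_recurrence_matrix(emb, eps, euclid, params$theiler)
  attr(R, "radius_used") <- eps
  attr(R, "params") <- params
  R
}

#' Recurrence rate
#'
#' The density of recurrent points, `RR = (1/N^2) sum_ij R_ij` — the
#' probability that any state recurs. With `theiler = 0` the identity line
#' contributes, so `RR >= 1/N`.
#'
#' @param R A recurrence matrix from [recurrence_matrix()].
#' @return Fraction in `(0, 1]`.
#' @export
recurrence_rate <- function(R) {
  if (is.null(dim(R)) || nrow(R) == 0L) data_error("empty recurrence matrix")
  sum(as.numeric(R)) / (nrow(R)^2)
}

#' Diagonal and vertical line-length histograms
#'
#' Collects the lengths of maximal runs of recurrent points along the
#' upper-triangle diagonals (the identity line is always excluded, as is
#' any Theiler band; by symmetry each diagonal line is counted once) and
#' along the columns of the matrix as stored. These feed the determinism,
#' laminarity, mean-line, trapping-time and entropy measures.
#'
#' @param R A recurrence matrix.
#' @param theiler Exclusion half-width used when scanning diagonals;
#'   defaults to the value recorded in the matrix's parameters.
#' @return List with integer vectors `diagonal` and `vertical` of run
#'   lengths (one entry per maximal line, unsorted).
#' @export
line_histograms <- function(R, theiler = NULL) {
  if (is.null(dim(R)) || nrow(R) < 1L) data_error("invalid recurrence matrix")
  if (is.null(theiler)) {
    p <- attr(R, "params")
    theiler <- if (is.null(p)) 0L else p$theiler
  }
  storage.mode(R) <- "integer"
  list(diagonal = .cpp_diagonal_line_lengths(R, as.integer(theiler)),
       vertical = .cpp_vertical_line_lengths(R))
}

# Shannon entropy (nats) of a vector of line lengths, over the normalised
# distribution of lengths >= lmin.
line_entropy <- function(lengths) {
  p <- tabulate(lengths)
  p <- p[p > 0] / sum(p)
  -sum(p * log(p))
}

#' Scalar recurrence measures
#'
#' Computes, from a recurrence matrix, the standard recurrence-plot
#' measures:
#' \describe{
#'   \item{rr}{recurrence rate, `sum(R) / N^2` (identity line included
#'     when `theiler = 0`).}
#'   \item{det}{determinism — the fraction of off-identity recurrent
#'     points lying on diagonal lines of length >= `lmin`.}
#'   \item{l_mean}{mean diagonal line length over lines >= `lmin`.}
#'   \item{entr}{Shannon entropy (nats) of the diagonal line-length
#'     distribution over lines >= `lmin`.}
#'   \item{lam}{laminarity — the fraction of recurrent points lying on
#'     vertical lines of length >= `lmin`.}
#'   \item{tt}{trapping time — mean vertical line length over lines >=
#'     `lmin`.}
#'   \item{trend}{least-squares slope of per-diagonal recurrence density
#'     against distance from the identity line (the outermost 10% of
#'     offsets, where diagonals are short and densities noisy, are
#'     excluded from the fit).}
#' }
#' When no line reaches `lmin`, the affected line-based measures are
#' returned as `NA` (missing, not zero).
#'
#' @param R A recurrence matrix from [recurrence_matrix()].
#' @param params The [rqa_params] used to build it (defaults to the ones
#'   recorded on the matrix).
#' @return An object of class `rqa_result`: list with fields `rr`, `det`,
#'   `lam`, `l_mean`, `tt`, `entr`, `trend`, `n_embedded`, `radius_used`
#'   and `params`.
#' @export
rqa_measures <- function(R, params = NULL) {
  if (is.null(params)) params <- attr(R, "params")
  if (is.null(params)) params <- rqa_params()
  hist <- line_histograms(R, theiler = params$theiler)
  rqa_result_from_parts(total = sum(as.numeric(R)), n = nrow(R),
                        dl = hist$diagonal, vl = hist$vertical,
                        dens = .cpp_diagonal_density(R), params = params,
                        radius_used = attr(R, "radius_used"))
}

# Assemble an rqa_result from the counting primitives (shared by the
# matrix-based path and the fused engine behind rqa()).
rqa_result_from_parts <- function(total, n, dl, vl, dens, params,
                                  radius_used) {
  lmin <- params$lmin
  rr <- total / n^2
  # recurrent points off the identity line / outside the band, upper triangle
  off_upper <- (total - if (params$theiler == 0L) n else 0) / 2
  dl_long <- dl[dl >= lmin]
  det <- if (off_upper > 0 && length(dl_long)) sum(dl_long) / off_upper else NA_real_
  l_mean <- if (length(dl_long)) mean(dl_long) else NA_real_
  entr <- if (length(dl_long)) line_entropy(dl_long) else NA_real_
  vl_long <- vl[vl >= lmin]
  lam <- if (total > 0 && length(vl_long)) sum(vl_long) / total else NA_real_
  tt <- if (length(vl_long)) mean(vl_long) else NA_real_
  trend <- NA_real_
  if (n >= 10L) {
    k <- seq_len(n - 1L)
    keep <- k > params$theiler & k <= floor(0.9 * (n - 1L))
    if (sum(keep) >= 3L) {
      kk <- k[keep]; dd <- dens[keep]
      trend <- stats::cov(kk, dd) / stats::var(kk)
    }
  }
  structure(list(rr = rr, det = det, lam = lam, l_mean = l_mean, tt = tt,
                 entr = entr, trend = trend, n_embedded = n,
                 radius_used = radius_used, params = params),
            class = "rqa_result")
}

#' @export
print.rqa_result <- function(x, ...) {
  cat(sprintf(paste0("<rqa_result> n = %d embedded vectors ",
                     "(m = %d, tau = %d, radius = %g [%s], lmin = %d)\n"),
              x$n_embedded, x$params$m, x$params$tau, x$params$radius,
              x$params$radius_mode, x$params$lmin))
  cat(sprintf("  RR %.4f | DET %.3f | LAM %.3f | L %.2f | TT %.2f | ENTR %.3f | trend %.3g\n",
              x$rr, x$det, x$lam, x$l_mean, x$tt, x$entr, x$trend))
  invisible(x)
}

#' Full recurrence analysis of a scalar series
#'
#' Convenience wrapper: embed, threshold, and compute all scalar measures.
#' In the published pipeline the input is the boxcar-reduced (100 Hz)
#' anterior-posterior quiet-stance series.
#'
#' @param x Numeric series (e.g. the AP channel of a reduced
#'   [cop_trace]).
#' @param params An [rqa_params].
#' @return An [rqa_measures()] result.
#' @examples
#' x <- sin(seq(0, 20 * pi, length.out = 500))
#' rqa(x, rqa_params(m = 2, tau = 5, radius = 0.2))$det
#' @export
rqa <- function(x, params = rqa_params()) {
  emb <- embed_series(x, params$m, params$tau)
  if (nrow(emb) < 2L) data_error("need at least 2 embedded vectors")
  euclid <- params$norm == "euclidean"
  eps <- params$radius
  if (params$radius_mode == "fraction_of_mean_distance")
    eps <- params$radius * .cpp_mean_pairwise_distance(emb, euclid)
  parts <- .cpp_rqa_engine(emb, eps, euclid, params$theiler)
  rqa_result_from_parts(total = parts$total, n = parts$n,
                        dl = parts$diagonal, vl = parts$vertical,
                        dens = parts$density, params = params,
                        radius_used = eps)
}

#' Eyes-open minus eyes-closed recurrence rate
#'
#' The signed quiet-stance recurrence contrast: negative values mean the
#' subject's sway is relatively more recurrent with eyes closed — the
#' signature associated with stronger vection.
#'
#' @param result_open,result_closed [rqa_measures()] results computed with
#'   identical parameters.
#' @return `rr_open - rr_closed` (signed fraction).
#' @export
rr_difference <- function(result_open, result_closed) {
  stopifnot(inherits(result_open, "rqa_result"),
            inherits(result_closed, "rqa_result"))
  po <- result_open$params; pc <- result_closed$params
  same <- identical(po$m, pc$m) && identical(po$tau, pc$tau) &&
    identical(po$radius, pc$radius) && identical(po$norm, pc$norm) &&
    identical(po$theiler, pc$theiler) && identical(po$lmin, pc$lmin) &&
    identical(po$radius_mode, pc$radius_mode)
  if (!same)
    consistency_error("RQA results were computed with different parameters")
  result_open$rr - result_closed$rr
}
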