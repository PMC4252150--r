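#' Pearson correlation with pairwise deletion
#'
#' Sample Pearson r between two numeric vectors after pairwise deletion of
#' missing values, with the two-sided p-value from the t transform on
#' `n - 2` degrees of freedom. Raw p-values only — no multiplicity
#' adjustment is applied here (see [correlation_table()], which reports the
#' number of tests so users can adjust themselves).
#'
#' @param x,y Numeric vectors of equal length (paired by subject).
#' @param feature,outcome Optional labels carried into the result.
#' @return An object of class `correlation_result`: list with `feature`,
#'   `outcome`, `r`, `p`, `n` (pairs used after deletion) and `df`.
#' @export
pearson_cor <- function(x, y, feature = "x", outcome = "y") {
  if (length(x) != length(y)) data_error("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) data_error(sprintf("need >= 3 complete pairs, got %d", n))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    degenerate_error("undefined correlation: zero variance in an argument")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(feature = feature, outcome = outcome,
                 r = unname(ct$estimate), p = ct$p.value, n = n,
                 df = unname(ct$parameter)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation> %s ~ %s: r = %.3f (p = %.4g, n = %d)\n",
              x$feature, x$outcome, x$r, x$p, x$n))
  invisible(x)
}

#' Paired t-test
#'
#' Two-sided paired t-test, `t = mean(a - b) / (sd(a - b) / sqrt(n))` on
#' `n - 1` degrees of freedom. Constant differences (zero variance) are a
#' degenerate error rather than an infinite statistic.
#'
#' @param a,b Equal-length numeric vectors paired by subject.
#' @return An object of class `paired_test_result`: list with `mean_diff`,
#'   `t`, `df` and `p`.
#' @examples
#' paired_t(c(2, 4, 6), c(1, 2, 3))  # t = 3.464, df = 2
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) data_error("a and b must have equal length")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2L) data_error("need >= 2 complete pairs")
  d <- a - b
  if (stats::sd(d) == 0)
    degenerate_error("degenerate paired t-test: differences have zero variance")
  tt <- stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
  structure(list(mean_diff = unname(tt$estimate), t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("<paired t> mean diff %.4g, t(%d) = %.3f, p = %.4g\n",
              x$mean_diff, x$df, x$t, x$p))
  invisible(x)
}

#' Default feature/outcome correlation layouts
#'
#' `vepr_correlation_pairs()` mirrors the VEPR-by-vection table (each flow
#' direction's VEPR against the matching direction's verbal, throttle-max
#' and latency outcomes); `rqa_correlation_pairs()` mirrors the
#' recurrence-by-vection table (the eyes-open-minus-closed recurrence
#' difference, eyes-open and eyes-closed recurrence rates against verbal
#' and throttle-max outcomes for both directions).
#'
#' @return data.frame with columns `feature` and `outcome` naming feature
#'   table columns.
#' @export
rqa_correlation_pairs <- function() {
  expand.grid(
    feature = c("rr_diff", "rr_eo", "rr_ec"),
    outcome = c("verbal_expanding", "throttle_max_expanding",
                "verbal_contracting", "throttle_max_contracting"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[, c("feature", "outcome")]
}

#' @rdname rqa_correlation_pairs
#' @export
vepr_correlation_pairs <- function() {
  rbind(
    expand.grid(feature = "vepr_expanding",
                outcome = c("verbal_expanding", "throttle_max_expanding",
                            "latency_expanding"),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    expand.grid(feature = "vepr_contracting",
                outcome = c("verbal_contracting", "throttle_max_contracting",
                            "latency_contracting"),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
}

#' Correlation table over a feature table
#'
#' Computes one Pearson correlation per requested (feature, outcome) pair,
#' with pairwise-complete observations, preserving the requested order.
#' Pairs whose correlation is undefined (zero variance or too few complete
#' pairs) are flagged in the `note` column with `NA` statistics rather
#' than aborting the table. The number of tests performed is attached as
#' the `n_tests` attribute; no multiplicity adjustment is applied.
#'
#' @param features A [feature_table].
#' @param pairs data.frame with character columns `feature` and `outcome`
#'   naming feature-table columns (defaults to the recurrence layout).
#' @return data.frame with columns `feature`, `outcome`, `r`, `p`, `n`,
#'   `note`.
#' @export
correlation_table <- function(features, pairs = rqa_correlation_pairs()) {
  features <- feature_table(features)
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) == 0L)
    return(data.frame(feature = character(), outcome = character(),
                      r = numeric(), p = numeric(), n = integer(),
                      note = character()))
  if (!all(c("feature", "outcome") %in% names(pairs)))
    spec_error("pairs must have 'feature' and 'outcome' columns")
  unknown <- setdiff(unique(c(pairs$feature, pairs$outcome)), names(features))
  if (length(unknown))
    spec_error(sprintf("unknown feature table column(s): %s",
                       paste(unknown, collapse = ", ")))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    f <- as.character(pairs$feature[i]); o <- as.character(pairs$outcome[i])
    res <- tryCatch(pearson_cor(features[[f]], features[[o]], f, o),
                    swayrqa_degenerate_error = function(e) e,
                    swayrqa_data_error = function(e) e)
    if (inherits(res, "correlation_result")) {
      data.frame(feature = f, outcome = o, r = res$r, p = res$p, n = res$n,
                 note = "")
    } else {
      data.frame(feature = f, outcome = o, r = NA_real_, p = NA_real_,
                 n = sum(is.finite(features[[f]]) & is.finite(features[[o]])),
                 note = conditionMessage(res))
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "n_tests") <- nrow(out)
  out
}
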