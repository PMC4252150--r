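# Independent brute-force oracles, deliberately written as plain loops over
# the definitions so they share no code path with the package internals.

oracle_path_length <- function(ap, ml) {
  total <- 0
  for (i in seq_len(length(ap) - 1)) {
    total <- total + sqrt((ap[i + 1] - ap[i])^2 + (ml[i + 1] - ml[i])^2)
  }
  total
}

oracle_dist <- function(a, b, norm) {
  if (norm == "euclidean") sqrt(sum((a - b)^2)) else max(abs(a - b))
}

oracle_recurrence_matrix <- function(emb, radius, norm = "euclidean",
                                     theiler = 0) {
  n <- nrow(emb)
  R <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) <= theiler) {
        R[i, j] <- if (theiler == 0 && i == j) 1L else 0L
      } else {
        R[i, j] <- as.integer(oracle_dist(emb[i, ], emb[j, ], norm) <= radius)
      }
    }
  }
  R
}

# run lengths of 1s in a 0/1 vector
oracle_runs <- function(x) {
  r <- rle(x)
  r$lengths[r$values == 1]
}

oracle_diag_lengths <- function(R, theiler = 0) {
  n <- nrow(R)
  out <- integer(0)
  for (k in seq(theiler + 1, n - 1)) {
    idx <- cbind(seq_len(n - k), seq_len(n - k) + k)
    out <- c(out, oracle_runs(R[idx]))
  }
  out
}

oracle_vert_lengths <- function(R) {
  out <- integer(0)
  for (j in seq_len(ncol(R))) out <- c(out, oracle_runs(R[, j]))
  out
}

# tiny helpers used across test files
make_trace <- function(ap, ml = rep(0, length(ap)), rate = 1000) {
  cop_trace(time = (seq_along(ap) - 1) / rate, ap = ap, ml = ml, rate = rate)
}

random_trace <- function(n, rate = 1000, seed = 1) {
  set.seed(seed)
  make_trace(stats::rnorm(n), stats::rnorm(n), rate = rate)
}
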