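test_that("time-delay embedding enumerates lagged coordinates", {
  expect_equal(embed_series(1:5, 2, 2),
               cbind(c(1, 2, 3), c(3, 4, 5)))
  # m = 1 is the identity embedding
  expect_equal(as.numeric(embed_series(4:9, 1, 3)), as.numeric(4:9))
  # count identity on the published configuration
  expect_equal(nrow(embed_series(rnorm(6000), 8, 15)), 5895L)
  expect_error(embed_series(1:10, 8, 15), class = "swayrqa_data_error")
})

test_that("recurrence matrix follows the thresholded-distance definition", {
  # constant series: all distances zero, all entries recurrent
  Rc <- recurrence_matrix(embed_series(rep(2, 12), 2, 1),
                          rqa_params(m = 2, tau = 1, radius = 0.5))
  expect_true(all(Rc == 1L))

  # boundary convention: distance exactly equal to radius is recurrent
  emb <- rbind(c(0, 0), c(3, 4))
  Rb <- recurrence_matrix(emb, rqa_params(m = 2, tau = 1, radius = 5))
  expect_equal(Rb[1, 2], 1L)
  Rb2 <- recurrence_matrix(emb, rqa_params(m = 2, tau = 1, radius = 4.999))
  expect_equal(Rb2[1, 2], 0L)

  # exhaustive pairwise oracle, both norms, with and without Theiler band
  set.seed(101)
  emb <- matrix(rnorm(200 * 3), 200, 3)
  for (norm in c("euclidean", "maximum")) {
    for (theiler in c(0L, 3L)) {
      p <- rqa_params(m = 3, tau = 1, radius = 0.8, norm = norm,
                      theiler = theiler)
      expect_identical(unclass(recurrence_matrix(emb, p))[1:200, 1:200],
                       oracle_recurrence_matrix(emb, 0.8, norm, theiler))
    }
  }
  expect_error(recurrence_matrix(emb,
                                 local({p <- rqa_params(); p$radius <- -1; p})),
               class = "swayrqa_parameter_error")
})

test_that("recurrence rate is the density of the matrix", {
  all_ones <- matrix(1L, 10, 10)
  expect_equal(recurrence_rate(all_ones), 1)
  expect_equal(recurrence_rate(diag(1L, 10)), 0.1)  # identity line only
  set.seed(5)
  R <- matrix(rbinom(400, 1, 0.3), 20, 20)
  expect_equal(recurrence_rate(R), mean(R))
})

test_that("line histograms count maximal runs, identity line excluded", {
  # all-ones 5x5: upper-triangle diagonals have lengths 4, 3, 2, 1
  all_ones <- matrix(1L, 5, 5)
  h <- line_histograms(all_ones, theiler = 0)
  expect_equal(sort(h$diagonal), c(1, 2, 3, 4))
  expect_equal(h$vertical, rep(5L, 5))

  # identity-only matrix: no off-diagonal structure at all
  h_id <- line_histograms(diag(1L, 10), theiler = 0)
  expect_length(h_id$diagonal, 0L)
  expect_equal(h_id$vertical, rep(1L, 10))

  # random matrices match the run-length oracle
  set.seed(6)
  for (rep in 1:5) {
    R <- matrix(rbinom(900, 1, 0.4), 30, 30)
    R <- R | t(R); diag(R) <- 1L
    R <- matrix(as.integer(R), 30, 30)
    h <- line_histograms(R, theiler = 0)
    expect_equal(sort(h$diagonal), sort(oracle_diag_lengths(R, 0)))
    expect_equal(sort(h$vertical), sort(oracle_vert_lengths(R)))
  }

  # embedded sine: diagonal structure dominated by long lines
  x <- sin(seq(0, 30 * pi, length.out = 600))
  p <- rqa_params(m = 2, tau = 10, radius = 0.1)
  hs <- line_histograms(recurrence_matrix(embed_series(x, 2, 10), p))
  expect_gt(max(hs$diagonal), 50)
})

test_that("scalar measures separate deterministic from shuffled signals", {
  p_rel <- rqa_params(radius = 0.15, radius_mode = "fraction_of_mean_distance")
  x <- sin(seq(0, 40 * pi, length.out = 1000))
  res_sine <- rqa(x, p_rel)
  expect_gte(res_sine$det, 0.95)
  expect_true(res_sine$rr > 1 / res_sine$n_embedded)  # identity line floor

  # white noise, radius tuned so its recurrence rate is ~0.05
  set.seed(31)
  noise <- rnorm(1000)
  p_noise <- rqa_params(radius = 0.6, radius_mode = "fraction_of_mean_distance")
  res_noise <- rqa(noise, p_noise)
  expect_equal(res_noise$rr, 0.05, tolerance = 0.5)
  expect_lt(res_noise$det, res_sine$det)

  # constant series: perfect recurrence
  res_const <- rqa(rep(1, 200), rqa_params(m = 2, tau = 1, radius = 0.5))
  expect_equal(res_const$rr, 1)
  expect_gt(res_const$det, 0.99)  # -> 1 as n grows; finite-size edge lines
  expect_equal(res_const$lam, 1)
})

test_that("entropy is zero when a single line length occurs", {
  # one diagonal line of length 5 and nothing else
  R <- diag(1L, 12)
  for (i in 1:5) { R[i, i + 6] <- 1L; R[i + 6, i] <- 1L }
  res <- rqa_measures(R, rqa_params(m = 1, tau = 1, radius = 1, lmin = 4))
  expect_equal(res$entr, 0)
  expect_equal(res$l_mean, 5)
})

test_that("measures with no line above lmin are missing, not zero", {
  # sparse isolated recurrences: no diagonal or vertical line reaches 4
  R <- diag(1L, 20)
  R[1, 10] <- R[10, 1] <- 1L
  R[3, 15] <- R[15, 3] <- 1L
  res <- rqa_measures(R, rqa_params(m = 1, tau = 1, radius = 1, lmin = 4))
  expect_true(is.na(res$det))
  expect_true(is.na(res$l_mean))
  expect_true(is.na(res$entr))
  expect_true(is.na(res$tt))
})

test_that("recurrence rate is non-decreasing in the radius", {
  set.seed(17)
  x <- cumsum(rnorm(300))
  emb <- embed_series(x, 3, 2)
  radii <- c(0.2, 0.5, 1, 2, 5, 10)
  rr <- vapply(radii, function(r)
    recurrence_rate(recurrence_matrix(emb, rqa_params(m = 3, tau = 2,
                                                      radius = r))),
    numeric(1))
  expect_true(all(diff(rr) >= 0))
})

test_that("fused rqa() agrees with the explicit matrix pipeline", {
  set.seed(23)
  for (rep in 1:4) {
    x <- as.numeric(arima.sim(list(ar = 0.9), 260))
    p <- rqa_params(m = sample(1:4, 1), tau = sample(1:5, 1),
                    radius = runif(1, 0.3, 1.5),
                    norm = sample(c("euclidean", "maximum"), 1),
                    theiler = sample(0:2, 1))
    fast <- rqa(x, p)
    R <- recurrence_matrix(embed_series(x, p$m, p$tau), p)
    slow <- rqa_measures(R, p)
    for (field in c("rr", "det", "lam", "l_mean", "tt", "entr", "trend"))
      expect_equal(fast[[field]], slow[[field]], tolerance = 1e-12,
                   label = sprintf("%s (rep %d)", field, rep))
  }
})

test_that("shuffling a periodic series decreases determinism", {
  x <- sin(seq(0, 40 * pi, length.out = 800))
  emb <- embed_series(x, 8, 15)
  eps <- 0.25 * swayrqa:::.cpp_mean_pairwise_distance(emb, TRUE, 1024L)
  p_abs <- rqa_params(radius = eps)
  det_sine <- rqa(x, p_abs)$det
  worse <- vapply(1:10, function(s) {
    set.seed(s)
    d <- rqa(sample(x), p_abs)$det
    if (is.na(d)) d <- 0  # too few lines: trivially less deterministic
    d < det_sine
  }, logical(1))
  expect_gte(sum(worse), 9L)
})

test_that("rr difference is a checked, antisymmetric contrast", {
  p <- rqa_params(m = 2, tau = 3, radius = 0.5)
  set.seed(41)
  a <- rqa(rnorm(150), p)
  b <- rqa(rnorm(150), p)
  expect_equal(rr_difference(a, a), 0)
  expect_equal(rr_difference(a, b), -rr_difference(b, a))
  p2 <- rqa_params(m = 3, tau = 3, radius = 0.5)
  cc <- rqa(rnorm(150), p2)
  expect_error(rr_difference(a, cc), class = "swayrqa_consistency_error")
})
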