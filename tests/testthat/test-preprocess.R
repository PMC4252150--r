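test_that("zero-phase Butterworth passes DC exactly and kills stopband", {
  n <- 4000
  dc <- make_trace(rep(3.7, n), rep(-1.2, n))
  out <- butterworth_filter(dc, filter_spec(order = 5, cutoff = 10))
  expect_equal(out$ap, dc$ap, tolerance = 1e-8)
  expect_equal(out$ml, dc$ml, tolerance = 1e-8)

  # 100 Hz sine at 1000 Hz, cutoff 10 Hz: analytic two-pass magnitude is
  # (1 + (100/10)^10)^-1 ~ 1e-10; assert well under 1% in the central span
  t <- (0:(n - 1)) / 1000
  sine <- make_trace(sin(2 * pi * 100 * t))
  out <- butterworth_filter(sine, filter_spec(order = 5, cutoff = 10))
  mid <- (n / 4):(3 * n / 4)
  expect_lt(max(abs(out$ap[mid])), 0.01)

  # white noise loses variance under any low-pass
  wn <- random_trace(5000, seed = 11)
  out <- butterworth_filter(wn, filter_spec())
  expect_lt(var(out$ap), var(wn$ap))
  expect_lt(var(out$ml), var(wn$ml))

  expect_error(butterworth_filter(wn, filter_spec(cutoff = 600)),
               class = "swayrqa_parameter_error")
  expect_error(butterworth_filter(make_trace(rnorm(12)), filter_spec()),
               class = "swayrqa_data_error")
})

test_that("filtering is shift-equivariant and introduces no lag", {
  tr <- random_trace(3000, seed = 5)
  spec <- filter_spec()
  base <- butterworth_filter(tr, spec)
  shifted <- butterworth_filter(make_trace(tr$ap + 12.5, tr$ml - 4), spec)
  expect_equal(shifted$ap, base$ap + 12.5, tolerance = 1e-7)
  expect_equal(shifted$ml, base$ml - 4, tolerance = 1e-7)

  # band-limited input: cross-correlation of input and output peaks at lag 0
  t <- (0:2999) / 1000
  x <- sin(2 * pi * 2 * t) + 0.5 * sin(2 * pi * 5 * t + 1)
  out <- butterworth_filter(make_trace(x), spec)
  cc <- ccf(x, out$ap, lag.max = 50, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("boxcar decimation averages non-overlapping windows", {
  tr <- make_trace(c(0, 2, 4, 6), rate = 1000)
  out <- boxcar_downsample(tr, 2)
  expect_equal(out$ap, c(1, 5))
  expect_equal(out$rate, 500)

  # width 1 is the identity
  expect_equal(boxcar_downsample(tr, 1)$ap, tr$ap)

  # 60 s at 1000 Hz, width 10 -> 6000 samples at 100 Hz
  tr60 <- random_trace(60000, seed = 2)
  red <- boxcar_downsample(tr60, 10)
  expect_length(red$ap, 6000L)
  expect_equal(red$rate, 100)
  expect_identical(attr(red, "discarded"), 0L)

  # trailing remainder is discarded and counted, mean of retained span kept
  tr7 <- make_trace(as.numeric(1:7), rate = 7)
  out <- boxcar_downsample(tr7, 3)
  expect_length(out$ap, 2L)
  expect_identical(attr(out, "discarded"), 1L)
  expect_equal(mean(out$ap), mean(tr7$ap[1:6]), tolerance = 1e-9)

  # shift-equivariance
  base <- boxcar_downsample(tr60, 10)
  shifted <- boxcar_downsample(make_trace(tr60$ap + 3, tr60$ml + 3), 10)
  expect_equal(shifted$ap, base$ap + 3, tolerance = 1e-9)

  expect_error(boxcar_downsample(tr, 0), class = "swayrqa_parameter_error")
})

test_that("session segmentation tiles the schedule without gap or overlap", {
  tr <- random_trace(36000, rate = 100, seed = 7)  # 360 s
  m <- session_manifest("S01", "standing_flow_expanding",
                        blocks = standard_flow_blocks(3), rate = 100)
  segs <- segment_session(tr, m)
  expect_equal(nrow(segs), 12L)
  expect_true(all(segs$n == 3000L))
  # index sets partition the covered range exactly
  idx <- unlist(Map(seq, segs$start, segs$end))
  expect_identical(sort(idx), 1:36000)
  expect_identical(anyDuplicated(idx), 0L)

  # single-block schedule covers the whole trace
  tr1 <- random_trace(6000, rate = 100, seed = 8)
  m1 <- session_manifest("S01", "quiet_eyes_open",
                         blocks = data.frame(label = "blank", duration = 60),
                         rate = 100)
  segs1 <- segment_session(tr1, m1)
  expect_equal(segs1$start, 1L)
  expect_equal(segs1$end, 6000L)

  # schedule exceeding the trace is a consistency error
  m_bad <- session_manifest("S01", "standing_flow_expanding",
                            blocks = data.frame(label = rep("flow", 2),
                                                duration = c(200, 200)),
                            rate = 100)
  expect_error(segment_session(tr, m_bad),
               class = "swayrqa_consistency_error")
})
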