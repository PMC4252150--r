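# Build a blocked session whose AP level is piecewise constant: `base`
# during non-flow blocks, `base + offset[k]` during the k-th flow block.
step_session <- function(offsets, base = 0, rate = 10, block_s = 5) {
  blocks <- standard_flow_blocks(repeats = length(offsets), block_s = block_s)
  lv <- numeric(0)
  k <- 0
  for (i in seq_len(nrow(blocks))) {
    add <- if (blocks$label[i] == "flow") { k <- k + 1; offsets[k] } else 0
    lv <- c(lv, rep(base + add, block_s * rate))
  }
  list(trace = make_trace(lv, rate = rate),
       manifest = session_manifest("S01", "standing_flow_contracting",
                                   blocks = blocks, rate = rate))
}

test_that("VEPR is the flow-minus-preceding-baseline AP mean", {
  # flow level equals baseline -> zero response
  s0 <- step_session(c(0, 0, 0))
  expect_equal(compute_vepr(s0$trace, s0$manifest)$mean_vepr, 0)

  # constant +9 mm step during flow
  s9 <- step_session(c(9, 9, 9), base = 2)
  v <- compute_vepr(s9$trace, s9$manifest)
  expect_equal(v$per_repeat, rep(9, 3))
  expect_equal(v$mean_vepr, 9)

  # three repeats with different offsets average arithmetically
  s <- step_session(c(6, 9, 12))
  v <- compute_vepr(s$trace, s$manifest)
  expect_equal(v$per_repeat, c(6, 9, 12))
  expect_equal(v$mean_vepr, 9)

  # invariant to adding a constant to the whole trace
  tr_shift <- make_trace(s$trace$ap + 55, s$trace$ml, rate = s$trace$rate)
  expect_equal(compute_vepr(tr_shift, s$manifest)$mean_vepr, 9,
               tolerance = 1e-9)

  # a flow block with nothing before it is a schedule error
  m_bad <- session_manifest("S01", "standing_flow_expanding",
                            blocks = data.frame(label = c("flow", "blank"),
                                                duration = c(5, 5)),
                            rate = 10)
  tr_bad <- make_trace(rep(0, 100), rate = 10)
  expect_error(compute_vepr(tr_bad, m_bad),
               class = "swayrqa_consistency_error")
})

test_that("expanding flow drives backward and contracting forward sway", {
  spec <- cohort_spec(n_subjects = 2, rate = 250, duration = 12,
                      flow_repeats = 1, block_s = 4, master_seed = 1)
  p <- subject_params("S01", v = 0.8, sigma = 0.3, vepr_gain = 3, seed = 9)
  fe <- gen_flow_session(p, "expanding", spec)
  fc <- gen_flow_session(p, "contracting", spec)
  ve <- compute_vepr(fe$trace, fe$manifest)$mean_vepr
  vc <- compute_vepr(fc$trace, fc$manifest)$mean_vepr
  expect_lt(ve, 0)
  expect_gt(vc, 0)
  expect_gt(abs(vc), abs(ve))
})

test_that("throttle maximum and latency read off the rating trace", {
  ramp <- vection_record("S01", "expanding", 1,
                         data.frame(time_s = (0:1000) / 100,
                                    level_pct = seq(0, 100, length.out = 1001)),
                         verbal = 80)
  expect_equal(throttle_max(ramp), 100)
  expect_equal(throttle_latency(ramp, 5), 0.5, tolerance = 0.02)

  flat <- vection_record("S01", "expanding", 2,
                         data.frame(time_s = (0:99) / 100,
                                    level_pct = rep(0, 100)))
  expect_equal(throttle_max(flat), 0)
  expect_true(is.na(throttle_latency(flat)))

  low <- vection_record("S01", "expanding", 3,
                        data.frame(time_s = (0:99) / 100,
                                   level_pct = rep(4, 100)))
  expect_true(is.na(throttle_latency(low, 5)))

  # noisy trace: equals the exhaustive linear scan
  set.seed(77)
  lv <- pmin(100, pmax(0, cumsum(rnorm(500, 0.2, 1))))
  noisy <- vection_record("S01", "contracting", 1,
                          data.frame(time_s = (0:499) / 100, level_pct = lv))
  expect_equal(throttle_max(noisy), max(lv))
  scan_hit <- NA_real_
  for (i in seq_along(lv)) if (lv[i] >= 5) { scan_hit <- (i - 1) / 100; break }
  expect_equal(throttle_latency(noisy, 5), scan_hit)

  # latency never increases as the cutoff is lowered
  lats <- vapply(c(40, 20, 10, 5, 1), function(cc)
    throttle_latency(noisy, cc), numeric(1))
  expect_true(all(diff(lats) <= 0))
})

test_that("vection aggregation averages trials and counts missing onsets", {
  mk <- function(i, verbal, peak, rise = TRUE) {
    lv <- if (rise) seq(0, peak, length.out = 101) else rep(peak, 101)
    vection_record("S01", "expanding", i,
                   data.frame(time_s = (0:100) / 10, level_pct = lv),
                   verbal = verbal)
  }
  # identical trials aggregate to any single trial
  same <- lapply(1:8, mk, verbal = 40, peak = 30)
  agg <- aggregate_vection(same)
  expect_equal(agg$verbal_mean, 40)
  expect_equal(agg$throttle_max_mean, 30)
  expect_equal(agg$latency_mean, throttle_latency(same[[1]]))
  expect_equal(agg$latency_missing, 0L)

  expect_equal(aggregate_vection(list(mk(1, 40, 10),
                                      mk(2, 60, 10)))$verbal_mean, 50)

  # 8 trials, 3 below the cutoff: latency mean over the 5 defined ones
  mixed <- c(lapply(1:5, mk, verbal = 50, peak = 30),
             lapply(6:8, mk, verbal = 50, peak = 3))
  agg <- aggregate_vection(mixed)
  expect_equal(agg$latency_missing, 3L)
  expect_equal(agg$latency_mean,
               mean(vapply(mixed[1:5], throttle_latency, numeric(1))))

  expect_error(aggregate_vection(list()), class = "swayrqa_data_error")
})
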