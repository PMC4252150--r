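# Small, fast study conditions for generator property tests; the full-scale
# design (60 s at 1000 Hz) is exercised in the acceptance suite.
small_spec <- function(master_seed = 1, ...) {
  cohort_spec(n_subjects = 4, rate = 500, duration = 12, flow_repeats = 1,
              block_s = 5, master_seed = master_seed, ...)
}

test_that("every generator output is a pure function of params and seed", {
  spec <- small_spec()
  p <- subject_params("S01", v = 0.4, seed = 321)
  expect_identical(gen_quiet_stance(p, "open", spec)$ap,
                   gen_quiet_stance(p, "open", spec)$ap)
  expect_identical(gen_flow_session(p, "contracting", spec)$trace$ap,
                   gen_flow_session(p, "contracting", spec)$trace$ap)
  r1 <- gen_vection(p, "expanding", spec)
  r2 <- gen_vection(p, "expanding", spec)
  expect_identical(vapply(r1, `[[`, numeric(1), "verbal"),
                   vapply(r2, `[[`, numeric(1), "verbal"))
  # open and closed streams differ (different sub-seeds)
  expect_false(identical(gen_quiet_stance(p, "open", spec)$ml,
                         gen_quiet_stance(p, "closed", spec)$ml))
  # generators do not disturb the caller's RNG state
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(gen_quiet_stance(p, "open", spec)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("visual dependence orders eyes-open recurrence as constructed", {
  spec <- small_spec()
  pars <- rqa_params(radius = 0.15, radius_mode = "fraction_of_mean_distance")
  rr_of <- function(v, seed) {
    p <- subject_params("X", v = v, seed = seed)
    tr <- butterworth_filter(gen_quiet_stance(p, "open", spec))
    rqa(boxcar_downsample(tr, 10)$ap, pars)$rr
  }
  wins <- vapply(1:10, function(s) rr_of(0, 1000 + s) > rr_of(1, 1000 + s),
                 logical(1))
  expect_gte(sum(wins), 9L)
})

test_that("eyes-closed sway exceeds eyes-open sway on cohort averages", {
  spec <- cohort_spec(n_subjects = 20, rate = 500, duration = 12,
                      master_seed = 7)
  coh <- simulate_cohort(spec, include = "quiet")
  paths <- vapply(coh$quiet, function(q) {
    c(open = path_length(butterworth_filter(q$open)),
      closed = path_length(butterworth_filter(q$closed)))
  }, numeric(2))
  expect_gt(mean(paths["closed", ]), mean(paths["open", ]))
})

test_that("flow sessions inject recoverable postural shifts", {
  spec <- small_spec()
  # no gain, no response (within noise)
  p0 <- subject_params("X", v = 0.9, sigma = 0.3, vepr_gain = 0, seed = 4)
  s0 <- gen_flow_session(p0, "contracting", spec)
  expect_lt(abs(compute_vepr(s0$trace, s0$manifest)$mean_vepr), 0.5)

  # injected contracting shift of +9 mm recovered within +/- 1 mm
  p9 <- subject_params("X", v = 1, sigma = 0.3, vepr_gain = 9 / 7.7, seed = 5)
  s9 <- gen_flow_session(p9, "contracting", spec)
  expect_equal(compute_vepr(s9$trace, s9$manifest)$mean_vepr, 9,
               tolerance = 1 / 9)

  # contracting response exceeds expanding at equal v, across seeds
  bigger <- vapply(1:6, function(s) {
    p <- subject_params("X", v = 0.7, sigma = 0.5, seed = 100 + s)
    fe <- gen_flow_session(p, "expanding", spec)
    fc <- gen_flow_session(p, "contracting", spec)
    abs(compute_vepr(fc$trace, fc$manifest)$mean_vepr) >
      abs(compute_vepr(fe$trace, fe$manifest)$mean_vepr)
  }, logical(1))
  expect_gte(sum(bigger), 5L)

  # the manifest matches the generated schedule exactly
  segs <- segment_session(s9$trace, s9$manifest)
  expect_equal(sum(segs$n), length(s9$trace$time))
})

test_that("verbal ratings follow the coupling construction", {
  # zero rating noise: all trials collapse to the deterministic mean
  spec0 <- small_spec(noise_sd = 0)
  p <- subject_params("X", v = 0, seed = 8)
  verb <- vapply(gen_vection(p, "expanding", spec0), `[[`, numeric(1),
                 "verbal")
  expect_equal(sd(verb), 0)
  expect_equal(verb[1], 100 * (0.376 + 0.7 * 0.75 * (0 - 0.5)),
               tolerance = 1e-9)

  # monotone in v at fixed seed (negative coupling => increasing)
  grid_means <- vapply(c(0.1, 0.4, 0.7, 0.9), function(v) {
    p <- subject_params("X", v = v, seed = 8)
    mean(vapply(gen_vection(p, "expanding", spec0), `[[`, numeric(1),
                "verbal"))
  }, numeric(1))
  expect_true(all(diff(grid_means) > 0))

  # contracting above expanding; throttle max bounded by its verbal rating
  spec <- small_spec()
  p <- subject_params("X", v = 0.5, seed = 12)
  exp_recs <- gen_vection(p, "expanding", spec)
  con_recs <- gen_vection(p, "contracting", spec)
  expect_gt(aggregate_vection(con_recs)$verbal_mean,
            aggregate_vection(exp_recs)$verbal_mean)
  for (r in c(exp_recs, con_recs))
    expect_lte(throttle_max(r), r$verbal + 1e-9)
})

test_that("cohorts rebuild bit-identically from the master seed", {
  spec <- small_spec(master_seed = 99)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  gen_cohort(spec, d1)
  gen_cohort(spec, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 0)
  expect_identical(files, list.files(d2, recursive = TRUE))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = f)
  # 4 subjects x (2 quiet + 2 flow traces + manifests, 2x2 vection files)
  expect_length(list.files(file.path(d1, "S01")), 12L)

  # loading reproduces the in-memory cohort
  coh <- simulate_cohort(spec)
  loaded <- load_cohort(d1)
  expect_equal(loaded$subjects$v, coh$subjects$v, tolerance = 1e-9)
  expect_equal(loaded$quiet$S02$open$ap, coh$quiet$S02$open$ap,
               tolerance = 1e-9)
  expect_equal(vapply(loaded$vection$S03$contracting, `[[`, numeric(1),
                      "verbal"),
               vapply(coh$vection$S03$contracting, `[[`, numeric(1),
                      "verbal"),
               tolerance = 1e-9)
})
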