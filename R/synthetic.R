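# Synthetic cohort generator.
#
# One latent scalar per subject — visual dependence v in [0, 1] — drives
# every condition contrast the analysis consumes:
#   * quiet stance, eyes open: mean-reverting (OU / AR(1)) sway plus a slow
#     sinusoidal component of amplitude a * (1 - v), so LOW visual
#     dependence yields MORE recurrent eyes-open structure;
#   * quiet stance, eyes closed: the same mean-reverting process with noise
#     scaled by (1 + v) — eyes-closed sway grows with visual dependence;
#   * standing flow: the AP mean shifts backward by vepr_gain * v under
#     expanding flow and forward by k * vepr_gain * v (k > 1) under
#     contracting flow;
#   * seated vection: verbal ratings increase with v (slope set by the
#     cohort coupling target), contracting above expanding; throttle traces
#     rise sigmoidally to a verbal-linked maximum with onset latency
#     decreasing in v.
# Everything is a pure function of (params, seed).

#' Per-subject generator parameters
#'
#' @param subject_id Identifier string.
#' @param v Visual dependence in `[0, 1]`: the latent construct coupling
#'   sway structure to vection strength.
#' @param sigma Baseline sway noise (stationary SD of the mean-reverting
#'   process), mm; must be > 0.
#' @param periodic_amp Amplitude `a` of the eyes-open sinusoidal sway
#'   component at `v = 0`, mm (>= 0). The realised amplitude is
#'   `a * (1 - v)`.
#' @param periodic_freq Frequency of that component, Hz (below the Nyquist
#'   frequency of the generated rate).
#' @param vepr_gain Postural gain to optic flow, mm: expanding flow shifts
#'   the AP mean by `-vepr_gain * v`, contracting by
#'   `+contract_gain_ratio * vepr_gain * v`.
#' @param seed Integer seed for this subject's random streams.
#' @return An object of class `subject_params`.
#' @export
subject_params <- function(subject_id, v = 0.5, sigma = 2, periodic_amp = 5,
                           periodic_freq = 0.15, vepr_gain = 2.3,
                           seed = 1L) {
  if (!is_scalar_string(subject_id)) parameter_error("subject_id must be a string")
  if (!is_scalar_number(v) || v < 0 || v > 1)
    parameter_error("v must lie in [0, 1]")
  if (!is_scalar_number(sigma) || sigma <= 0) parameter_error("sigma must be > 0")
  if (!is_scalar_number(periodic_amp) || periodic_amp < 0)
    parameter_error("periodic_amp must be >= 0")
  if (!is_scalar_number(periodic_freq) || periodic_freq <= 0)
    parameter_error("periodic_freq must be > 0")
  if (!is_scalar_number(vepr_gain) || vepr_gain < 0)
    parameter_error("vepr_gain must be >= 0")
  structure(list(subject_id = subject_id, v = v, sigma = sigma,
                 periodic_amp = periodic_amp, periodic_freq = periodic_freq,
                 vepr_gain = vepr_gain, seed = as.integer(seed)),
            class = "subject_params")
}

#' Cohort-level generator specification
#'
#' Defaults reproduce the emulated study design: 60 s quiet-stance traces
#' at 1000 Hz, 30 s blocks repeated three times for standing flow, 8 seated
#' trials per flow direction, and a coupling of -0.7 between the
#' eyes-open-minus-eyes-closed recurrence signature and mean vection (the
#' headline association the analysis is built to detect; internally the
#' verbal-rating slope on `v` is `-coupling`, so a negative coupling makes
#' vection increase with visual dependence).
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param rate Force-plate sampling rate, Hz.
#' @param duration Quiet-stance trace duration, seconds. Must leave room
#'   for the default time-delay embedding after boxcar reduction.
#' @param coupling Target correlation between the recurrence difference
#'   (eyes open minus closed) and mean vection, in `[-1, 1]`.
#' @param noise_sd Between-subject rating noise, percent.
#' @param n_trials Seated vection trials per direction.
#' @param flow_repeats Repetitions of the blank/flow/blank/fixation block
#'   sequence in standing-flow sessions.
#' @param block_s Block duration, seconds.
#' @param master_seed Master seed; every per-subject seed derives from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 13, rate = 1000, duration = 60,
                        coupling = -0.7, noise_sd = 8, n_trials = 8,
                        flow_repeats = 3, block_s = 30, master_seed = 1L) {
  if (!is_scalar_number(n_subjects) || n_subjects < 2)
    parameter_error("n_subjects must be >= 2")
  if (!is_scalar_number(rate) || rate <= 0) parameter_error("rate must be > 0")
  if (!is_scalar_number(coupling) || coupling < -1 || coupling > 1)
    parameter_error("coupling must lie in [-1, 1]")
  if (!is_scalar_number(noise_sd) || noise_sd < 0)
    parameter_error("noise_sd must be >= 0")
  # default RQA embedding spans (m-1)*tau samples at the boxcar-reduced rate
  if (!is_scalar_number(duration) || duration * rate / 10 < 7 * 15 + 2)
    parameter_error("duration too short for the default embedding after 10x reduction")
  structure(list(n_subjects = as.integer(n_subjects), rate = rate,
                 duration = duration, coupling = coupling,
                 noise_sd = noise_sd, n_trials = as.integer(n_trials),
                 flow_repeats = as.integer(flow_repeats), block_s = block_s,
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

# Stationary mean-reverting (Ornstein-Uhlenbeck / AR(1)) series: reversion
# rate `revert` per second, stationary SD `sd`. Initialised from the
# stationary distribution.
ou_series <- function(n, rate, sd, revert = 0.8) {
  phi <- exp(-revert / rate)
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive",
                           init = stats::rnorm(1, 0, sd)))
}

#' Generate a quiet-stance CoP trace
#'
#' See the construction notes at the top of the generator: eyes-open AP
#' sway carries a sinusoidal component of amplitude
#' `periodic_amp * (1 - v)`; eyes-closed sway has its noise SD scaled by
#' `(1 + v)`. ML is an independent mean-reverting process at 60% of the AP
#' noise SD.
#'
#' @param p A [subject_params].
#' @param eyes `"open"` or `"closed"`.
#' @param spec A [cohort_spec] (rate and duration are taken from it).
#' @return A [cop_trace].
#' @export
gen_quiet_stance <- function(p, eyes = c("open", "closed"),
                             spec = cohort_spec()) {
  stopifnot(inherits(p, "subject_params"), inherits(spec, "cohort_spec"))
  eyes <- match.arg(eyes)
  if (p$periodic_freq >= spec$rate / 2)
    parameter_error("periodic_freq must be below the Nyquist frequency")
  n <- round(spec$duration * spec$rate)
  time <- (seq_len(n) - 1) / spec$rate
  with_seed(p$seed + if (eyes == "open") 11L else 12L, {
    if (eyes == "open") {
      phase <- stats::runif(1, 0, 2 * pi)
      ap <- ou_series(n, spec$rate, p$sigma) +
        p$periodic_amp * (1 - p$v) * sin(2 * pi * p$periodic_freq * time + phase)
      ml <- ou_series(n, spec$rate, 0.6 * p$sigma)
    } else {
      scl <- 1 + p$v
      ap <- ou_series(n, spec$rate, p$sigma * scl)
      ml <- ou_series(n, spec$rate, 0.6 * p$sigma * scl)
    }
    cop_trace(time = time, ap = ap, ml = ml, rate = spec$rate)
  })
}

# Ratio of the contracting to the expanding postural gain; forward sway to
# contracting flow is several-fold larger than backward sway to expanding
# flow (foot physiology: one can lean much further forward than backward).
contract_gain_ratio <- function() 7.7

#' Generate a blocked standing-flow session
#'
#' Baseline mean-reverting sway with the AP mean shifted during each flow
#' block: backward (`-vepr_gain * v`) for expanding flow, forward and
#' larger (`+7.7 * vepr_gain * v`) for contracting flow. The returned
#' manifest matches the generated schedule exactly.
#'
#' @inheritParams gen_quiet_stance
#' @param direction `"expanding"` or `"contracting"`.
#' @return List with elements `trace` ([cop_trace]) and `manifest`
#'   ([session_manifest]).
#' @export
gen_flow_session <- function(p, direction = c("expanding", "contracting"),
                             spec = cohort_spec()) {
  stopifnot(inherits(p, "subject_params"), inherits(spec, "cohort_spec"))
  direction <- match.arg(direction)
  blocks <- standard_flow_blocks(spec$flow_repeats, spec$block_s)
  n_blk <- round(blocks$duration * spec$rate)
  n <- sum(n_blk)
  shift <- if (direction == "expanding") -p$vepr_gain * p$v
           else contract_gain_ratio() * p$vepr_gain * p$v
  offset <- rep(ifelse(blocks$label == "flow", shift, 0), n_blk)
  with_seed(p$seed + if (direction == "expanding") 21L else 22L, {
    ap <- ou_series(n, spec$rate, p$sigma) + offset
    ml <- ou_series(n, spec$rate, 0.6 * p$sigma)
    trace <- cop_trace(time = (seq_len(n) - 1) / spec$rate, ap = ap,
                       ml = ml, rate = spec$rate)
    manifest <- session_manifest(
      subject_id = p$subject_id,
      condition = paste0("standing_flow_", direction),
      blocks = blocks, rate = spec$rate)
    list(trace = trace, manifest = manifest)
  })
}

# Verbal-rating construction shared by gen_vection: fraction-scale mean for
# a subject and direction before trial noise and clipping.
verbal_mean_frac <- function(v, direction, coupling) {
  b0 <- 0.376                      # expanding cohort-mean target at v = 0.5
  b1 <- -coupling * 0.75           # slope on v; coupling < 0 => increasing
  contr <- if (direction == "contracting") 0.23 else 0
  b0 + b1 * (v - 0.5) + contr
}

#' Generate seated vection trials
#'
#' Per trial, the verbal rating is
#' `clip(100 * (b0 + b1 (v - 1/2) + contracting offset) + noise, 0, 100)`
#' with the slope `b1 = -coupling * 0.75`; the throttle trace rises
#' sigmoidally from exactly zero at stimulus onset to a maximum drawn as a
#' fraction (0.65--0.95) of the trial's verbal rating, with onset time
#' decreasing in `v`. Trials whose throttle never reaches the 5% cutoff
#' yield missing latencies downstream, as in real rating data.
#'
#' @inheritParams gen_flow_session
#' @param n_trials Number of trials (defaults to the cohort spec's).
#' @param trial_s Trial duration, seconds.
#' @param throttle_rate Throttle sampling rate, Hz.
#' @return List of [vection_record]s.
#' @export
gen_vection <- function(p, direction = c("expanding", "contracting"),
                        spec = cohort_spec(), n_trials = spec$n_trials,
                        trial_s = 30, throttle_rate = 100) {
  stopifnot(inherits(p, "subject_params"), inherits(spec, "cohort_spec"))
  direction <- match.arg(direction)
  base <- 100 * verbal_mean_frac(p$v, direction, spec$coupling)
  tt <- seq(0, trial_s, by = 1 / throttle_rate)
  with_seed(p$seed + if (direction == "expanding") 31L else 32L, {
    subj_noise <- stats::rnorm(1, 0, spec$noise_sd)
    lapply(seq_len(n_trials), function(i) {
      verbal <- min(100, max(0, base + subj_noise +
                                  stats::rnorm(1, 0, 0.6 * spec$noise_sd)))
      tmax <- verbal * stats::runif(1, 0.65, 0.95)
      t0 <- max(1, 1 + 5 * (1 - p$v) + stats::rnorm(1, 0, 0.4))
      s <- 0.6
      base_lv <- stats::plogis(-t0 / s)
      level <- tmax * pmax(0, stats::plogis((tt - t0) / s) - base_lv) /
        (1 - base_lv)
      vection_record(p$subject_id, direction, i,
                     throttle = data.frame(time_s = tt,
                                           level_pct = pmin(100, level)),
                     verbal = verbal)
    })
  })
}

# Draw per-subject parameters for a cohort; reproducible from master_seed.
draw_subject_params <- function(spec) {
  with_seed(spec$master_seed, {
    n <- spec$n_subjects
    ids <- sprintf("S%02d", seq_len(n))
    v <- stats::runif(n, 0.05, 0.95)
    sigma <- stats::rlnorm(n, log(2), 0.2)
    amp <- stats::runif(n, 4.5, 5.5)
    freq <- stats::runif(n, 0.12, 0.18)
    gain <- pmax(0.5, stats::rnorm(n, 2.3, 0.4))
    seeds <- sample.int(2^30, n)
    data.frame(subject_id = ids, v = v, sigma = sigma, periodic_amp = amp,
               periodic_freq = freq, vepr_gain = gain, seed = seeds,
               stringsAsFactors = FALSE)
  })
}

params_row <- function(df, i) {
  subject_params(df$subject_id[i], v = df$v[i], sigma = df$sigma[i],
                 periodic_amp = df$periodic_amp[i],
                 periodic_freq = df$periodic_freq[i],
                 vepr_gain = df$vepr_gain[i], seed = df$seed[i])
}

#' Simulate a complete cohort in memory
#'
#' Generates, for every subject, the requested condition families: quiet
#' stance (eyes open/closed), blocked standing-flow sessions (both
#' directions), and seated vection trials (both directions).
#'
#' @param spec A [cohort_spec].
#' @param include Character subset of `c("quiet", "flow", "vection")`.
#' @return A list of class `sway_cohort` with elements `spec`, `subjects`
#'   (the drawn per-subject parameters) and, per included family, named
#'   per-subject lists: `quiet` (`$open`, `$closed` traces), `flow`
#'   (`$expanding`, `$contracting`, each `list(trace, manifest)`), and
#'   `vection` (`$expanding`, `$contracting` lists of [vection_record]s).
#' @export
simulate_cohort <- function(spec = cohort_spec(),
                            include = c("quiet", "flow", "vection")) {
  stopifnot(inherits(spec, "cohort_spec"))
  include <- match.arg(include, several.ok = TRUE)
  subjects <- draw_subject_params(spec)
  out <- list(spec = spec, subjects = subjects)
  per_subject <- function(f) {
    res <- lapply(seq_len(nrow(subjects)), function(i) f(params_row(subjects, i)))
    names(res) <- subjects$subject_id
    res
  }
  if ("quiet" %in% include)
    out$quiet <- per_subject(function(p)
      list(open = gen_quiet_stance(p, "open", spec),
           closed = gen_quiet_stance(p, "closed", spec)))
  if ("flow" %in% include)
    out$flow <- per_subject(function(p)
      list(expanding = gen_flow_session(p, "expanding", spec),
           contracting = gen_flow_session(p, "contracting", spec)))
  if ("vection" %in% include)
    out$vection <- per_subject(function(p)
      list(expanding = gen_vection(p, "expanding", spec),
           contracting = gen_vection(p, "contracting", spec)))
  class(out) <- "sway_cohort"
  out
}

#' Write a synthetic cohort to disk
#'
#' Generates (or takes) a cohort and writes every trace, manifest, throttle
#' trial and verbal rating as plain CSV/YAML under `dir`, one subdirectory
#' per subject, plus a `cohort.yaml` recording the spec and every
#' per-subject parameter and seed. Re-running with the same spec
#' reproduces the files bit-exactly.
#'
#' @param spec A [cohort_spec].
#' @param dir Output directory (created if needed).
#' @param cohort Optionally a pre-generated [simulate_cohort()] result.
#' @param include Condition families to generate when `cohort` is `NULL`.
#' @return `dir`, invisibly.
#' @export
gen_cohort <- function(spec = cohort_spec(), dir,
                       cohort = NULL,
                       include = c("quiet", "flow", "vection")) {
  if (is.null(cohort)) cohort <- simulate_cohort(spec, include)
  spec <- cohort$spec
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    io_error(sprintf("cannot create output directory %s", dir))
  yaml::write_yaml(list(spec = unclass(spec),
                        subjects = lapply(seq_len(nrow(cohort$subjects)),
                                          function(i) as.list(cohort$subjects[i, ]))),
                   file.path(dir, "cohort.yaml"),
                   precision = 15L)
  for (sid in cohort$subjects$subject_id) {
    sdir <- file.path(dir, sid)
    dir.create(sdir, showWarnings = FALSE)
    if (!is.null(cohort$quiet)) {
      for (eyes in c("open", "closed")) {
        base <- paste0("quiet_eyes_", eyes)
        write_cop_trace(cohort$quiet[[sid]][[eyes]],
                        file.path(sdir, paste0(base, ".csv")))
        write_manifest(session_manifest(sid, paste0("quiet_eyes_", eyes),
                                        rate = spec$rate,
                                        trace_file = paste0(base, ".csv")),
                       file.path(sdir, paste0(base, ".yaml")))
      }
    }
    if (!is.null(cohort$flow)) {
      for (dirn in c("expanding", "contracting")) {
        base <- paste0("flow_", dirn)
        sess <- cohort$flow[[sid]][[dirn]]
        write_cop_trace(sess$trace, file.path(sdir, paste0(base, ".csv")))
        m <- sess$manifest
        m$trace_file <- paste0(base, ".csv")
        write_manifest(m, file.path(sdir, paste0(base, ".yaml")))
      }
    }
    if (!is.null(cohort$vection)) {
      for (dirn in c("expanding", "contracting")) {
        recs <- cohort$vection[[sid]][[dirn]]
        thr <- do.call(rbind, lapply(recs, function(r)
          cbind(trial = r$trial_index, r$throttle)))
        utils::write.csv(thr, file.path(sdir, paste0("throttle_", dirn, ".csv")),
                         row.names = FALSE, quote = FALSE)
        vb <- data.frame(trial = vapply(recs, `[[`, integer(1), "trial_index"),
                         verbal_pct = vapply(recs, `[[`, numeric(1), "verbal"))
        utils::write.csv(vb, file.path(sdir, paste0("verbal_", dirn, ".csv")),
                         row.names = FALSE, quote = FALSE)
      }
    }
  }
  invisible(dir)
}

#' Load a cohort written by [gen_cohort()]
#'
#' @param dir Cohort directory containing `cohort.yaml`.
#' @return A `sway_cohort` list mirroring [simulate_cohort()] output.
#'   Missing per-subject files are tolerated (their slots are `NULL`) with
#'   a warning, so partially recorded cohorts still load.
#' @export
load_cohort <- function(dir) {
  meta_path <- file.path(dir, "cohort.yaml")
  if (!file.exists(meta_path)) io_error(sprintf("no cohort.yaml in %s", dir))
  meta <- yaml::read_yaml(meta_path)
  spec <- do.call(cohort_spec, meta$spec)
  subjects <- do.call(rbind, lapply(meta$subjects, as.data.frame))
  out <- list(spec = spec, subjects = subjects)
  read_if <- function(path, reader, ...) {
    if (file.exists(path)) reader(path, ...) else {
      warning(sprintf("missing file: %s", path), call. = FALSE)
      NULL
    }
  }
  quiet <- list(); flow <- list(); vection <- list()
  for (sid in subjects$subject_id) {
    sdir <- file.path(dir, sid)
    q <- list(
      open = read_if(file.path(sdir, "quiet_eyes_open.csv"), read_cop_trace,
                     rate = spec$rate),
      closed = read_if(file.path(sdir, "quiet_eyes_closed.csv"),
                       read_cop_trace, rate = spec$rate))
    if (!is.null(q$open) || !is.null(q$closed)) quiet[[sid]] <- q
    f <- lapply(c(expanding = "expanding", contracting = "contracting"),
                function(dirn) {
      mp <- file.path(sdir, paste0("flow_", dirn, ".yaml"))
      if (!file.exists(mp)) return(NULL)
      m <- read_manifest(mp, check_trace = FALSE)
      tr <- read_if(m$trace_file, read_cop_trace, rate = m$rate,
                    ap_forward_sign = m$ap_forward_sign)
      if (is.null(tr)) NULL else list(trace = tr, manifest = m)
    })
    if (any(!vapply(f, is.null, logical(1)))) flow[[sid]] <- f
    vn <- lapply(c(expanding = "expanding", contracting = "contracting"),
                 function(dirn) {
      tp <- file.path(sdir, paste0("throttle_", dirn, ".csv"))
      vp <- file.path(sdir, paste0("verbal_", dirn, ".csv"))
      if (!file.exists(tp) || !file.exists(vp)) return(NULL)
      thr <- utils::read.csv(tp)
      vb <- utils::read.csv(vp)
      lapply(sort(unique(thr$trial)), function(k)
        vection_record(sid, dirn, k,
                       throttle = thr[thr$trial == k, c("time_s", "level_pct")],
                       verbal = vb$verbal_pct[match(k, vb$trial)]))
    })
    if (any(!vapply(vn, is.null, logical(1)))) vection[[sid]] <- vn
  }
  if (length(quiet)) out$quiet <- quiet
  if (length(flow)) out$flow <- flow
  if (length(vection)) out$vection <- vection
  class(out) <- "sway_cohort"
  out
}
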