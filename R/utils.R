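# Internal helpers shared across modules.

# Classed conditions so callers can distinguish format, data, parameter,
# consistency and degenerate-geometry failures programmatically.
stop_swayrqa <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "swayrqa_error", "error")))
}

format_error      <- function(msg) stop_swayrqa(msg, "swayrqa_format_error")
data_error        <- function(msg) stop_swayrqa(msg, "swayrqa_data_error")
parameter_error   <- function(msg) stop_swayrqa(msg, "swayrqa_parameter_error")
consistency_error <- function(msg) stop_swayrqa(msg, "swayrqa_consistency_error")
degenerate_error  <- function(msg) stop_swayrqa(msg, "swayrqa_degenerate_error")
spec_error        <- function(msg) stop_swayrqa(msg, "swayrqa_spec_error")
io_error          <- function(msg) stop_swayrqa(msg, "swayrqa_io_error")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards. All generator randomness goes through this, so every synthetic
# object is a pure function of (params, seed).
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

is_scalar_string <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)
}
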