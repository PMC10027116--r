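# Internal helpers shared across modules.

# Infer a sampling rate (Hz) from a strictly increasing time column.
infer_fs <- function(time) {
  dt <- diff(time)
  if (length(dt) < 1L || any(dt <= 0)) {
    abort("`time` must be strictly increasing with at least two samples.")
  }
  fs <- 1 / stats::median(dt)
  # snap to an integer rate when the deviation is pure float noise
  if (abs(fs - round(fs)) < 1e-6 * fs) fs <- round(fs)
  fs
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards (so seeded internals never perturb user code).
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Wrap degrees into [0, 360).
wrap_deg <- function(x) {
  out <- x %% 360
  out[out == 360] <- 0
  out
}

# Circular-safe interpolation of an angle series (degrees) at query times:
# interpolate the unit phasor, then take the argument.
interp_angle <- function(t, angle_deg, t_out) {
  rad <- angle_deg * pi / 180
  re <- stats::approx(t, cos(rad), xout = t_out, rule = 2)$y
  im <- stats::approx(t, sin(rad), xout = t_out, rule = 2)$y
  wrap_deg(atan2(im, re) * 180 / pi)
}

# Effective number of independent segments for Welch-style averaging of
# `k` segments at the given overlap fraction (rectangular window: adjacent
# half-overlapping periodograms correlate ~ overlap^2).
effective_segments <- function(k, overlap = 0) {
  if (overlap <= 0) return(as.numeric(k))
  k / (1 + 2 * overlap^2)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}
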