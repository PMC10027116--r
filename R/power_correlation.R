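#' Frequency-pair power correlogram
#'
#' Correlation coefficients between the windowed spectral power at every
#' frequency pair, across windows, within one region (`segset_b` omitted;
#' symmetric with unit diagonal) or across two regions (generally
#' asymmetric, and entries may take any value in `[-1, 1]`). All windows
#' are pooled regardless of running speed, so speed-driven co-variation of
#' theta, harmonic and gamma power appears as positive off-diagonal
#' structure, and an oscillation whose amplitude is modulated at theta
#' frequency shows up as an off-axis diagonal between carrier side-bins one
#' theta step apart.
#'
#' @param segset_a A `segment_set` of windows from the first region.
#' @param segset_b Optional `segment_set` from a second region, aligned with
#'   `segset_a`; defaults to `segset_a` (within-region).
#' @param log_power Correlate log-power (default `TRUE`, variance
#'   stabilizing) or raw power.
#' @param method Correlation coefficient: `"pearson"` (default) or
#'   `"spearman"`.
#' @param max_freq Restrict the grid to frequencies at or below this (Hz).
#' @return A `power_correlogram` object: fields `f_a`, `f_b`, `r` (matrix,
#'   rows = frequencies of `a`), `n_windows`, `regions`, `method`. Use
#'   [tidy()] for a long tibble.
#' @export
power_correlogram <- function(segset_a, segset_b = segset_a,
                              log_power = TRUE,
                              method = c("pearson", "spearman"),
                              max_freq = NULL) {
  method <- match.arg(method)
  check_aligned(segset_a, segset_b)
  K <- segset_a$n_segments
  if (K < 3) abort("need at least 3 windows to correlate power.")
  n <- segset_a$window_samples
  grid <- frequency_grid(n, segset_a$fs)
  half <- 2:(n %/% 2 + 1L)  # skip DC: de-meaned windows carry no 0-Hz power
  f <- grid$f[half]
  if (!is.null(max_freq)) {
    keep <- f <= max_freq
    half <- half[keep]; f <- f[keep]
  }
  pw <- function(ss) {
    p <- Mod(segment_dft(ss$segments)[, half, drop = FALSE])^2
    if (log_power) log(p + .Machine$double.xmin) else p
  }
  pa <- pw(segset_a)
  same <- identical(segset_a, segset_b)
  pb <- if (same) pa else pw(segset_b)
  r <- stats::cor(pa, pb, method = method)
  structure(
    list(f_a = f, f_b = f, r = r, n_windows = K,
         regions = c(segset_a$region %||% "a", segset_b$region %||% "b"),
         within = same, method = method, log_power = log_power),
    class = "power_correlogram"
  )
}

#' @export
print.power_correlogram <- function(x, ...) {
  cat(sprintf("<power_correlogram> %s (%s), %d x %d frequencies, %d windows\n",
              if (x$within) "within-region" else
                paste(x$regions, collapse = " x "),
              x$method, length(x$f_a), length(x$f_b), x$n_windows))
  invisible(x)
}

#' @rdname power_correlogram
#' @param x A `power_correlogram`.
#' @param ... Unused.
#' @export
tidy.power_correlogram <- function(x, ...) {
  grid <- expand.grid(i = seq_along(x$f_a), j = seq_along(x$f_b))
  tibble(f_a = x$f_a[grid$i], f_b = x$f_b[grid$j],
         r = x$r[cbind(grid$i, grid$j)])
}

#' @rdname power_correlogram
#' @export
glance.power_correlogram <- function(x, ...) {
  off <- x$r
  if (x$within) diag(off) <- NA
  tibble(n_windows = x$n_windows, method = x$method,
         max_off_diagonal = max(off, na.rm = TRUE),
         min_r = min(x$r, na.rm = TRUE))
}

#' Band-pair summary of a power correlogram
#'
#' Mean correlation coefficient for every pair of named frequency bands
#' (e.g. theta, theta harmonics, gamma). Bands outside the correlogram grid
#' are dropped with a warning.
#'
#' @param pc A `power_correlogram`.
#' @param bands Tibble with columns `band`, `lower`, `upper` (Hz). Default:
#'   theta 6-10, harmonic2 16-20, harmonic3 24-30, harmonic4 32-40, gamma
#'   60-120 Hz.
#' @return Tibble with `band_a`, `band_b`, `mean_r`, `n_pairs`.
#' @export
correlogram_bands_report <- function(pc, bands = NULL) {
  stopifnot(inherits(pc, "power_correlogram"))
  if (is.null(bands)) {
    bands <- tibble(band = c("theta", "harmonic2", "harmonic3", "harmonic4", "gamma"),
                    lower = c(6, 16, 24, 32, 60),
                    upper = c(10, 20, 30, 40, 120))
  }
  in_grid <- function(lo, hi, f) any(f >= lo & f <= hi)
  ok_a <- vapply(seq_len(nrow(bands)),
                 function(i) in_grid(bands$lower[i], bands$upper[i], pc$f_a),
                 logical(1))
  if (any(!ok_a)) {
    warn(sprintf("band(s) outside the frequency grid omitted: %s",
                 paste(bands$band[!ok_a], collapse = ", ")))
    bands <- bands[ok_a, ]
  }
  purrr::map_dfr(seq_len(nrow(bands)), function(i) {
    purrr::map_dfr(seq_len(nrow(bands)), function(j) {
      sel_a <- pc$f_a >= bands$lower[i] & pc$f_a <= bands$upper[i]
      sel_b <- pc$f_b >= bands$lower[j] & pc$f_b <= bands$upper[j]
      block <- pc$r[sel_a, sel_b, drop = FALSE]
      tibble(band_a = bands$band[i], band_b = bands$band[j],
             mean_r = mean(block), n_pairs = length(block))
    })
  })
}
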