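#' Frequency grid of an N-point DFT
#'
#' For `n` samples at spacing `dt = 1/fs`, the DFT lives on frequencies
#' `f_k = k * df`, `k = 0..n-1`, with resolution `df = 1/(n*dt)`. At the
#' pipeline defaults (1250-point windows, 1250 Hz) the resolution is 1 Hz.
#'
#' @param n Number of points.
#' @param fs Sampling rate, Hz.
#' @return A list with `n`, `dt`, `df`, and the frequency vector `f`
#'   (length `n`, strictly increasing from 0).
#' @export
#' @examples
#' frequency_grid(1250, 1250)$df  # 1 Hz
frequency_grid <- function(n, fs) {
  if (n < 1) abort("`n` must be positive.")
  dt <- 1 / fs
  df <- fs / n  # = 1/(n*dt), computed this way so integer rates stay exact
  list(n = as.integer(n), dt = dt, df = df, f = (seq_len(n) - 1) * df)
}

#' Discrete Fourier transform of a de-meaned segment
#'
#' Standard DFT `P_k = sum_j p_j exp(-2*pi*i*k*j/N)`; the segment mean is
#' removed first (enforced, matching the estimators downstream, which all
#' work on de-meaned windows). For real input the coefficients obey the
#' Hermitian symmetry `P_{N-k} = Conj(P_k)`.
#'
#' @param x Numeric vector (one segment).
#' @return Complex vector of length `length(x)`.
#' @export
dft <- function(x) {
  if (length(x) == 0) abort("zero-length segment.")
  stats::fft(x - mean(x))
}

# Batch DFT of a segment matrix (K x N): de-mean each row, return K x N complex.
segment_dft <- function(segments) {
  if (nrow(segments) == 0) {
    return(matrix(complex(0), nrow = 0, ncol = ncol(segments)))
  }
  centered <- segments - rowMeans(segments)
  t(stats::mvfft(t(centered)))
}

#' Welch cross-spectrum of two aligned segment ensembles
#'
#' Ensemble average `S(f_k) = <P_k Q_k*>` over segments, where `P`, `Q` are
#' the DFTs of de-meaned windows of the two series. With `p == q` this is
#' the auto-spectrum (real, non-negative). Values are reported one-sided
#' (bins `0..N/2`, interior bins doubled) as densities per Hz, so that
#' `sum(power) * df` equals the mean de-meaned segment variance (Parseval).
#'
#' @param segset_p,segset_q `segment_set` objects with identical window
#'   boundaries (pass the same object twice for an auto-spectrum).
#' @return A `spectrum_estimate` object; use [tidy()] for a tibble with
#'   `frequency`, `power` (auto) or `power`, `phase` (cross).
#' @export
cross_spectrum <- function(segset_p, segset_q = segset_p) {
  check_aligned(segset_p, segset_q)
  K <- segset_p$n_segments
  if (K < 1) abort("need at least one segment.")
  n <- segset_p$window_samples
  P <- segment_dft(segset_p$segments)
  Q <- if (identical(segset_p, segset_q)) P else segment_dft(segset_q$segments)
  S <- colMeans(P * Conj(Q))
  grid <- frequency_grid(n, segset_p$fs)
  half <- seq_len(n %/% 2 + 1L)
  scale <- rep(2, length(half)); scale[1] <- 1
  if (n %% 2 == 0) scale[length(half)] <- 1
  vals <- S[half] * scale / (n^2 * grid$df)
  auto <- identical(segset_p, segset_q)
  k_eff <- effective_segments(K, segset_p$overlap)
  structure(
    list(frequency = grid$f[half],
         values = if (auto) Re(vals) else vals,
         df = grid$df, fs = segset_p$fs, window_samples = n,
         auto = auto, n_segments = K, dof = 2 * k_eff,
         condition = segset_p$condition,
         regions = c(segset_p$region %||% NA_character_,
                     segset_q$region %||% NA_character_)),
    class = "spectrum_estimate"
  )
}

check_aligned <- function(a, b, c = NULL) {
  sets <- list(a, b, c)
  sets <- sets[!vapply(sets, is.null, logical(1))]
  ns <- vapply(sets, function(s) s$n_segments, numeric(1))
  ws <- vapply(sets, function(s) s$window_samples, numeric(1))
  fss <- vapply(sets, function(s) s$fs, numeric(1))
  if (length(unique(ns)) != 1L || length(unique(ws)) != 1L ||
      length(unique(fss)) != 1L) {
    abort("segment sets are not aligned (segment count, window length and sampling rate must match).")
  }
  invisible(TRUE)
}

#' @export
print.spectrum_estimate <- function(x, ...) {
  cat(sprintf("<spectrum_estimate> %s, %d bins (df = %.4g Hz), %d segments (dof %.1f)%s\n",
              if (x$auto) "auto" else "cross", length(x$frequency), x$df,
              x$n_segments, x$dof,
              if (!is.null(x$condition)) paste0(", condition ", x$condition) else ""))
  invisible(x)
}

#' @rdname cross_spectrum
#' @param x A `spectrum_estimate`.
#' @param ... Unused.
#' @export
tidy.spectrum_estimate <- function(x, ...) {
  if (x$auto) {
    tibble(frequency = x$frequency, power = x$values,
           condition = x$condition %||% NA_character_)
  } else {
    tibble(frequency = x$frequency, power = Mod(x$values),
           phase = Arg(x$values), condition = x$condition %||% NA_character_)
  }
}

#' @rdname cross_spectrum
#' @export
glance.spectrum_estimate <- function(x, ...) {
  tibble(kind = if (x$auto) "auto" else "cross",
         n_segments = x$n_segments, dof = x$dof, df = x$df,
         total_power = sum(Re(x$values)) * x$df)
}

#' Speed-binned power spectral densities
#'
#' One Welch auto-spectrum per speed bin and region, from fixed windows
#' assigned to bins by their mean running speed. At the defaults (1-s
#' windows at 1250 Hz, 50% overlap) the frequency resolution is 1 Hz.
#'
#' @inheritParams segment_by_speed
#' @param max_freq Optional upper frequency bound for the output (Hz).
#' @return A tibble with columns `bin`, `region`, `frequency`, `power`,
#'   `n_segments`, `dof`. Empty bins are omitted with a warning.
#' @export
psd_by_speed <- function(lfp, trajectory, bins = speed_bins(),
                         window = 1, overlap = 0.5, max_freq = NULL) {
  segs <- segment_by_speed(lfp, trajectory, bins, window, overlap)
  empty <- unique(segs$bin[segs$n_segments == 0])
  if (length(empty)) {
    warn(sprintf("speed bin(s) with no qualifying windows omitted: %s",
                 paste(empty, collapse = ", ")))
  }
  segs <- dplyr::filter(segs, .data$n_segments > 0)
  out <- purrr::map_dfr(seq_len(nrow(segs)), function(i) {
    est <- cross_spectrum(segs$segments[[i]])
    tibble(bin = segs$bin[i], region = segs$region[i],
           frequency = est$frequency, power = est$values,
           n_segments = est$n_segments, dof = est$dof)
  })
  if (!is.null(max_freq)) out <- dplyr::filter(out, .data$frequency <= max_freq)
  out
}

#' Across-member confidence interval for power spectra
#'
#' Pointwise t-interval on log-power across ensemble members (typically one
#' spectrum per animal), returned on the power scale. Requires at least two
#' members; for a single recording, bootstrap across segments instead.
#'
#' @param spectra Tibble with columns `member`, `frequency`, `power` (one row
#'   per member and frequency).
#' @param level Coverage level, default 0.95.
#' @return Tibble with `frequency`, `mean_power` (geometric mean), `ci_low`,
#'   `ci_high`, `n_members`.
#' @export
psd_confidence_interval <- function(spectra, level = 0.95) {
  n_members <- length(unique(spectra$member))
  if (n_members < 2) {
    abort("need >= 2 members for an across-member interval; for a single recording use a segment-level bootstrap.")
  }
  alpha <- 1 - level
  spectra |>
    dplyr::group_by(.data$frequency) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      m = mean(log(.data$power)),
      s = stats::sd(log(.data$power)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      half = stats::qt(1 - alpha / 2, df = .data$n_members - 1) *
        .data$s / sqrt(.data$n_members),
      mean_power = exp(.data$m),
      ci_low = exp(.data$m - .data$half),
      ci_high = exp(.data$m + .data$half)
    ) |>
    dplyr::select("frequency", "mean_power", "ci_low", "ci_high", "n_members")
}

#' Paired high-minus-low speed power difference
#'
#' Per-frequency paired difference of log-power between two conditions,
#' pairing members (e.g. animals), with a t-interval on the mean difference.
#' Swapping the arguments flips the sign of the difference.
#'
#' @param high,low Tibbles with `member`, `frequency`, `power`; members must
#'   pair up exactly.
#' @param level Coverage level, default 0.95.
#' @return Tibble with `frequency`, `difference` (mean log-power difference,
#'   high minus low), `ci_low`, `ci_high`, `n_members`.
#' @export
psd_difference <- function(high, low, level = 0.95) {
  if (!setequal(unique(high$member), unique(low$member))) {
    abort("`high` and `low` must contain the same members (paired design).")
  }
  joined <- dplyr::inner_join(
    dplyr::transmute(high, .data$member, .data$frequency, lp_high = log(.data$power)),
    dplyr::transmute(low, .data$member, .data$frequency, lp_low = log(.data$power)),
    by = c("member", "frequency")
  )
  alpha <- 1 - level
  joined |>
    dplyr::mutate(d = .data$lp_high - .data$lp_low) |>
    dplyr::group_by(.data$frequency) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      difference = mean(.data$d),
      s = stats::sd(.data$d),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      half = stats::qt(1 - alpha / 2, df = .data$n_members - 1) *
        .data$s / sqrt(.data$n_members),
      ci_low = .data$difference - .data$half,
      ci_high = .data$difference + .data$half
    ) |>
    dplyr::select("frequency", "difference", "ci_low", "ci_high", "n_members")
}
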