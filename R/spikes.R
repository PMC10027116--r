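#' Binarize a spike train onto a regular sample grid
#'
#' Converts spike times into a 0/1 series at the LFP sampling rate
#' (default 1250 Hz): a sample is 1 when at least one spike maps to it by
#' nearest-sample assignment. Spikes outside the span are dropped with a
#' message.
#'
#' @param spike_times Numeric vector of spike times, seconds.
#' @param span Length-2 vector `c(t0, t1)`, the time span to cover.
#' @param fs Grid rate in Hz, default 1250.
#' @return Integer vector of length `round((t1 - t0) * fs)`.
#' @export
binarize_spike_train <- function(spike_times, span, fs = 1250) {
  n <- round((span[2] - span[1]) * fs)
  out <- integer(n)
  if (length(spike_times)) {
    idx <- round((spike_times - span[1]) * fs) + 1L
    dropped <- sum(idx < 1L | idx > n)
    if (dropped > 0) {
      inform(sprintf("%d spike(s) outside the span dropped.", dropped))
    }
    idx <- idx[idx >= 1L & idx <= n]
    out[idx] <- 1L
  }
  out
}

#' Instantaneous theta phase of an LFP channel
#'
#' Band-passes the trace (Butterworth, zero-phase `filtfilt`) and takes the
#' analytic-signal angle. Phase convention: 0 degrees at the band-passed
#' waveform peak, increasing through the falling flank (90), trough (180)
#' and rising flank (270).
#'
#' @param lfp LFP tibble filtered to one region (`time`, `voltage`).
#' @param band Pass band in Hz, default `c(6, 10)`.
#' @param order Butterworth order, default 3.
#' @return Tibble with `time` and `phase` (degrees in `[0, 360)`).
#' @export
theta_phase <- function(lfp, band = c(6, 10), order = 3) {
  fs <- infer_fs(lfp$time)
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  filt <- signal::filtfilt(bf, lfp$voltage - mean(lfp$voltage))
  tibble(time = lfp$time, phase = wrap_deg(Arg(analytic_signal(filt)) * 180 / pi))
}

# analytic signal via the FFT construction: zero negative frequencies,
# double positive ones
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Occupancy-normalized circular tuning curve
#'
#' Bins a circular variable (head direction or theta phase, degrees) into
#' fixed-width bins, counts spikes per bin (spike angles interpolated from
#' the series), normalizes by the time spent in each bin, and records the
#' spike angles for the circular statistics. Zero-occupancy bins are masked
#' (`NA` rate), not an error.
#'
#' @param spike_times Numeric vector of spike times, seconds.
#' @param series Tibble with `time` and the circular variable in its second
#'   column (degrees in `[0, 360)`), regularly sampled.
#' @param bin_width Bin width in degrees; default 12 (30 bins). Use 30 for
#'   the 12-bin variant.
#' @param variable Label, e.g. `"head_direction"` or `"theta_phase"`.
#' @return A `modulation_profile`: tibble-like object with per-bin
#'   `bin_center`, `occupancy` (s), `count`, `rate` (Hz), plus metadata and
#'   the interpolated spike angles.
#' @export
tuning_curve <- function(spike_times, series, bin_width = 12,
                         variable = "circular") {
  if (360 %% bin_width != 0) abort("`bin_width` must divide 360.")
  angle <- series[[2]]
  ok <- is.finite(angle)
  dt <- 1 / infer_fs(series$time)
  edges <- seq(0, 360, by = bin_width)
  centers <- edges[-length(edges)] + bin_width / 2
  occ_counts <- tabulate(pmin(floor(angle[ok] / bin_width), length(centers) - 1) + 1L,
                         nbins = length(centers))
  occupancy <- occ_counts * dt
  spike_angles <- if (length(spike_times)) {
    interp_angle(series$time[ok], angle[ok], spike_times)
  } else {
    numeric(0)
  }
  counts <- tabulate(pmin(floor(spike_angles / bin_width), length(centers) - 1) + 1L,
                     nbins = length(centers))
  rate <- ifelse(occupancy > 0, counts / occupancy, NA_real_)
  structure(
    list(bins = tibble(bin_center = centers, occupancy = occupancy,
                       count = counts, rate = rate),
         bin_width = bin_width, variable = variable,
         n_spikes = length(spike_angles),
         mean_rate = length(spike_angles) / sum(occupancy),
         spike_angles = spike_angles),
    class = "modulation_profile"
  )
}

#' @export
print.modulation_profile <- function(x, ...) {
  cat(sprintf("<modulation_profile> %s, %d bins of %g deg, %d spikes (mean rate %.3g Hz)\n",
              x$variable, nrow(x$bins), x$bin_width, x$n_spikes, x$mean_rate))
  invisible(x)
}

#' @rdname tuning_curve
#' @param x A `modulation_profile`.
#' @param ... Unused.
#' @export
tidy.modulation_profile <- function(x, ...) x$bins

#' @rdname tuning_curve
#' @export
glance.modulation_profile <- function(x, ...) {
  ray <- rayleigh_test(x$spike_angles)
  tibble(variable = x$variable, n_spikes = x$n_spikes,
         mean_rate = x$mean_rate,
         depth = if (any(is.finite(x$bins$rate)) && max(x$bins$rate, na.rm = TRUE) > 0)
           modulation_depth(x) else NA_real_,
         kappa = concentration(x),
         rayleigh_z = ray$z, rayleigh_p = ray$p)
}

#' Modulation depth of a tuning curve
#'
#' `(max - min) / max` of the occupancy-normalized bin-wise firing rates:
#' 0 for a flat curve, 1 when some bin is silent.
#'
#' @param profile A `modulation_profile`.
#' @return Scalar in `[0, 1]`.
#' @export
modulation_depth <- function(profile) {
  r <- profile$bins$rate
  r <- r[is.finite(r)]
  if (!length(r) || max(r) <= 0) abort("all-zero (or fully masked) profile: depth undefined.")
  (max(r) - min(r)) / max(r)
}

#' Rayleigh test of circular nonuniformity
#'
#' Rayleigh z statistic `z = n * Rbar^2` with the standard finite-sample
#' p-value approximation. By default computed on the spike angles
#' themselves; pass `weights` for the occupancy-weighted bin-rate variant.
#'
#' @param angles Angles in degrees.
#' @param weights Optional non-negative weights (e.g. bin-wise rates at bin
#'   centers).
#' @return One-row tibble with `n`, `rbar`, `z`, `p` (`NA` when fewer than
#'   two spikes/angles are available).
#' @export
rayleigh_test <- function(angles, weights = NULL) {
  rad <- angles * pi / 180
  if (is.null(weights)) weights <- rep(1, length(rad))
  ok <- is.finite(rad) & is.finite(weights)
  rad <- rad[ok]; weights <- weights[ok]
  n <- sum(weights)
  if (length(rad) < 2 || n <= 0) {
    return(tibble(n = length(rad), rbar = NA_real_, z = NA_real_, p = NA_real_))
  }
  rbar <- Mod(sum(weights * exp(1i * rad))) / n
  z <- n * rbar^2
  # Zar's approximation; clamp into (0, 1]
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - (rbar * n)^2)) - (1 + 2 * n))
  tibble(n = length(rad), rbar = rbar, z = z, p = min(max(p, 0), 1))
}

#' Von Mises concentration of a tuning curve
#'
#' Concentration parameter kappa obtained by inverting the mean resultant
#' length of the occupancy-normalized bin-wise firing rates (weights at bin
#' centers), using the standard piecewise inversion. Degenerate profiles
#' (all mass in one bin) are capped at `kappa_max`.
#'
#' @param profile A `modulation_profile` (or a numeric vector of angles in
#'   degrees, for which the unweighted sample kappa is returned).
#' @param kappa_max Cap for degenerate inputs, default 500.
#' @return Scalar kappa estimate (>= 0).
#' @export
concentration <- function(profile, kappa_max = 500) {
  if (inherits(profile, "modulation_profile")) {
    w <- profile$bins$rate
    theta <- profile$bins$bin_center
    ok <- is.finite(w)
    w <- w[ok]; theta <- theta[ok]
    if (!length(w) || sum(w) <= 0) return(0)
    rbar <- Mod(sum(w * exp(1i * theta * pi / 180))) / sum(w)
  } else {
    rad <- profile[is.finite(profile)] * pi / 180
    if (!length(rad)) return(0)
    rbar <- Mod(mean(exp(1i * rad)))
  }
  a1inv(rbar, kappa_max)
}

# Fisher's inversion of the mean resultant length -> kappa
a1inv <- function(rbar, kappa_max = 500) {
  if (!is.finite(rbar) || rbar <= 0) return(0)
  if (rbar >= 1) return(kappa_max)
  k <- if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
  min(k, kappa_max)
}

#' Classify a cell by head-direction and theta-phase tuning
#'
#' A cell is head-direction (HD) tuned when its directional firing is
#' nonuniform (Rayleigh p < `p_threshold`, i.e. nonuniformity with
#' probability > 0.995 at the default) AND the concentration of the
#' directional rate distribution is at least `kappa_threshold`; it is theta
#' modulated when its phase-wise firing is nonuniform at the same level AND
#' its phase modulation depth is at least `depth_threshold`; otherwise it is
#' "other". A cell meeting both criteria is labelled by `precedence`
#' (default HD).
#'
#' @param hd_profile,theta_profile `modulation_profile`s over head direction
#'   and theta phase for the same cell.
#' @param p_threshold Rayleigh p threshold, default 0.005.
#' @param kappa_threshold HD concentration threshold, default 1.0.
#' @param depth_threshold Theta modulation-depth threshold, default 0.1
#'   (strict: a depth of exactly 0.1 passes, anything below does not).
#' @param precedence `"HD"` or `"theta"` for double-qualifiers.
#' @return One-row tibble: `class` plus the criteria record (`hd_p`,
#'   `hd_kappa`, `hd_depth`, `theta_p`, `theta_depth`, `mean_rate`).
#' @export
classify_cell <- function(hd_profile, theta_profile,
                          p_threshold = 0.005, kappa_threshold = 1.0,
                          depth_threshold = 0.1,
                          precedence = c("HD", "theta")) {
  precedence <- match.arg(precedence)
  hd_ray <- rayleigh_test(hd_profile$spike_angles)
  th_ray <- rayleigh_test(theta_profile$spike_angles)
  hd_kappa <- concentration(hd_profile)
  safe_depth <- function(p) {
    tryCatch(modulation_depth(p), error = function(e) NA_real_)
  }
  hd_depth <- safe_depth(hd_profile)
  th_depth <- safe_depth(theta_profile)
  is_hd <- isTRUE(hd_ray$p < p_threshold) && isTRUE(hd_kappa >= kappa_threshold)
  is_theta <- isTRUE(th_ray$p < p_threshold) && isTRUE(th_depth >= depth_threshold)
  class <- if (is_hd && is_theta) {
    if (precedence == "HD") "HD" else "theta"
  } else if (is_hd) "HD" else if (is_theta) "theta" else "other"
  tibble(class = class, mean_rate = hd_profile$mean_rate,
         hd_p = hd_ray$p, hd_kappa = hd_kappa, hd_depth = hd_depth,
         theta_p = th_ray$p, theta_depth = th_depth)
}

#' Classify every cell in a recording
#'
#' Driver over a spike table: builds head-direction and theta-phase tuning
#' curves per cell and applies [classify_cell()].
#'
#' @param spikes Tibble with `cell_id`, `time`.
#' @param trajectory Trajectory tibble with `head_direction`.
#' @param phase Theta-phase tibble from [theta_phase()].
#' @inheritParams classify_cell
#' @inheritParams tuning_curve
#' @return Tibble with one row per cell: `cell_id`, `class`, and the
#'   criteria record.
#' @export
classify_cells <- function(spikes, trajectory, phase, bin_width = 12,
                           p_threshold = 0.005, kappa_threshold = 1.0,
                           depth_threshold = 0.1,
                           precedence = c("HD", "theta")) {
  precedence <- match.arg(precedence)
  hd_series <- dplyr::select(trajectory, "time", "head_direction")
  purrr::map_dfr(unique(spikes$cell_id), function(id) {
    st <- spikes$time[spikes$cell_id == id]
    hd_prof <- tuning_curve(st, hd_series, bin_width, "head_direction")
    th_prof <- tuning_curve(st, phase, bin_width, "theta_phase")
    dplyr::bind_cols(
      tibble(cell_id = id),
      classify_cell(hd_prof, th_prof, p_threshold, kappa_threshold,
                    depth_threshold, precedence)
    )
  })
}

#' Speed-binned spike-train power spectra
#'
#' Cuts the recording into 1-s non-overlapping segments, assigns each by its
#' mean running speed, binarizes every cell's spikes at `fs`, and computes
#' per-cell Welch spectra per speed bin. Each cell's spectrum is divided by
#' its mean power over the report band (so power is in arbitrary units and
#' high-rate cells do not dominate population averages); the report band
#' starts at 4 Hz because the positive mean of binary spike trains inflates
#' the lowest frequencies.
#'
#' @param spikes Tibble with `cell_id`, `time`.
#' @param trajectory Trajectory tibble (speed computed if absent).
#' @param bins Speed bins from [speed_bins()].
#' @param fs Binarization rate, Hz (default 1250).
#' @param window Segment length in seconds, default 1 (non-overlapping).
#' @param band Report band in Hz, default `c(4, 100)`.
#' @return Tibble with `cell_id`, `bin`, `frequency`, `power` (normalized to
#'   mean 1 over the band), `n_segments`, `n_spikes`, `mean_rate`. Cells
#'   with no spikes in a bin are excluded with a message.
#' @export
spike_psd_by_speed <- function(spikes, trajectory, bins = speed_bins(),
                               fs = 1250, window = 1, band = c(4, 100)) {
  if (!"speed" %in% names(trajectory)) trajectory <- compute_speed(trajectory)
  t0 <- min(trajectory$time)
  t1 <- max(trajectory$time)
  n_win <- floor((t1 - t0) / window)
  if (n_win < 1) abort("trajectory too short for one window.")
  starts <- t0 + (seq_len(n_win) - 1) * window
  win_speed <- vapply(starts, function(s) {
    v <- trajectory$speed[trajectory$time >= s & trajectory$time < s + window]
    if (!length(v) || anyNA(v)) NA_real_ else mean(v)
  }, numeric(1))
  nseg <- round(window * fs)
  purrr::map_dfr(unique(spikes$cell_id), function(id) {
    st <- spikes$time[spikes$cell_id == id]
    binary <- binarize_spike_train(st, span = c(t0, t0 + n_win * window), fs = fs)
    segmat <- matrix(binary[seq_len(n_win * nseg)], nrow = n_win, byrow = TRUE)
    purrr::map_dfr(seq_len(nrow(bins)), function(i) {
      sel <- which(!is.na(win_speed) &
                     win_speed > bins$lower[i] & win_speed < bins$upper[i])
      if (!length(sel)) return(tibble())
      sub <- segmat[sel, , drop = FALSE]
      n_spk <- sum(sub)
      if (n_spk == 0) {
        inform(sprintf("cell %s: no spikes in bin '%s'; excluded.", id, bins$label[i]))
        return(tibble())
      }
      ss <- new_segment_set(sub, fs = fs, overlap = 0,
                            starts = starts[sel], condition = bins$label[i])
      est <- cross_spectrum(ss)
      keep <- est$frequency >= band[1] & est$frequency <= band[2]
      p <- est$values[keep]
      tibble(cell_id = id, bin = bins$label[i],
             frequency = est$frequency[keep], power = p / mean(p),
             n_segments = length(sel), n_spikes = n_spk,
             mean_rate = n_spk / (length(sel) * window))
    })
  })
}
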