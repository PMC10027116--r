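#' Specification for the synthetic two-region session generator
#'
#' Collects every parameter of the synthetic data model in one list, so that
#' each coupling strength the analyses estimate is a known, recoverable
#' number. The model emulates the statistical structure the pipeline
#' assumes: a 1/f-type broadband background; a theta rhythm (default 8 Hz)
#' whose amplitude grows with running speed and whose harmonics are
#' phase-locked to the fundamental with offsets controlling waveform
#' skewness/asymmetry; a gamma band carried by narrow-band filtered noise
#' whose envelope is modulated by theta phase (coupling coefficient `c`) and
#' whose amplitude and peak frequency grow with speed; a second "thalamic"
#' region sharing the theta phase with a lag but with gamma power an order
#' of magnitude lower; and spike trains of head-direction-tuned,
#' theta-phase-tuned, and untuned cells on a simulated trajectory whose
#' speed follows a piecewise schedule spanning the analysis speed bins.
#'
#' @param duration Session length, s (default 240).
#' @param sampling_rate LFP rate, Hz (default 1250).
#' @param tracking_rate Tracking rate, Hz (default 39.0625 = 1250/32).
#' @param speed_levels,speed_block Piecewise-constant speed schedule: levels
#'   in cm/s cycled in blocks of `speed_block` seconds. Defaults 5/12/20
#'   cm/s in 10-s blocks, covering the low/mid/high bins.
#' @param theta Named list: `f0` (Hz), `amplitude`, `speed_gain` (fractional
#'   amplitude increase per 10 cm/s), `n_harmonics`, `harmonic_decay`
#'   (geometric amplitude ratio), `harmonic_phases` (degrees; 0 = pure
#'   skewness, 90 = pure asymmetry), `freq_jitter` (Hz, slow wander of the
#'   instantaneous frequency that decorrelates window phases).
#' @param gamma Named list of per-region settings `H` and `T`, each with
#'   `center` (Hz), `width` (Hz), `amplitude`, `speed_gain`, `coupling`
#'   (theta-phase envelope modulation depth, in `[0, 1]`), `freq_shift`
#'   (Hz of peak-frequency growth from rest to 20 cm/s); plus `power_ratio`
#'   (H-to-T gamma power ratio, default 10).
#' @param background Per-region `alpha` (1/f exponent; length 2 with `knee`
#'   for a two-slope spectrum) and `amplitude` (standard deviation).
#' @param cross_region Named list: `theta_lag` (s, thalamic theta phase lag).
#' @param cells Named list: `n_hd`, `n_theta`, `n_other`, `base_rate` (Hz),
#'   `rate_spread` (lognormal sdlog), `kappa` (HD concentration), `locking`
#'   (theta-cell modulation depth m). Cell modulation is scaled down for
#'   high-rate cells (depth-rate anticorrelation).
#' @param ... Overrides merged into the defaults.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(duration = 240, sampling_rate = 1250,
                           tracking_rate = 1250 / 32,
                           speed_levels = c(5, 12, 20), speed_block = 10,
                           theta = list(), gamma = list(),
                           background = list(), cross_region = list(),
                           cells = list(), ...) {
  spec <- list(
    duration = duration, sampling_rate = sampling_rate,
    tracking_rate = tracking_rate,
    speed_levels = speed_levels, speed_block = speed_block,
    theta = modifyList(list(
      f0 = 8, amplitude = 60, speed_gain = 1, n_harmonics = 3,
      harmonic_decay = 0.5, harmonic_phases = c(0, 0, 0), freq_jitter = 0.4
    ), theta),
    gamma = modifyList(list(
      H = list(center = 84, width = 16, amplitude = 18, speed_gain = 1,
               coupling = 0.6, freq_shift = 8),
      T = list(center = 78, width = 14, amplitude = NA, speed_gain = 1,
               coupling = 0.4, freq_shift = 6),
      power_ratio = 10
    ), gamma),
    background = modifyList(list(
      H = list(alpha = c(1, 2), knee = 40, amplitude = 25),
      T = list(alpha = 2, knee = NA, amplitude = 25)
    ), background),
    cross_region = modifyList(list(theta_lag = 0.01), cross_region),
    cells = modifyList(list(
      n_hd = 20, n_theta = 20, n_other = 20,
      base_rate = 5, rate_spread = 0.4, kappa = 2, locking = 0.6
    ), cells)
  )
  spec <- modifyList(spec, list(...))
  if (is.na(spec$gamma$T$amplitude)) {
    spec$gamma$T$amplitude <- spec$gamma$H$amplitude / sqrt(spec$gamma$power_ratio)
  }
  structure(spec, class = "generator_spec")
}

#' Simulate a smooth trajectory following a speed schedule
#'
#' A 2-D random-heading path whose instantaneous speed tracks the piecewise
#' schedule within a few percent; head direction is the heading of motion
#' plus a small jitter.
#'
#' @param spec A [generator_spec()].
#' @param seed Optional seed (RNG state is restored afterwards).
#' @return Trajectory tibble: `time`, `x`, `y` (cm), `head_direction` (deg).
#' @export
generate_trajectory <- function(spec, seed = NULL) {
  if (!is.null(seed)) return(with_seed(seed, generate_trajectory(spec)))
  dt <- 1 / spec$tracking_rate
  n <- round(spec$duration * spec$tracking_rate)
  t <- (seq_len(n) - 1) * dt
  sched <- schedule_speed(t, spec$speed_levels, spec$speed_block)
  # +-2% smooth speed noise, zero-mean
  noise <- as.numeric(stats::filter(stats::rnorm(n), rep(1 / 25, 25), sides = 2, circular = TRUE))
  v <- pmax(0, sched * (1 + 0.1 * noise))
  heading <- cumsum(stats::rnorm(n, 0, 0.6 * sqrt(dt)))
  x <- cumsum(v * cos(heading) * dt)
  y <- cumsum(v * sin(heading) * dt)
  hd <- wrap_deg(heading * 180 / pi + stats::rnorm(n, 0, 4))
  tibble(time = t, x = x, y = y, head_direction = hd)
}

schedule_speed <- function(t, levels, block) {
  idx <- (floor(t / block) %% length(levels)) + 1
  levels[idx]
}

#' Simulate the two-region LFP
#'
#' Builds region H (hippocampal-like) as 1/f background + speed-gained
#' theta with phase-locked harmonics + theta-phase-modulated narrow-band
#' gamma, and region T (thalamic-like) with the same construction on a
#' lagged copy of the theta phase and gamma power scaled down by the
#' configured ratio.
#'
#' @param spec A [generator_spec()].
#' @param trajectory Trajectory covering the session (from
#'   [generate_trajectory()]).
#' @param seed Optional seed.
#' @return Long LFP tibble (`time`, `voltage`, `region` in `c("H", "T")`)
#'   with attribute `"theta_phase"`: a tibble of the ground-truth theta
#'   phase (degrees) of region H.
#' @export
generate_lfp <- function(spec, trajectory, seed = NULL) {
  if (!is.null(seed)) return(with_seed(seed, generate_lfp(spec, trajectory)))
  fs <- spec$sampling_rate
  n <- round(spec$duration * fs)
  t <- (seq_len(n) - 1) / fs
  v <- stats::approx(trajectory$time,
                     schedule_speed(trajectory$time, spec$speed_levels, spec$speed_block),
                     xout = t, rule = 2)$y

  # instantaneous theta frequency wanders slowly so window phases decorrelate
  th <- spec$theta
  f_wander <- slow_noise(n, fs, tau = 2) * th$freq_jitter
  phase <- 2 * pi * cumsum(th$f0 + f_wander) / fs

  region_trace <- function(region, phase_r) {
    bg <- spec$background[[region]]
    ga <- spec$gamma[[region]]
    theta_amp <- th$amplitude * (1 + th$speed_gain * v / 10)
    theta_sig <- theta_amp * cos(phase_r)
    for (k in seq_len(th$n_harmonics)) {
      psi <- th$harmonic_phases[min(k, length(th$harmonic_phases))] * pi / 180
      theta_sig <- theta_sig + theta_amp * th$harmonic_decay^k *
        cos((k + 1) * phase_r + psi)
    }
    gamma_sig <- gamma_component(ga, v, phase_r, fs, n)
    bg_sig <- one_over_f(n, fs, bg$alpha, bg$knee) * bg$amplitude
    theta_sig + gamma_sig + bg_sig
  }

  lag_samp <- round(spec$cross_region$theta_lag * fs)
  phase_T <- if (lag_samp > 0) {
    c(rep(phase[1], lag_samp), phase[seq_len(n - lag_samp)])
  } else {
    phase
  }
  out <- dplyr::bind_rows(
    tibble(time = t, voltage = region_trace("H", phase), region = "H"),
    tibble(time = t, voltage = region_trace("T", phase_T), region = "T")
  )
  attr(out, "theta_phase") <- tibble(time = t, phase = wrap_deg(phase * 180 / pi))
  out
}

# narrow-band noise carrier with theta-phase-modulated envelope and a
# speed-dependent crossfade to a higher-frequency carrier (peak freq growth)
gamma_component <- function(ga, v, phase, fs, n) {
  if (ga$amplitude <= 0) return(numeric(n))
  carrier <- function(center) {
    band <- c(center - ga$width / 2, center + ga$width / 2)
    bf <- signal::butter(3, band / (fs / 2), type = "pass")
    x <- signal::filtfilt(bf, stats::rnorm(n))
    x / stats::sd(x)
  }
  lo <- carrier(ga$center)
  hi <- if (ga$freq_shift > 0) carrier(ga$center + ga$freq_shift) else lo
  w <- pmin(1, pmax(0, v / 20))
  car <- sqrt(1 - w) * lo + sqrt(w) * hi
  env <- ga$amplitude * (1 + ga$speed_gain * v / 10) *
    (1 + ga$coupling * cos(phase))
  env * car
}

# zero-mean, unit-sd noise with ~tau-second autocorrelation
slow_noise <- function(n, fs, tau) {
  w <- max(2L, round(tau * fs))
  x <- as.numeric(stats::filter(stats::rnorm(n), rep(1, w) / w, sides = 2, circular = TRUE))
  x / stats::sd(x)
}

# 1/f^(alpha/2) amplitude-shaped Gaussian noise, unit sd; two-slope when
# alpha has length 2 with a knee frequency
one_over_f <- function(n, fs, alpha, knee = NA) {
  f <- frequency_grid(n, fs)$f
  f_fold <- pmin(f, fs - f)           # two-sided spectrum magnitudes
  a <- if (length(alpha) == 2 && is.finite(knee)) {
    ifelse(f_fold <= knee, alpha[1], alpha[2])
  } else {
    rep(alpha[1], n)
  }
  shape <- numeric(n)
  nz <- f_fold > 0
  shape[nz] <- f_fold[nz]^(-a[nz] / 2)
  if (length(alpha) == 2 && is.finite(knee)) {
    # continuity at the knee: rescale the steep branch
    hi <- nz & f_fold > knee
    shape[hi] <- shape[hi] * knee^(alpha[2] / 2 - alpha[1] / 2)
  }
  x <- Re(stats::fft(stats::fft(stats::rnorm(n)) * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Simulate spike trains on the generated session
#'
#' Inhomogeneous Poisson trains by thinning on the LFP sample grid:
#' head-direction cells follow a von Mises tuning of the trajectory heading,
#' theta cells follow `1 + m cos(theta phase)` using the LFP ground-truth
#' phase, untuned cells are homogeneous. Modulation (kappa, m) is scaled
#' down for high-rate cells so that depth anticorrelates with rate, as in
#' cortical data. Ground-truth labels and parameters are returned alongside.
#'
#' @param spec A [generator_spec()].
#' @param trajectory Trajectory tibble.
#' @param lfp LFP from [generate_lfp()] (source of the ground-truth theta
#'   phase attribute; falls back to band-pass extraction if absent).
#' @param seed Optional seed.
#' @return List with `spikes` (tibble `cell_id`, `time`) and `truth`
#'   (tibble `cell_id`, `class`, `base_rate`, `kappa`, `locking`,
#'   `preferred`).
#' @export
generate_spikes <- function(spec, trajectory, lfp, seed = NULL) {
  if (!is.null(seed)) return(with_seed(seed, generate_spikes(spec, trajectory, lfp)))
  cs <- spec$cells
  fs <- spec$sampling_rate
  n <- round(spec$duration * fs)
  t <- (seq_len(n) - 1) / fs
  dt <- 1 / fs
  hd <- interp_angle(trajectory$time, trajectory$head_direction, t)
  ph_tbl <- attr(lfp, "theta_phase")
  ph <- if (!is.null(ph_tbl)) {
    stats::approx(ph_tbl$time, unwrap_deg(ph_tbl$phase), xout = t, rule = 2)$y %% 360
  } else {
    theta_phase(dplyr::filter(lfp, .data$region == "H"))$phase
  }
  classes <- rep(c("HD", "theta", "other"), c(cs$n_hd, cs$n_theta, cs$n_other))
  n_cells <- length(classes)
  base <- cs$base_rate * exp(stats::rnorm(n_cells, 0, cs$rate_spread))
  mod_scale <- pmin(1.5, pmax(0.25, (cs$base_rate / base)^0.7))
  pref <- stats::runif(n_cells, 0, 360)
  rows <- purrr::map(seq_len(n_cells), function(i) {
    rate <- switch(classes[i],
      HD = {
        k <- cs$kappa * mod_scale[i]
        base[i] * exp(k * cos((hd - pref[i]) * pi / 180)) / besselI(k, 0)
      },
      theta = {
        m <- min(0.95, cs$locking * mod_scale[i])
        base[i] * (1 + m * cos((ph - pref[i]) * pi / 180))
      },
      other = rep(base[i], n)
    )
    spk <- t[stats::runif(n) < rate * dt]
    tibble(cell_id = sprintf("c%02d", i), time = spk)
  })
  truth <- tibble(
    cell_id = sprintf("c%02d", seq_len(n_cells)), class = classes,
    base_rate = base,
    kappa = ifelse(classes == "HD", cs$kappa * mod_scale, 0),
    locking = ifelse(classes == "theta",
                     pmin(0.95, cs$locking * mod_scale), 0),
    preferred = pref
  )
  list(spikes = dplyr::bind_rows(rows), truth = truth)
}

# unwrap degree phase series to a continuous ramp (for interpolation)
unwrap_deg <- function(p) {
  d <- diff(p)
  d <- d - 360 * round(d / 360)
  cumsum(c(p[1], d))
}

#' Simulate a full session, optionally writing it in the on-disk dialects
#'
#' Runs trajectory, LFP and spike generation under one seed and (when `dir`
#' is given) writes the same file dialects the readers consume -- flat
#' binary LFP (`session.eeg`), tracking (`session.whl`), spikes
#' (`session.res`/`.clu`) -- plus `epochs.tsv`, a `meta.yaml` sidecar and a
#' `truth.yaml` ground-truth record, so the whole pipeline can be exercised
#' end to end from files.
#'
#' @param spec A [generator_spec()].
#' @param seed Seed for the whole session (default 1).
#' @param dir Optional output directory (created if missing).
#' @return List with `lfp`, `trajectory`, `spikes`, `truth`, `epochs`,
#'   `spec`, invisibly when writing.
#' @export
simulate_session <- function(spec = generator_spec(), seed = 1, dir = NULL) {
  out <- with_seed(seed, {
    trajectory <- generate_trajectory(spec)
    lfp <- generate_lfp(spec, trajectory)
    spk <- generate_spikes(spec, trajectory, lfp)
    list(lfp = lfp, trajectory = trajectory, spikes = spk$spikes,
         truth = spk$truth,
         epochs = tibble(start = 0, end = spec$duration, label = "RUN"),
         spec = spec)
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    scale <- max(abs(out$lfp$voltage)) / 20000
    write_flat_binary_lfp(out$lfp, file.path(dir, "session.eeg"), scale = scale)
    write_tracking(out$trajectory, file.path(dir, "session.whl"))
    write_spike_files(out$spikes, file.path(dir, "session.res"),
                      file.path(dir, "session.clu"), spec$sampling_rate)
    utils::write.table(out$epochs, file.path(dir, "epochs.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    yaml::write_yaml(list(sampling_rate = spec$sampling_rate,
                          tracking_rate = spec$tracking_rate,
                          regions = unique(out$lfp$region),
                          scale = scale, seed = seed),
                     file.path(dir, "meta.yaml"))
    yaml::write_yaml(list(cells = lapply(seq_len(nrow(out$truth)), function(i)
      as.list(out$truth[i, ])),
      theta = spec$theta, gamma = spec$gamma),
      file.path(dir, "truth.yaml"))
    return(invisible(out))
  }
  out
}
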