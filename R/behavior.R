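#' Speed bins
#'
#' Constructor for a set of running-speed bins. Bins may overlap: the default
#' set is low 1-9 cm/s, mid 8-16 cm/s, and high > 15 cm/s, where the mid bin
#' deliberately overlaps both neighbours, so a window whose mean speed is,
#' say, 8.5 cm/s belongs to both the low and the mid bin.
#'
#' @param labels Character vector of bin labels.
#' @param lower,upper Numeric vectors of bin edges in cm/s; `upper` may be
#'   `Inf` for an open bin. Assignment is half-open on neither side: a window
#'   joins a bin when `lower <= speed <= upper` fails only strictly, i.e.
#'   membership is `speed > lower & speed < upper` for the interior
#'   convention used here (open intervals, matching "1-9", "8-16", ">15"
#'   read as ranges between the printed edges).
#' @return A tibble with columns `label`, `lower`, `upper`.
#' @export
#' @examples
#' speed_bins()
speed_bins <- function(labels = c("low", "mid", "high"),
                       lower = c(1, 8, 15),
                       upper = c(9, 16, Inf)) {
  if (any(lower >= upper)) abort("each bin must have lower < upper.")
  tibble(label = labels, lower = lower, upper = upper)
}

#' Running speed from a trajectory
#'
#' Computes speed as the magnitude of the time derivative of position,
#' optionally smoothed with a boxcar. Missing positions propagate to missing
#' speeds.
#'
#' @param trajectory Trajectory tibble with `time`, `x`, `y`.
#' @param smoothing_window Boxcar width in seconds (default 0.5); 0 disables
#'   smoothing.
#' @return The trajectory with an added `speed` column (cm/s, `NA` where
#'   position is missing).
#' @export
compute_speed <- function(trajectory, smoothing_window = 0.5) {
  ok <- is.finite(trajectory$x) & is.finite(trajectory$y)
  if (sum(ok) < 2) abort("need at least two valid position samples.")
  t <- trajectory$time
  dx <- c(diff(trajectory$x), NA_real_)
  dy <- c(diff(trajectory$y), NA_real_)
  dt <- c(diff(t), NA_real_)
  sp <- sqrt(dx^2 + dy^2) / dt
  # forward difference: carry the last defined value so lengths match
  n <- length(sp)
  if (n >= 2) sp[n] <- sp[n - 1L]
  if (smoothing_window > 0) {
    w <- max(1L, round(smoothing_window * infer_fs(t)))
    if (w > 1L) {
      kern <- rep(1 / w, w)
      sm <- stats::filter(sp, kern, sides = 2)
      sp <- as.numeric(sm)
      # boxcar shrinks the ends; fall back to the raw value there
      sp[is.na(sp) & !is.na(dx)] <- (sqrt(dx^2 + dy^2) / dt)[is.na(sp) & !is.na(dx)]
    }
  }
  dplyr::mutate(trajectory, speed = sp)
}

#' Cut a numeric series into equal-length windows
#'
#' Internal workhorse behind all segment ensembles: splits a regularly
#' sampled series into (optionally overlapping) windows of a fixed number of
#' samples. Returns a `segment_set` object holding a segments-by-samples
#' matrix plus window metadata.
#'
#' @param x Numeric vector (one channel's samples) or an LFP tibble filtered
#'   to a single region.
#' @param fs Sampling rate in Hz (inferred from `time` for tibble input).
#' @param window Window length in seconds (default 1, i.e. 1250 samples at
#'   1250 Hz).
#' @param overlap Overlap fraction in `[0, 1)`; default 0.5.
#' @param condition Optional condition label carried on the result.
#' @param region Optional region label.
#' @param t0 Time of the first sample (default 0; taken from the tibble).
#' @return A `segment_set`: list with `segments` (K x N matrix), `fs`,
#'   `window_samples`, `overlap`, `n_segments`, `starts` (window start times,
#'   s), `condition`, `region`.
#' @export
segment_windows <- function(x, fs = NULL, window = 1, overlap = 0.5,
                            condition = NULL, region = NULL, t0 = 0) {
  if (is.data.frame(x)) {
    if (is.null(region) && "region" %in% names(x)) {
      region <- unique(x$region)
      if (length(region) != 1L) {
        abort("`x` holds several regions; filter to one before segmenting.")
      }
    }
    fs <- fs %||% infer_fs(x$time)
    t0 <- x$time[1]
    x <- x$voltage
  }
  if (is.null(fs)) abort("`fs` is required for vector input.")
  n <- round(window * fs)
  if (n < 2) abort("window too short.")
  step <- max(1L, round(n * (1 - overlap)))
  starts <- seq(1L, length(x) - n + 1L, by = step)
  if (length(x) < n) starts <- integer(0)
  seg <- if (length(starts)) {
    t(vapply(starts, function(s) x[s:(s + n - 1L)], numeric(n)))
  } else {
    matrix(numeric(0), nrow = 0, ncol = n)
  }
  new_segment_set(seg, fs = fs, overlap = overlap,
                  starts = t0 + (starts - 1L) / fs,
                  condition = condition, region = region)
}

new_segment_set <- function(segments, fs, overlap, starts,
                            condition = NULL, region = NULL) {
  structure(
    list(segments = segments, fs = fs, window_samples = ncol(segments),
         overlap = overlap, n_segments = nrow(segments),
         starts = starts, condition = condition, region = region),
    class = "segment_set"
  )
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf(
    "<segment_set> %d segments x %d samples (%.4g s at %g Hz, %d%% overlap)%s%s\n",
    x$n_segments, x$window_samples, x$window_samples / x$fs, x$fs,
    round(100 * x$overlap),
    if (!is.null(x$region)) paste0(", region ", x$region) else "",
    if (!is.null(x$condition)) paste0(", condition ", x$condition) else ""
  ))
  invisible(x)
}

# subset a segment_set by row index
segment_subset <- function(ss, idx) {
  new_segment_set(ss$segments[idx, , drop = FALSE], fs = ss$fs,
                  overlap = ss$overlap, starts = ss$starts[idx],
                  condition = ss$condition, region = ss$region)
}

#' Assign fixed windows to speed bins
#'
#' Cuts each LFP channel (or any regularly sampled series) into fixed
#' windows, computes the mean running speed inside each window from the
#' trajectory, and assigns windows to speed bins by that mean. Windows
#' containing any missing speed sample are dropped. Because the default bins
#' overlap, a window can appear in more than one bin.
#'
#' @param lfp LFP tibble (`time`, `voltage`, `region`), possibly several
#'   regions.
#' @param trajectory Trajectory tibble; `speed` is computed via
#'   [compute_speed()] if absent.
#' @param bins Speed-bin tibble from [speed_bins()].
#' @param window Window length in seconds (default 1).
#' @param overlap Overlap fraction (default 0.5 for LFP; use 0 for the 1-s
#'   non-overlapping spike-train convention).
#' @param smoothing_window Passed to [compute_speed()] when speed is missing.
#' @return A tibble with one row per (bin, region): columns `bin`, `region`,
#'   `n_segments`, and `segments` (a list-column of `segment_set`). Bins with
#'   no qualifying window are kept with `n_segments = 0` so callers can flag
#'   them.
#' @export
segment_by_speed <- function(lfp, trajectory, bins = speed_bins(),
                             window = 1, overlap = 0.5,
                             smoothing_window = 0.5) {
  if (!"speed" %in% names(trajectory)) {
    trajectory <- compute_speed(trajectory, smoothing_window)
  }
  regions <- unique(lfp$region)
  per_region <- lapply(regions, function(r) {
    segment_windows(dplyr::filter(lfp, .data$region == r),
                    window = window, overlap = overlap, region = r)
  })
  names(per_region) <- regions
  ref <- per_region[[1]]
  win_speed <- window_mean_speed(ref, trajectory)
  out <- purrr::map_dfr(seq_len(nrow(bins)), function(i) {
    sel <- which(!is.na(win_speed) &
                   win_speed > bins$lower[i] & win_speed < bins$upper[i])
    purrr::map_dfr(regions, function(r) {
      ss <- segment_subset(per_region[[r]], sel)
      ss$condition <- bins$label[i]
      tibble(bin = bins$label[i], region = r,
             n_segments = ss$n_segments, segments = list(ss))
    })
  })
  out
}

# mean speed inside each window of a segment_set, NA if any speed sample
# inside the window is missing or the trajectory does not cover it
window_mean_speed <- function(ss, trajectory) {
  dur <- ss$window_samples / ss$fs
  tt <- trajectory$time
  vapply(ss$starts, function(s) {
    inside <- tt >= s & tt < s + dur
    if (!any(inside)) return(NA_real_)
    v <- trajectory$speed[inside]
    if (anyNA(v)) NA_real_ else mean(v)
  }, numeric(1))
}

#' Restrict a timed series to labelled epochs
#'
#' Keeps only the rows of a series whose `time` falls inside intervals
#' carrying the requested label, concatenating across intervals.
#'
#' @param series Any tibble with a `time` column (LFP, trajectory, spikes).
#' @param epochs Tibble with `start`, `end`, `label` columns (seconds).
#' @param label Label to keep (e.g. `"RUN"` or `"REM"`).
#' @return The filtered series (possibly empty if the label is absent).
#' @export
restrict_to_epoch <- function(series, epochs, label) {
  keep <- dplyr::filter(epochs, .data$label == !!label)
  if (nrow(keep) == 0) return(series[0, ])
  inside <- rep(FALSE, nrow(series))
  for (i in seq_len(nrow(keep))) {
    inside <- inside | (series$time >= keep$start[i] & series$time < keep$end[i])
  }
  series[inside, ]
}
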