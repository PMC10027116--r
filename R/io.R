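#' Read interleaved flat-binary LFP
#'
#' Reads the flat-binary multi-channel LFP dialect used by Neuroscope-family
#' tools (`.eeg`/`.lfp`): little-endian 16-bit signed integers, channels
#' interleaved sample by sample (sample `j` of channel `c` at position
#' `j * n_channels + c`).
#'
#' @param path Path to the flat binary file.
#' @param n_channels Number of interleaved channels.
#' @param sampling_rate Sampling rate in Hz.
#' @param scale Volts (or any unit) per integer count; voltages are
#'   `raw_int * scale`. Default 1.
#' @param regions Optional character vector of region labels, one per channel;
#'   defaults to `"ch1"`, `"ch2"`, ...
#' @param endian Byte order, `"little"` (default, Neuroscope convention) or
#'   `"big"`.
#'
#' @return A tibble with columns `time` (s), `voltage`, and `region`, in long
#'   format with all channels stacked.
#' @export
read_flat_binary_lfp <- function(path, n_channels, sampling_rate, scale = 1,
                                 regions = NULL, endian = "little") {
  bytes <- file.size(path)
  if (is.na(bytes)) abort(sprintf("file not found: %s", path))
  bps <- 2L * n_channels
  if (bytes %% bps != 0) {
    abort(sprintf(
      "flat binary size %d bytes is not divisible by %d (= %d channels x 2 bytes); expected a multiple of %d.",
      bytes, bps, n_channels, bps
    ))
  }
  n_samples <- bytes %/% bps
  raw <- readBin(path, what = "integer", n = n_samples * n_channels,
                 size = 2L, signed = TRUE, endian = endian)
  if (is.null(regions)) regions <- paste0("ch", seq_len(n_channels))
  if (length(regions) != n_channels) {
    abort("`regions` must have one label per channel.")
  }
  mat <- matrix(raw, nrow = n_channels)  # column j = sample j, interleaved
  t <- (seq_len(n_samples) - 1L) / sampling_rate
  purrr::map_dfr(seq_len(n_channels), function(c) {
    tibble(time = t, voltage = as.numeric(mat[c, ]) * scale, region = regions[c])
  })
}

#' Write interleaved flat-binary LFP
#'
#' Inverse of [read_flat_binary_lfp()]: writes a long-format LFP tibble as
#' little-endian interleaved int16. Values are divided by `scale` and rounded.
#'
#' @param lfp Tibble with `time`, `voltage`, `region` columns.
#' @param path Output path.
#' @inheritParams read_flat_binary_lfp
#' @return `path`, invisibly.
#' @export
write_flat_binary_lfp <- function(lfp, path, scale = 1, endian = "little") {
  regions <- unique(lfp$region)
  cols <- lapply(regions, function(r) lfp$voltage[lfp$region == r])
  n <- unique(lengths(cols))
  if (length(n) != 1L) abort("all channels must have the same sample count.")
  mat <- do.call(rbind, lapply(cols, function(v) as.integer(round(v / scale))))
  if (any(abs(mat) > 32767, na.rm = TRUE)) {
    abort("values exceed int16 range after scaling; increase `scale`.")
  }
  writeBin(as.integer(mat), path, size = 2L, endian = endian)
  invisible(path)
}

#' Read spike time / cluster file pair
#'
#' Reads the `.res`/`.clu` dialect: `.res` holds one spike sample index per
#' line; `.clu` holds the number of clusters on its first line, then one
#' cluster id per spike. Cluster ids 0 and 1 conventionally mark artifact and
#' noise and are excluded by default.
#'
#' @param res_path,clu_path Paths to the spike index and cluster files.
#' @param sampling_rate Rate (Hz) the sample indices refer to.
#' @param exclude_clusters Cluster ids dropped from the output
#'   (default `c(0, 1)`).
#' @return A tibble with columns `cell_id` (the cluster id, as character) and
#'   `time` (spike time in seconds), one row per spike.
#' @export
read_spike_files <- function(res_path, clu_path, sampling_rate,
                             exclude_clusters = c(0, 1)) {
  res <- scan(res_path, what = double(), quiet = TRUE)
  clu <- scan(clu_path, what = double(), quiet = TRUE)
  if (length(clu) == 0 && length(res) == 0) {
    return(tibble(cell_id = character(), time = double()))
  }
  if (length(clu) != length(res) + 1L) {
    abort(sprintf(
      "res/clu length mismatch: %d spike indices but %d cluster lines (expected %d = spikes + 1 header).",
      length(res), length(clu), length(res) + 1L
    ))
  }
  ids <- clu[-1L]
  keep <- !(ids %in% exclude_clusters)
  tibble(cell_id = as.character(ids[keep]), time = res[keep] / sampling_rate) |>
    dplyr::arrange(.data$cell_id, .data$time)
}

#' Write spike time / cluster file pair
#'
#' @param spikes Tibble with `cell_id` and `time` columns.
#' @param res_path,clu_path Output paths.
#' @param sampling_rate Rate (Hz) used to convert times to sample indices.
#' @return `res_path`, invisibly.
#' @export
write_spike_files <- function(spikes, res_path, clu_path, sampling_rate) {
  ord <- order(spikes$time)
  idx <- as.integer(round(spikes$time[ord] * sampling_rate))
  ids <- spikes$cell_id[ord]
  levels <- unique(ids)
  num <- match(ids, levels) + 1L  # start at 2: ids 0/1 are reserved conventions
  writeLines(as.character(idx), res_path)
  writeLines(c(as.character(length(levels) + 2L), as.character(num)), clu_path)
  invisible(res_path)
}

#' Read position / head-direction tracking
#'
#' Reads whitespace-delimited tracking files (`.whl` dialect) at a fixed
#' tracking rate. A value of -1 marks lost tracking and becomes `NA`. With
#' two columns the file holds `x y`; with four columns it holds the two LED
#' positions `x1 y1 x2 y2`, from which head direction is derived as
#' `atan2(y1 - y2, x1 - x2)` (front LED minus back LED), reported in degrees
#' in `[0, 360)`.
#'
#' @param path Path to the tracking file.
#' @param tracking_rate Sampling rate of the tracking system, Hz.
#' @return A trajectory tibble with columns `time` (s), `x`, `y` (cm, `NA`
#'   when tracking is lost) and, for 4-column input, `head_direction`
#'   (degrees in `[0, 360)`).
#' @export
read_tracking <- function(path, tracking_rate) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(time = double(), x = double(), y = double()))
  }
  rows <- strsplit(trimws(lines), "\\s+")
  ncol <- length(rows[[1]])
  if (ncol < 2) abort("tracking file must have at least two numeric columns.")
  mat <- matrix(NA_real_, nrow = length(rows), ncol = ncol)
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != ncol) {
      abort(sprintf("tracking line %d has %d fields, expected %d.",
                    i, length(rows[[i]]), ncol))
    }
    v <- suppressWarnings(as.numeric(rows[[i]]))
    if (anyNA(v)) abort(sprintf("non-numeric tracking value on line %d.", i))
    mat[i, ] <- v
  }
  mat[mat == -1] <- NA_real_
  t <- (seq_len(nrow(mat)) - 1L) / tracking_rate
  if (ncol >= 4) {
    hd <- wrap_deg(atan2(mat[, 2] - mat[, 4], mat[, 1] - mat[, 3]) * 180 / pi)
    tibble(time = t,
           x = (mat[, 1] + mat[, 3]) / 2,
           y = (mat[, 2] + mat[, 4]) / 2,
           head_direction = hd)
  } else {
    tibble(time = t, x = mat[, 1], y = mat[, 2])
  }
}

#' Write tracking file
#'
#' Writes a trajectory tibble in the whitespace-delimited tracking dialect
#' read by [read_tracking()]. Missing positions become the -1 sentinel. When
#' `head_direction` is present, two LED positions straddling the head centre
#' are written (4 columns); otherwise `x y` (2 columns).
#'
#' @param trajectory Trajectory tibble (`time`, `x`, `y`, optional
#'   `head_direction`).
#' @param path Output path.
#' @param led_distance Distance between the two synthesized LEDs, same unit
#'   as `x`/`y`. Default 2.
#' @return `path`, invisibly.
#' @export
write_tracking <- function(trajectory, path, led_distance = 2) {
  if ("head_direction" %in% names(trajectory)) {
    rad <- trajectory$head_direction * pi / 180
    h <- led_distance / 2
    m <- cbind(trajectory$x + h * cos(rad), trajectory$y + h * sin(rad),
               trajectory$x - h * cos(rad), trajectory$y - h * sin(rad))
  } else {
    m <- cbind(trajectory$x, trajectory$y)
  }
  m[is.na(m)] <- -1
  writeLines(apply(format(m, trim = TRUE, scientific = FALSE), 1L, paste, collapse = " "),
             path)
  invisible(path)
}

#' Read a simulated or converted recording session from a directory
#'
#' Expects the layout written by [simulate_session()]: `session.eeg`,
#' `session.whl`, `session.res` / `session.clu`, `epochs.tsv`, and a
#' `meta.yaml` sidecar holding `sampling_rate`, `tracking_rate`, `regions`,
#' and `scale`.
#'
#' @param dir Session directory.
#' @return A list with elements `lfp`, `trajectory`, `spikes`, `epochs`,
#'   `meta`.
#' @export
read_session <- function(dir) {
  meta_path <- file.path(dir, "meta.yaml")
  if (!file.exists(meta_path)) abort(sprintf("no meta.yaml in %s", dir))
  meta <- yaml::read_yaml(meta_path)
  lfp <- read_flat_binary_lfp(file.path(dir, "session.eeg"),
                              n_channels = length(meta$regions),
                              sampling_rate = meta$sampling_rate,
                              scale = meta$scale %||% 1,
                              regions = unlist(meta$regions))
  trajectory <- read_tracking(file.path(dir, "session.whl"), meta$tracking_rate)
  spikes <- if (file.exists(file.path(dir, "session.res"))) {
    read_spike_files(file.path(dir, "session.res"), file.path(dir, "session.clu"),
                     meta$sampling_rate)
  } else {
    tibble(cell_id = character(), time = double())
  }
  epochs_path <- file.path(dir, "epochs.tsv")
  epochs <- if (file.exists(epochs_path)) {
    as_tibble(utils::read.delim(epochs_path))
  } else {
    tibble(start = 0, end = max(lfp$time), label = "RUN")
  }
  list(lfp = lfp, trajectory = trajectory, spikes = spikes,
       epochs = epochs, meta = meta)
}
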