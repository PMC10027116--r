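#' Plot a spectrum estimate
#'
#' Log-power spectrum with the frequency axis in Hz.
#'
#' @param object A `spectrum_estimate`.
#' @param max_freq Upper frequency limit (Hz), default 120.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectrum_estimate <- function(object, max_freq = 120, ...) {
  df <- dplyr::filter(tidy(object), .data$frequency <= max_freq,
                      .data$frequency > 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$frequency, .data$power)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "power density",
                  title = if (object$auto) "power spectral density" else "cross-spectrum magnitude")
}

#' Plot speed-binned power spectra
#'
#' One log-power curve per speed bin, faceted by region.
#'
#' @param psd Tibble from [psd_by_speed()].
#' @param max_freq Upper frequency limit (Hz), default 120.
#' @return A ggplot.
#' @export
plot_psd_by_speed <- function(psd, max_freq = 120) {
  df <- dplyr::filter(psd, .data$frequency <= max_freq, .data$frequency > 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$frequency, .data$power, colour = .data$bin)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~region, scales = "free_y") +
    ggplot2::labs(x = "frequency (Hz)", y = "power density", colour = "speed bin")
}

#' Plot a bicoherence plane
#'
#' Raster of the bicoherence modulus `|b|` over the principal domain.
#'
#' @param object A `bispectrum_estimate`.
#' @param part One of `"modulus"`, `"real"` (skewness-related), `"imag"`
#'   (asymmetry-related).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bispectrum_estimate <- function(object,
                                         part = c("modulus", "real", "imag"),
                                         ...) {
  part <- match.arg(part)
  df <- dplyr::filter(tidy(object), .data$in_principal_domain)
  df$value <- switch(part, modulus = df$bicoherence,
                     real = df$skewness_part, imag = df$asymmetry_part)
  ggplot2::ggplot(df, ggplot2::aes(.data$f1, .data$f2, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    (if (part == "modulus") ggplot2::scale_fill_viridis_c(limits = c(0, 1))
     else ggplot2::scale_fill_gradient2()) +
    ggplot2::labs(x = "f1 (Hz)", y = "f2 (Hz)",
                  fill = switch(part, modulus = "|b|", real = "Re b", imag = "Im b"))
}

#' Plot a power correlogram
#'
#' Raster of the frequency-pair correlation matrix; within-region planes
#' show only the lower triangle (the matrix is symmetric there).
#'
#' @param object A `power_correlogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.power_correlogram <- function(object, ...) {
  df <- tidy(object)
  if (object$within) df <- dplyr::filter(df, .data$f_b <= .data$f_a)
  ggplot2::ggplot(df, ggplot2::aes(.data$f_a, .data$f_b, fill = .data$r)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = sprintf("frequency, %s (Hz)", object$regions[1]),
                  y = sprintf("frequency, %s (Hz)", object$regions[2]),
                  fill = "r")
}

#' Plot a circular tuning curve
#'
#' Occupancy-normalized firing rate over the circular variable.
#'
#' @param object A `modulation_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.modulation_profile <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$bin_center, .data$rate)) +
    ggplot2::geom_col(width = object$bin_width * 0.9) +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::labs(x = object$variable, y = "rate (Hz)")
}

#' Plot coupling strength by speed bin
#'
#' ROI-summed bicoherence per triad type across speed bins, faceted by
#' region pair and arrangement.
#'
#' @param summary Tibble from [coupling_by_speed()].
#' @return A ggplot.
#' @export
plot_coupling_summary <- function(summary) {
  df <- dplyr::filter(summary, !.data$masked)
  ggplot2::ggplot(df, ggplot2::aes(.data$bin, .data$strength,
                                   colour = .data$triad,
                                   group = .data$triad)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::facet_wrap(~arrangement, scales = "free_y") +
    ggplot2::labs(x = "speed bin", y = "ROI-summed bicoherence",
                  colour = "triad")
}
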