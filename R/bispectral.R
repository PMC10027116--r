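#' Auto- and cross-bispectrum with bicoherence normalization
#'
#' Ensemble-averaged triple product `B(f_m, f_n) = <P_m Q_n R*_{m+n}>` over
#' aligned de-meaned windows, where `P`, `Q`, `R` are the DFTs of the three
#' segment ensembles (pass one ensemble once for the auto-bispectrum, or
#' `p = q` from one region and `r` from another for the cross-regional
#' `ppq` arrangement). The normalized bicoherence
#' `b = B / sqrt(<|P_m Q_n|^2> <|R_{m+n}|^2>)` satisfies `|b| <= 1`
#' everywhere by the Cauchy-Schwarz inequality; its modulus measures
#' quadratic phase coupling of the frequency triad `(f_m, f_n, f_m + f_n)`
#' and its argument is the biphase.
#'
#' The plane is computed for `f1 >= 0` and `f2` of both signs (sum and
#' difference interactions); bins whose sum index falls outside the grid are
#' masked. The nonredundant principal domain is octant 1 for the auto case
#' and octants 1 and 8 for the `ppq` cross case (see [principal_domain()]).
#'
#' @param segset_p,segset_q,segset_r Aligned `segment_set` objects (same
#'   window boundaries). Defaults make `cross_bispectrum(ss)` the
#'   auto-bispectrum and `cross_bispectrum(ss_a, ss_a, ss_b)` the `ppq`
#'   cross arrangement.
#' @param max_freq Truncate the plane at this frequency (Hz) to save time;
#'   the DFTs always use the full window, so sum-frequency terms above
#'   `max_freq` remain exact. Default: Nyquist.
#' @return A `bispectrum_estimate` object with fields `f1`, `f2`, `B`
#'   (complex matrix, rows `f1`), `b` (normalized bicoherence), `mask`
#'   (principal-domain logical matrix), `kind`, `arrangement`, `dof`,
#'   `n_segments`, `condition`. Use [tidy()] for a long tibble.
#' @export
cross_bispectrum <- function(segset_p, segset_q = segset_p,
                             segset_r = segset_q, max_freq = NULL) {
  check_aligned(segset_p, segset_q, segset_r)
  K <- segset_p$n_segments
  if (K < 1) abort("need at least one segment.")
  n <- segset_p$window_samples
  fs <- segset_p$fs
  grid <- frequency_grid(n, fs)
  M <- n %/% 2L
  mmax <- if (is.null(max_freq)) M else min(M, floor(max_freq / grid$df))

  same_pq <- identical(segset_p, segset_q)
  same_qr <- identical(segset_q, segset_r)
  kind <- if (same_pq && same_qr) "auto" else if (same_pq) "cross_ppq" else "cross_pqr"

  P <- segment_dft(segset_p$segments)
  Q <- if (same_pq) P else segment_dft(segset_q$segments)
  R <- if (same_qr) Q else segment_dft(segset_r$segments)

  m_idx <- 0:mmax                      # rows, f1 >= 0
  n_idx <- (-mmax):mmax                # cols, f2 both signs
  # DFT array index (1-based) for signed frequency index k: k>=0 -> k+1,
  # k<0 -> N+k+1 (exact negative-frequency coefficient, no conjugation needed)
  col_of <- function(k) ifelse(k >= 0, k + 1L, n + k + 1L)
  q_cols <- col_of(n_idx)
  s_mat <- outer(m_idx, n_idx, "+")    # sum index m+n
  valid <- s_mat >= 0L & s_mat <= M
  s_safe <- ifelse(valid, s_mat, 0L) + 1L

  nr <- length(m_idx); nc <- length(n_idx)
  num <- matrix(0 + 0i, nr, nc)
  d1 <- matrix(0, nr, nc)
  d2v <- numeric(M + 1L)
  for (k in seq_len(K)) {
    pk <- P[k, m_idx + 1L]
    qk <- Q[k, q_cols]
    rk <- R[k, seq_len(M + 1L)]
    pq <- outer(pk, qk)
    num <- num + pq * Conj(matrix(rk[s_safe], nr, nc))
    d1 <- d1 + Mod(pq)^2
    d2v <- d2v + Mod(rk)^2
  }
  B <- num / K
  denom <- sqrt((d1 / K) * matrix(d2v[s_safe] / K, nr, nc))
  b <- B / denom
  b[!valid] <- NA_complex_
  B[!valid] <- NA_complex_
  # bins with (numerically) zero denominator -- e.g. anything touching the
  # de-meaned DC bin -- are undefined, not data
  dmax <- max(denom[valid], 0, na.rm = TRUE)
  b[valid & (!is.finite(denom) | denom <= 1e-10 * dmax)] <- NA_complex_

  f1 <- m_idx * grid$df
  f2 <- n_idx * grid$df
  pd <- principal_domain_mask(kind, f1, f2, f_nyquist = M * grid$df)
  structure(
    list(f1 = f1, f2 = f2, B = B, b = b, mask = pd & valid,
         kind = kind,
         arrangement = c(segset_p$region %||% "p", segset_q$region %||% "q",
                         segset_r$region %||% "r"),
         df = grid$df, fs = fs, window_samples = n,
         n_segments = K, dof = effective_segments(K, segset_p$overlap),
         condition = segset_p$condition),
    class = "bispectrum_estimate"
  )
}

#' Normalized bicoherence field of a bispectrum estimate
#'
#' Returns the complex normalized bicoherence `b` (modulus = bicoherence,
#' argument = biphase). Bins with a zero or undefined denominator are `NA`.
#'
#' @param est A `bispectrum_estimate`.
#' @return Complex matrix (rows `f1`, columns `f2`).
#' @export
normalize_bicoherence <- function(est) {
  stopifnot(inherits(est, "bispectrum_estimate"))
  est$b
}

# principal-domain logical mask given frequency axes
principal_domain_mask <- function(kind, f1, f2, f_nyquist) {
  F1 <- matrix(f1, length(f1), length(f2))
  F2 <- matrix(f2, length(f1), length(f2), byrow = TRUE)
  s_ok <- (F1 + F2) >= 0 & (F1 + F2) <= f_nyquist
  if (kind == "auto") {
    F2 >= 0 & F2 <= F1 & s_ok
  } else {
    abs(F2) <= F1 & s_ok
  }
}

#' Principal (nonredundant) domain of the bispectral plane
#'
#' The symmetries of the bispectrum make most of the `(f1, f2)` plane
#' redundant: for real signals, negating both frequencies conjugates the
#' estimate, and the first two slots commute. For the auto-bispectrum the
#' additional identity `B(m, -n) = Conj(B(m - n, n))` reduces the
#' nonredundant region to octant 1 (`0 <= f2 <= f1`, `f1 + f2 <=` Nyquist);
#' for the `ppq` cross arrangement it is octants 1 and 8
#' (`|f2| <= f1`), bounded by the Nyquist frequency.
#'
#' @param kind `"auto"` or `"cross_ppq"`.
#' @param n Window length in samples.
#' @param fs Sampling rate, Hz.
#' @param max_freq Optional truncation frequency (Hz), as in
#'   [cross_bispectrum()].
#' @return A list with `f1`, `f2` (axes, Hz) and `mask` (logical matrix,
#'   rows `f1`).
#' @export
principal_domain <- function(kind = c("auto", "cross_ppq"), n, fs,
                             max_freq = NULL) {
  kind <- match.arg(kind)
  grid <- frequency_grid(n, fs)
  M <- n %/% 2L
  mmax <- if (is.null(max_freq)) M else min(M, floor(max_freq / grid$df))
  f1 <- (0:mmax) * grid$df
  f2 <- ((-mmax):mmax) * grid$df
  list(f1 = f1, f2 = f2,
       mask = principal_domain_mask(kind, f1, f2, M * grid$df))
}

#' Skewness / asymmetry decomposition of the auto-bicoherence
#'
#' For a single region, the real part of the normalized auto-bispectrum
#' reflects the skewness of the waveform (vertical peak-trough imbalance,
#' "sawtooth" peakedness) while the imaginary part reflects its asymmetry
#' (forward-backward tilt). No such interpretation exists for cross
#' arrangements, which is an error here.
#'
#' @param est A `bispectrum_estimate` of kind `"auto"`.
#' @return A tibble over the principal domain with columns `f1`, `f2`,
#'   `skewness_part`, `asymmetry_part`.
#' @export
skewness_asymmetry_decomposition <- function(est) {
  stopifnot(inherits(est, "bispectrum_estimate"))
  if (est$kind != "auto") {
    abort("skewness/asymmetry interpretation requires the auto-bispectrum; cross arrangements have no such decomposition.")
  }
  idx <- which(est$mask, arr.ind = TRUE)
  tibble(f1 = est$f1[idx[, 1]], f2 = est$f2[idx[, 2]],
         skewness_part = Re(est$b[idx]),
         asymmetry_part = Im(est$b[idx]))
}

# package-local cache for Monte-Carlo null thresholds
.threshold_cache <- new.env(parent = emptyenv())

#' Bicoherence significance level under a Gaussian-noise null
#'
#' Monte-Carlo estimate of the `level` quantile of the bicoherence modulus
#' `|b|` at an interior frequency pair for Gaussian white noise, when the
#' estimate averages `dof` effective (independent) segments. The null level
#' scales as `1/sqrt(dof)` (empirically ~ `sqrt(3/dof)`). Results are cached
#' per `(dof, n_reps, seed, level)`, and the user's RNG state is untouched.
#'
#' @param dof Effective number of averaged segments (>= 2).
#' @param n_reps Monte-Carlo replicates, default 2000.
#' @param seed RNG seed for the replicates, default 1.
#' @param level Quantile, default 0.95.
#' @return The `|b|` threshold (scalar).
#' @export
significance_threshold <- function(dof, n_reps = 2000, seed = 1, level = 0.95) {
  stopifnot_scalar_number(dof, "dof")
  if (dof < 2) abort("`dof` must be >= 2.")
  K <- as.integer(round(dof))
  key <- sprintf("K%d_r%d_s%d_l%g", K, n_reps, seed, level)
  if (!is.null(.threshold_cache[[key]])) return(.threshold_cache[[key]])
  nfft <- 64L
  m <- 5L; nn <- 9L  # interior pair, sum index 14 < Nyquist 32
  vals <- with_seed(seed, {
    out <- numeric(n_reps)
    chunk <- max(1L, min(n_reps, 250L))
    done <- 0L
    while (done < n_reps) {
      nb <- min(chunk, n_reps - done)
      x <- matrix(stats::rnorm(nfft * K * nb), nrow = nfft)
      x <- sweep(x, 2L, colMeans(x))
      Fx <- stats::mvfft(x)
      X <- Fx[m + 1L, ] * Fx[nn + 1L, ]
      Y <- Fx[m + nn + 1L, ]
      dim(X) <- c(K, nb); dim(Y) <- c(K, nb)
      num <- Mod(colMeans(X * Conj(Y)))
      den <- sqrt(colMeans(Mod(X)^2) * colMeans(Mod(Y)^2))
      out[done + seq_len(nb)] <- num / den
      done <- done + nb
    }
    out
  })
  thr <- unname(stats::quantile(vals, level))
  .threshold_cache[[key]] <- thr
  thr
}

#' Coupling region of interest on the bicoherence plane
#'
#' Named polygonal regions over which bicoherence is summed to quantify
#' nonlinear coupling strength. Band defaults: theta (and harmonics)
#' `[4, 40]` Hz, gamma `[42, 100]` Hz. Available regions:
#' \describe{
#'   \item{`theta_theta`}{triangle `theta_lo <= f2 <= f1`, `f1 + f2 <`
#'     `theta_hi` -- theta and its harmonics phase-coupled to themselves.}
#'   \item{`theta_gamma_sum`}{quadrant-1 trapezoid, gamma on `f1`, theta on
#'     `f2` (sum triad `theta + gamma = gamma`).}
#'   \item{`theta_gamma_diff`}{octant-8 trapezoid, gamma on `f1`, negative
#'     theta on `f2` (difference triad `gamma - theta = gamma`).}
#'   \item{`theta_gamma_gg`}{octant-8 region with both axes in gamma and the
#'     sum in theta (`gamma - gamma = theta`, the "theta-modulated gamma"
#'     difference interaction).}
#'   \item{`gamma_gamma`}{octant-1 triangle with both axes in gamma.}
#' }
#' Membership is by bin centre; band edges are half-open (lower edge in,
#' upper edge out) so adjacent regions never double-count a bin. Regions are
#' always clipped to the principal domain of the estimate they are applied
#' to.
#'
#' @param name One of the region names above.
#' @param theta_band,gamma_band Band bounds in Hz.
#' @return A `coupling_roi` object.
#' @export
coupling_roi <- function(name = c("theta_theta", "theta_gamma_sum",
                                  "theta_gamma_diff", "theta_gamma_gg",
                                  "gamma_gamma"),
                         theta_band = c(4, 40), gamma_band = c(42, 100)) {
  name <- match.arg(name)
  structure(list(name = name, theta_band = theta_band, gamma_band = gamma_band),
            class = "coupling_roi")
}

# half-open bin-centre membership, before principal-domain clipping
roi_member <- function(roi, F1, F2) {
  th <- roi$theta_band; ga <- roi$gamma_band
  switch(roi$name,
    theta_theta = F2 >= th[1] & F2 <= F1 & (F1 + F2) < th[2],
    theta_gamma_sum = F1 >= ga[1] & F1 < ga[2] & F2 >= th[1] & F2 < th[2],
    theta_gamma_diff = F1 >= ga[1] & F1 < ga[2] & F2 <= -th[1] & F2 > -th[2],
    theta_gamma_gg = F1 >= ga[1] & F1 < ga[2] & F2 <= -ga[1] & F2 > -ga[2] &
      (F1 + F2) >= th[1] & (F1 + F2) < th[2],
    gamma_gamma = F2 >= ga[1] & F2 <= F1 & F1 < ga[2]
  )
}

#' ROI-summed coupling strength
#'
#' Sums the bicoherence modulus `|b|` over the bins of a region of interest
#' (clipped to the principal domain), the paper-style scalar statistic of
#' nonlinear coupling strength. The raw sum is reported together with the
#' bin count so a mean variant is derivable.
#'
#' @param est A `bispectrum_estimate`.
#' @param roi A `coupling_roi`.
#' @param squared Use `|b|^2` instead of `|b|` (default `FALSE`).
#' @return One-row tibble: `roi`, `strength`, `n_bins`, `dof`, `n_segments`,
#'   `condition`.
#' @export
roi_coupling_strength <- function(est, roi, squared = FALSE) {
  stopifnot(inherits(est, "bispectrum_estimate"), inherits(roi, "coupling_roi"))
  F1 <- matrix(est$f1, length(est$f1), length(est$f2))
  F2 <- matrix(est$f2, length(est$f1), length(est$f2), byrow = TRUE)
  sel <- roi_member(roi, F1, F2) & est$mask & is.finite(Mod(est$b))
  if (!any(sel)) {
    abort(sprintf("ROI '%s' contains no bins on this grid/principal domain.", roi$name))
  }
  v <- Mod(est$b[sel])
  tibble(roi = roi$name,
         strength = if (squared) sum(v^2) else sum(v),
         n_bins = sum(sel), dof = est$dof, n_segments = est$n_segments,
         condition = est$condition %||% NA_character_)
}

#' Enumerate cross-regional triad families and their ROIs
#'
#' For a pair of distinct regions `(a, b)` there are two `ppq` cross
#' arrangements (`a a b` and `b b a`). Each carries a theta-theta harmonic
#' triangle and three theta-gamma regions -- the quadrant-1 sum trapezoid
#' and the two octant-8 difference regions (`gamma - theta = gamma` and
#' `gamma - gamma = theta`) -- six theta-gamma regions per pair in total.
#' With identical labels the enumeration falls back to the auto case with
#' octant-1 ROIs only (theta-theta, theta-gamma sum, gamma-gamma).
#'
#' @param regions Character vector of two region labels (may be identical).
#' @inheritParams coupling_roi
#' @return Tibble with columns `arrangement` (three slot labels, collapsed),
#'   `slots` (list of length-3 character vectors), `triad` (ROI name),
#'   `components` (human-readable triad description), `roi` (list-column of
#'   `coupling_roi`).
#' @export
enumerate_triads <- function(regions, theta_band = c(4, 40),
                             gamma_band = c(42, 100)) {
  if (length(regions) != 2L) abort("`regions` must have length 2.")
  a <- regions[1]; b <- regions[2]
  roi_of <- function(nm) coupling_roi(nm, theta_band, gamma_band)
  if (a == b) {
    triads <- c("theta_theta", "theta_gamma_sum", "gamma_gamma")
    comps <- c(sprintf("theta[%s] theta[%s] theta[%s]", a, a, a),
               sprintf("theta[%s] gamma[%s] gamma[%s]", a, a, a),
               sprintf("gamma[%s] gamma[%s] gamma[%s]", a, a, a))
    return(tibble(arrangement = paste(a, a, a, sep = "-"),
                  slots = list(c(a, a, a)), triad = triads,
                  components = comps, roi = lapply(triads, roi_of)))
  }
  one_family <- function(p, q) {
    triads <- c("theta_theta", "theta_gamma_sum", "theta_gamma_diff",
                "theta_gamma_gg")
    comps <- c(
      sprintf("theta[%s] theta[%s] theta[%s]", p, p, q),
      sprintf("theta[%s] gamma[%s] gamma[%s]", p, p, q),
      sprintf("theta[%s] gamma[%s] gamma[%s]", p, q, p),
      sprintf("theta[%s] gamma[%s] gamma[%s]", q, p, p)
    )
    tibble(arrangement = paste(p, p, q, sep = "-"),
           slots = rep(list(c(p, p, q)), length(triads)),
           triad = triads, components = comps,
           roi = lapply(triads, roi_of))
  }
  dplyr::bind_rows(one_family(a, b), one_family(b, a))
}

#' Coupling strength by speed bin
#'
#' End-to-end driver: segments a multi-region LFP by running speed, computes
#' the auto- and cross-regional bispectra for every arrangement returned by
#' [enumerate_triads()], and sums bicoherence over each triad ROI, giving
#' one coupling scalar per (region pair, triad, speed bin). Bins with fewer
#' than `min_segments` qualifying windows are reported masked.
#'
#' @inheritParams segment_by_speed
#' @param pairs List of length-2 character vectors of region labels;
#'   defaults to every unordered pair of regions present plus each region
#'   with itself.
#' @param max_freq Plane truncation in Hz (default 110, covering the gamma
#'   band and its theta sidebands).
#' @param min_segments Minimum windows per bin (default 8).
#' @inheritParams coupling_roi
#' @return Tibble with `pair`, `arrangement`, `triad`, `components`, `bin`,
#'   `strength`, `n_bins`, `n_segments`, `dof`, `masked`, `reason`.
#' @export
coupling_by_speed <- function(lfp, trajectory, bins = speed_bins(),
                              pairs = NULL, window = 1, overlap = 0.5,
                              max_freq = 110, min_segments = 8,
                              theta_band = c(4, 40), gamma_band = c(42, 100)) {
  segs <- segment_by_speed(lfp, trajectory, bins, window, overlap)
  regions <- unique(segs$region)
  if (is.null(pairs)) {
    pairs <- lapply(regions, function(r) c(r, r))
    if (length(regions) > 1) {
      cmb <- utils::combn(regions, 2, simplify = FALSE)
      pairs <- c(pairs, cmb)
    }
  }
  get_ss <- function(bin, region) {
    segs$segments[[which(segs$bin == bin & segs$region == region)]]
  }
  purrr::map_dfr(pairs, function(pr) {
    triads <- enumerate_triads(pr, theta_band, gamma_band)
    purrr::map_dfr(unique(bins$label), function(bl) {
      purrr::map_dfr(unique(triads$arrangement), function(arr) {
        tri <- dplyr::filter(triads, .data$arrangement == arr)
        slots <- tri$slots[[1]]
        ss_p <- get_ss(bl, slots[1]); ss_r <- get_ss(bl, slots[3])
        base <- tibble(pair = paste(sort(unique(pr)), collapse = "-"),
                       arrangement = arr, triad = tri$triad,
                       components = tri$components, bin = bl)
        if (ss_p$n_segments < min_segments) {
          return(dplyr::mutate(base, strength = NA_real_, n_bins = NA_integer_,
                               n_segments = ss_p$n_segments, dof = NA_real_,
                               masked = TRUE,
                               reason = sprintf("only %d segments (< %d)",
                                                ss_p$n_segments, min_segments)))
        }
        est <- cross_bispectrum(ss_p, ss_p, ss_r, max_freq = max_freq)
        res <- purrr::map_dfr(tri$roi, function(r) roi_coupling_strength(est, r))
        dplyr::mutate(base, strength = res$strength, n_bins = res$n_bins,
                      n_segments = est$n_segments, dof = est$dof,
                      masked = FALSE, reason = NA_character_)
      })
    })
  })
}

#' @export
print.bispectrum_estimate <- function(x, ...) {
  cat(sprintf(
    "<bispectrum_estimate> %s [%s], plane %d x %d (df = %.4g Hz), %d segments (dof %.1f)%s\n",
    x$kind, paste(x$arrangement, collapse = ","),
    length(x$f1), length(x$f2), x$df, x$n_segments, x$dof,
    if (!is.null(x$condition)) paste0(", condition ", x$condition) else ""))
  invisible(x)
}

#' @rdname cross_bispectrum
#' @param x A `bispectrum_estimate`.
#' @param ... Unused.
#' @export
tidy.bispectrum_estimate <- function(x, ...) {
  grid <- expand.grid(i = seq_along(x$f1), j = seq_along(x$f2))
  tibble(
    f1 = x$f1[grid$i], f2 = x$f2[grid$j],
    bicoherence = Mod(x$b)[cbind(grid$i, grid$j)],
    biphase = Arg(x$b)[cbind(grid$i, grid$j)],
    skewness_part = Re(x$b)[cbind(grid$i, grid$j)],
    asymmetry_part = Im(x$b)[cbind(grid$i, grid$j)],
    in_principal_domain = x$mask[cbind(grid$i, grid$j)]
  )
}

#' @rdname cross_bispectrum
#' @export
glance.bispectrum_estimate <- function(x, ...) {
  bmax <- suppressWarnings(max(Mod(x$b)[x$mask], na.rm = TRUE))
  tibble(kind = x$kind, arrangement = paste(x$arrangement, collapse = "-"),
         n_segments = x$n_segments, dof = x$dof, df = x$df,
         max_bicoherence = bmax,
         significance_05 = significance_threshold(max(2, round(x$dof)),
                                                  n_reps = 500))
}
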