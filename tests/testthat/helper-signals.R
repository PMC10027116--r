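# Fixture builders shared across test files. All fixtures are generated in
# code under fixed seeds; nothing binary is stored.

# segment_set from a K x N matrix
seg_set <- function(mat, fs, overlap = 0, region = NULL, condition = NULL) {
  bicoh:::new_segment_set(mat, fs = fs, overlap = overlap,
                          starts = (seq_len(nrow(mat)) - 1) *
                            ncol(mat) / fs * (1 - overlap),
                          condition = condition, region = region)
}

# Frequency triad: components at f1, f2 and f1+f2 with per-segment random
# phases. coupled: sum component phase = phi1 + phi2 (quadratic phase
# coupling); otherwise an independent random phase.
make_triad_segments <- function(K, N = 256, fs = 256, freqs = c(20, 31),
                                coupled = TRUE, noise = 0, seed = 1) {
  withr::with_seed(seed, {
    t <- (0:(N - 1)) / fs
    mat <- t(vapply(seq_len(K), function(k) {
      p1 <- runif(1, 0, 2 * pi)
      p2 <- runif(1, 0, 2 * pi)
      p3 <- if (coupled) p1 + p2 else runif(1, 0, 2 * pi)
      cos(2 * pi * freqs[1] * t + p1) + cos(2 * pi * freqs[2] * t + p2) +
        cos(2 * pi * sum(freqs) * t + p3) + noise * rnorm(N)
    }, numeric(N)))
    seg_set(mat, fs)
  })
}

make_noise_segments <- function(K, N = 256, fs = 256, seed = 1) {
  withr::with_seed(seed, seg_set(matrix(rnorm(K * N), K, N), fs))
}

# Phase-shuffled surrogate: keep each segment's spectral magnitudes, draw
# fresh uniform phases (Hermitian-symmetrized), destroying cross-frequency
# phase relations.
phase_shuffle_segments <- function(ss, seed = 1) {
  withr::with_seed(seed, {
    N <- ss$window_samples
    M <- N %/% 2
    shuf <- t(apply(ss$segments, 1, function(x) {
      X <- fft(x - mean(x))
      ph <- runif(M - 1, 0, 2 * pi)
      Y <- complex(length.out = N)
      Y[1] <- 0
      Y[2:M] <- Mod(X[2:M]) * exp(1i * ph)
      Y[M + 1] <- Mod(X[M + 1])
      Y[(M + 2):N] <- Conj(Y[M:2])
      Re(fft(Y, inverse = TRUE)) / N
    }))
    out <- ss
    out$segments <- shuf
    out
  })
}

# Brute-force full-plane cross-bispectrum oracle: direct triple products on
# raw DFT indices (mod N), independent of the package's plane layout.
brute_force_bispectrum <- function(P, Q, R, m, n) {
  N <- ncol(P)
  idx <- function(v) (v %% N) + 1L
  mean(P[, idx(m)] * Q[, idx(n)] * Conj(R[, idx(m + n)]))
}

# Whole-record phase randomization (Theiler surrogate): preserves the
# record's overall spectrum but destroys time-localized envelope structure,
# so windowed power co-fluctuations vanish.
phase_shuffle_record <- function(x, seed = 1) {
  withr::with_seed(seed, {
    N <- length(x)
    M <- N %/% 2
    X <- fft(x - mean(x))
    ph <- runif(M - 1, 0, 2 * pi)
    Y <- complex(length.out = N)
    Y[1] <- 0
    Y[2:M] <- Mod(X[2:M]) * exp(1i * ph)
    Y[M + 1] <- Mod(X[M + 1])
    if (N %% 2 == 0) Y[(M + 2):N] <- Conj(Y[M:2]) else Y[(M + 2):N] <- Conj(Y[(M + 1):2])
    Re(fft(Y, inverse = TRUE)) / N
  })
}

# Von Mises sampler (Best & Fisher rejection), degrees.
circ_vm_sample <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      i <- i + 1L
      out[i] <- sign(u[3] - 0.5) * acos(f)
    }
  }
  (mu + out * 180 / pi) %% 360
}

# Cached synthetic sessions so several test files can share one simulation.
.session_cache <- new.env(parent = emptyenv())

cached_session <- function(key, spec, seed) {
  if (is.null(.session_cache[[key]])) {
    .session_cache[[key]] <- simulate_session(spec, seed = seed)
  }
  .session_cache[[key]]
}

base_session <- function() {
  cached_session("base", generator_spec(duration = 120), seed = 42)
}

high_bin_segments <- function(session, region = "H") {
  segs <- segment_by_speed(session$lfp, session$trajectory)
  segs$segments[[which(segs$bin == "high" & segs$region == region)]]
}
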