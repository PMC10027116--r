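test_that("the bispectrum of Gaussian noise vanishes with ensemble size", {
  est_small <- cross_bispectrum(make_noise_segments(10, seed = 1))
  est_big <- cross_bispectrum(make_noise_segments(400, N = 128, seed = 2))
  m_big <- mean(Mod(est_big$b)[est_big$mask & est_big$f1 > 0], na.rm = TRUE)
  m_small <- mean(Mod(est_small$b)[est_small$mask & est_small$f1 > 0], na.rm = TRUE)
  expect_lt(m_big, m_small)           # shrinks as K grows
  expect_lt(m_big, 3 / sqrt(400))     # O(1/sqrt(K)) level
})

test_that("a phase-coupled triad saturates bicoherence; a random-phase triad does not", {
  ss <- make_triad_segments(50, coupled = TRUE, seed = 3)
  est <- cross_bispectrum(ss)
  i <- which(est$f1 == 20); j <- which(est$f2 == 31)
  expect_gte(Mod(est$b[i, j]), 0.99)
  # direct triple-product oracle on a single segment
  one <- seg_set(ss$segments[1, , drop = FALSE], fs = ss$fs)
  est1 <- cross_bispectrum(one)
  P <- fft(ss$segments[1, ] - mean(ss$segments[1, ]))
  expect_equal(est1$B[i, j], P[21] * P[32] * Conj(P[52]), tolerance = 1e-8)
  # independent sum-component phase: |b| at the O(1/sqrt(K)) noise level
  ss0 <- make_triad_segments(64, coupled = FALSE, seed = 4)
  est0 <- cross_bispectrum(ss0)
  expect_lt(Mod(est0$b[i, j]), 4 / sqrt(64))
})

test_that("the normalization bounds |b| by 1 for every signal type in the battery", {
  battery <- list(
    make_noise_segments(12, seed = 5),
    make_triad_segments(12, coupled = TRUE, seed = 6),
    make_triad_segments(12, coupled = FALSE, seed = 7),
    make_triad_segments(12, coupled = TRUE, noise = 2, seed = 8)
  )
  t <- (0:255) / 256
  withr::with_seed(9, {
    battery <- c(battery, list(
      # sawtooth-skewed 8 Hz wave
      seg_set(t(replicate(12, {
        ph <- runif(1, 0, 2 * pi)
        rowSums(sapply(1:4, function(k) cos(2 * pi * 8 * k * t + k * ph) / k))
      })), fs = 256),
      # chirp
      seg_set(t(replicate(12, cos(2 * pi * (20 + 40 * t) * t + runif(1, 0, 6)))),
              fs = 256),
      # square wave
      seg_set(t(replicate(12, sign(sin(2 * pi * 10 * t + runif(1, 0, 6))))), fs = 256),
      # impulse train
      seg_set(t(replicate(12, as.numeric((0:255) %% 32 == sample(0:31, 1)))), fs = 256),
      # AM carrier
      seg_set(t(replicate(12, (1 + 0.8 * cos(2 * pi * 8 * t + runif(1, 0, 6))) *
                            cos(2 * pi * 60 * t + runif(1, 0, 6)))), fs = 256),
      # 1/f-shaped noise
      seg_set(t(replicate(12, bicoh:::one_over_f(256, 256, 1.5))), fs = 256)
    ))
  })
  for (k in seq_along(battery)) {
    est <- cross_bispectrum(battery[[k]])
    v <- Mod(est$b)
    v <- v[is.finite(v)]  # an all-masked plane (no valid triads) is vacuous
    expect_lte(if (length(v)) max(v) else 0, 1 + 1e-9,
               label = sprintf("battery signal %d max |b|", k))
  }
})

test_that("bicoherence is invariant to amplitude rescaling of the input", {
  ss <- make_triad_segments(20, noise = 1, seed = 10)
  est1 <- cross_bispectrum(ss)
  est2 <- cross_bispectrum(seg_set(7.3 * ss$segments, fs = ss$fs))
  expect_equal(est2$b, est1$b, tolerance = 1e-10)
})

test_that("principal domains are octant 1 (auto) and octants 1+8 (ppq cross)", {
  pd_auto <- principal_domain("auto", n = 64, fs = 64)
  pd_cross <- principal_domain("cross_ppq", n = 64, fs = 64)
  F1 <- matrix(pd_auto$f1, length(pd_auto$f1), length(pd_auto$f2))
  F2 <- matrix(pd_auto$f2, length(pd_auto$f1), length(pd_auto$f2), byrow = TRUE)
  expect_equal(pd_auto$mask, F2 >= 0 & F2 <= F1 & (F1 + F2) <= 32)
  expect_equal(pd_cross$mask, abs(F2) <= F1 & (F1 + F2) <= 32 & (F1 + F2) >= 0)
})

test_that("full-plane brute force equals the principal-domain estimate through the symmetries", {
  # ppq cross arrangement on a 64-point grid
  K <- 8; N <- 64; M <- N %/% 2
  withr::with_seed(11, {
    p <- matrix(rnorm(K * N), K, N)
    r <- matrix(rnorm(K * N), K, N)
  })
  ssp <- seg_set(p, fs = N); ssr <- seg_set(r, fs = N)
  est <- cross_bispectrum(ssp, ssp, ssr)
  P <- t(mvfft(t(p - rowMeans(p))))
  R <- t(mvfft(t(r - rowMeans(r))))
  # map any (m, n) to its principal representative in octants 1 or 8:
  # swap to put the larger magnitude first, negate (conjugating) if needed
  worst <- 0
  for (m in -M:M) for (n in -M:M) {
    if (abs(m + n) > M) next
    full <- brute_force_bispectrum(P, P, R, m, n)
    rep_ <- if (abs(m) >= abs(n)) c(m, n) else c(n, m)
    conj_flag <- rep_[1] < 0
    if (conj_flag) rep_ <- -rep_
    i <- which(est$f1 == rep_[1]); j <- which(est$f2 == rep_[2])
    impl <- est$B[i, j]
    if (conj_flag) impl <- Conj(impl)
    worst <- max(worst, Mod(full - impl))
  }
  expect_lt(worst, 1e-10)
  # auto-only extra symmetry B(m,-n) = Conj(B(m-n, n))
  est_a <- cross_bispectrum(ssp)
  for (m in 5:20) for (n in 1:4) {
    i1 <- which(est_a$f1 == m); j1 <- which(est_a$f2 == -n)
    i2 <- which(est_a$f1 == m - n); j2 <- which(est_a$f2 == n)
    expect_equal(est_a$B[i1, j1], Conj(est_a$B[i2, j2]), tolerance = 1e-10)
  }
})

test_that("time reversal negates the asymmetry part and preserves the skewness part", {
  # skewed + asymmetric 8 Hz wave: harmonics at mixed phase offsets
  N <- 250; fs <- 250; K <- 24
  t <- (0:(N - 1)) / fs
  mk <- function(rev = FALSE, flip = FALSE) {
    withr::with_seed(12, {
      m <- t(replicate(K, {
        ph <- runif(1, 0, 2 * pi)
        cos(2 * pi * 8 * t + ph) + 0.5 * cos(2 * pi * 16 * t + 2 * ph + pi / 4)
      }))
    })
    if (rev) m <- m[, N:1]
    if (flip) m <- -m
    seg_set(m, fs)
  }
  fwd <- cross_bispectrum(mk())
  bwd <- cross_bispectrum(mk(rev = TRUE))
  i <- which(fwd$f1 == 8); j <- which(fwd$f2 == 8)
  expect_equal(Re(bwd$b[i, j]), Re(fwd$b[i, j]), tolerance = 1e-6)
  expect_equal(Im(bwd$b[i, j]), -Im(fwd$b[i, j]), tolerance = 1e-6)
  # sign flip negates the whole third-order statistic
  neg <- cross_bispectrum(mk(flip = TRUE))
  expect_equal(neg$b[i, j], -fwd$b[i, j], tolerance = 1e-6)
  # decomposition only exists for the auto case
  other <- make_noise_segments(24, N = 250, fs = 250, seed = 13)
  crossed <- cross_bispectrum(mk(), mk(), other)
  expect_error(skewness_asymmetry_decomposition(crossed), "auto")
  dec <- skewness_asymmetry_decomposition(fwd)
  expect_true(all(c("skewness_part", "asymmetry_part") %in% names(dec)))
})

test_that("a sawtooth-skewed theta wave has positive skewness-related bicoherence at (8, 8)", {
  ses <- base_session()
  est <- cross_bispectrum(high_bin_segments(ses, "H"), max_freq = 40)
  i <- which(est$f1 == 8); j <- which(est$f2 == 8)
  # in-phase harmonics: peaky (positively skewed) wave, near-zero asymmetry
  expect_gt(Re(est$b[i, j]), 0.5)
  expect_lt(abs(Im(est$b[i, j])), Re(est$b[i, j]) / 3)
  # matches the direct third-moment sign of the waveform
  hseg <- high_bin_segments(ses, "H")$segments
  skew <- mean(apply(hseg, 1, function(s) mean(((s - mean(s)) / sd(s))^3)))
  expect_gt(skew, 0)
})

test_that("the Monte-Carlo null threshold is deterministic per seed and scales as 1/sqrt(dof)", {
  t1 <- significance_threshold(100, n_reps = 400, seed = 7)
  t2 <- significance_threshold(100, n_reps = 400, seed = 7)
  expect_identical(t1, t2)
  t25 <- significance_threshold(25, n_reps = 400, seed = 7)
  t400 <- significance_threshold(400, n_reps = 400, seed = 7)
  expect_equal(t25 / t1, 2, tolerance = 0.2)
  expect_equal(t1 / t400, 2, tolerance = 0.2)
  expect_error(significance_threshold(1), ">= 2")
})

test_that("ROI membership follows the stated geometry with half-open edges", {
  roi_tt <- coupling_roi("theta_theta")
  roi_sum <- coupling_roi("theta_gamma_sum")
  roi_diff <- coupling_roi("theta_gamma_diff")
  roi_gg <- coupling_roi("theta_gamma_gg")
  member <- function(roi, f1, f2) bicoh:::roi_member(roi, f1, f2)
  expect_true(member(roi_tt, 20, 10))
  expect_false(member(roi_tt, 30, 10))      # sum edge 40 is out (half-open)
  expect_false(member(roi_tt, 10, 3))       # below the theta band
  expect_true(member(roi_sum, 84, 8))
  expect_true(member(roi_sum, 42, 4))       # lower edges in
  expect_false(member(roi_sum, 100, 8))     # upper edge out
  expect_true(member(roi_diff, 84, -8))
  expect_false(member(roi_diff, 84, 8))
  expect_true(member(roi_gg, 84, -76))      # 84 - 76 = 8 Hz theta
  expect_false(member(roi_gg, 90, -44))     # difference 46 Hz falls above theta
  expect_false(member(roi_gg, 84, -20))     # |f2| below the gamma band
})

test_that("ROI sums are zero for a zero field and error for an empty ROI", {
  est <- cross_bispectrum(make_noise_segments(8, N = 128, fs = 128, seed = 14))
  est$b[] <- 0 + 0i
  out <- roi_coupling_strength(est, coupling_roi("theta_theta"))
  expect_equal(out$strength, 0)
  expect_gt(out$n_bins, 0)
  # a gamma ROI cannot fit a 16 Hz Nyquist grid
  tiny <- cross_bispectrum(make_noise_segments(8, N = 32, fs = 32, seed = 15))
  expect_error(roi_coupling_strength(tiny, coupling_roi("gamma_gamma")), "no bins")
})

test_that("triad enumeration yields two families with six theta-gamma regions per pair", {
  tri <- enumerate_triads(c("H", "T"))
  expect_equal(nrow(tri), 8L)
  expect_equal(sum(grepl("theta_gamma", tri$triad)), 6L)
  expect_setequal(unique(tri$arrangement), c("H-H-T", "T-T-H"))
  expect_equal(sum(tri$triad == "theta_theta"), 2L)
  auto <- enumerate_triads(c("A", "A"))
  expect_equal(auto$arrangement, rep("A-A-A", 3))
  expect_setequal(auto$triad, c("theta_theta", "theta_gamma_sum", "gamma_gamma"))
})

test_that("cross-regional gamma-envelope locking lights up its triad and not the uncoupled one", {
  # only the T-region gamma envelope is locked to the (shared) theta phase
  ses <- cached_session("tonly",
                        generator_spec(duration = 120,
                                       gamma = list(H = list(coupling = 0),
                                                    T = list(coupling = 0.7))),
                        seed = 61)
  ssH <- high_bin_segments(ses, "H"); ssT <- high_bin_segments(ses, "T")
  est_tth <- cross_bispectrum(ssT, ssT, ssH, max_freq = 110)
  est_hht <- cross_bispectrum(ssH, ssH, ssT, max_freq = 110)
  thr <- significance_threshold(round(est_tth$dof), n_reps = 500, seed = 3)
  coupled <- roi_coupling_strength(est_tth, coupling_roi("theta_gamma_gg"))
  uncoupled <- roi_coupling_strength(est_hht, coupling_roi("theta_gamma_sum"))
  expect_gt(coupled$strength / coupled$n_bins, uncoupled$strength / uncoupled$n_bins)
  expect_lt(uncoupled$strength / uncoupled$n_bins, 1.5 * thr)
})

test_that("phase-shuffled surrogates fall back to the null coupling level", {
  ses <- base_session()
  ssH <- high_bin_segments(ses, "H")
  est <- cross_bispectrum(ssH, max_freq = 110)
  surr <- cross_bispectrum(phase_shuffle_segments(ssH, seed = 16), max_freq = 110)
  roi <- coupling_roi("theta_gamma_sum")
  orig <- roi_coupling_strength(est, roi)
  null <- roi_coupling_strength(surr, roi)
  thr <- significance_threshold(round(est$dof), n_reps = 500, seed = 3)
  expect_gt(orig$strength, null$strength)
  expect_lt(null$strength / null$n_bins, 1.3 * thr)
})

test_that("coupling_by_speed masks under-populated bins and reports all triads", {
  ses <- base_session()
  bins <- speed_bins(labels = c("low", "high", "vhigh"),
                     lower = c(1, 15, 40), upper = c(9, Inf, Inf))
  out <- coupling_by_speed(ses$lfp, ses$trajectory, bins,
                           pairs = list(c("H", "T")), max_freq = 110)
  expect_true(all(out$masked[out$bin == "vhigh"]))
  expect_true(grepl("segments", out$reason[out$bin == "vhigh"][1]))
  ok <- dplyr::filter(out, bin != "vhigh")
  expect_false(any(ok$masked))
  expect_equal(sort(unique(ok$triad)),
               sort(unique(enumerate_triads(c("H", "T"))$triad)))
  # speed-coupled generator: theta-theta coupling grows from low to high
  tt <- dplyr::filter(ok, triad == "theta_theta", arrangement == "H-H-T")
  expect_gt(tt$strength[tt$bin == "high"], tt$strength[tt$bin == "low"])
})
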