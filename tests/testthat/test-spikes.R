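test_that("binarization maps spikes to nearest samples and drops out-of-span spikes", {
  expect_equal(sum(binarize_spike_train(numeric(0), span = c(0, 1))), 0L)
  spikes <- c(0.1, 0.2, 0.3, 0.9)
  out <- binarize_spike_train(spikes, span = c(0, 1), fs = 1250)
  expect_equal(sum(out), 4L)
  expect_equal(out[round(0.2 * 1250) + 1], 1L)
  expect_message(binarize_spike_train(c(0.5, 2.5), span = c(0, 1), fs = 1250),
                 "outside the span")
})

test_that("a theta-locked Poisson train shows a spike-train PSD peak at 8 Hz", {
  fs <- 1250; dur <- 60
  t <- (0:(dur * fs - 1)) / fs
  withr::with_seed(1, {
    rate <- 10 * (1 + 0.8 * cos(2 * pi * 8 * t))
    spikes <- t[runif(length(t)) < rate / fs]
  })
  binary <- binarize_spike_train(spikes, span = c(0, dur), fs = fs)
  ss <- seg_set(matrix(binary, nrow = dur, byrow = TRUE), fs = fs)
  est <- cross_spectrum(ss)
  band <- est$values[est$frequency >= 4 & est$frequency <= 100]
  f_band <- est$frequency[est$frequency >= 4 & est$frequency <= 100]
  expect_equal(f_band[which.max(band)], 8)
})

test_that("tuning curves are occupancy normalized", {
  # uniform occupancy, uniform spikes: flat curve
  series <- tibble::tibble(time = (0:35999) / 100,
                           angle = rep(seq(6, 354, by = 12), each = 1200))
  spikes <- series$time[seq(1, 36000, by = 100)]
  prof <- tuning_curve(spikes, series, bin_width = 12)
  expect_equal(nrow(prof$bins), 30L)
  expect_true(all(abs(prof$bins$rate - mean(prof$bins$rate)) < 1e-9))
  # doubling occupancy in one bin at equal counts halves its rate
  series2 <- tibble::tibble(
    time = (0:(1200 * 31 - 1)) / 100,
    angle = rep(c(seq(6, 354, by = 12), 6), each = 1200))  # first bin twice
  n_spk <- 5
  spk2 <- unlist(lapply(seq(6, 354, by = 12), function(a) {
    series2$time[which(series2$angle == a)[seq_len(n_spk)]]
  }))
  prof2 <- tuning_curve(spk2, series2, bin_width = 12)
  expect_equal(prof2$bins$rate[1] * 2, prof2$bins$rate[2], tolerance = 1e-9)
})

test_that("modulation depth follows (max - min)/max", {
  fake <- function(rates) {
    structure(list(bins = tibble::tibble(
      bin_center = seq_along(rates), occupancy = 1,
      count = rates, rate = rates),
      bin_width = 12, variable = "x", n_spikes = sum(rates),
      mean_rate = mean(rates), spike_angles = numeric(0)),
      class = "modulation_profile")
  }
  expect_equal(modulation_depth(fake(rep(4, 30))), 0)
  expect_equal(modulation_depth(fake(c(10, 2, 5))), 0.8)
  expect_equal(modulation_depth(fake(c(10, 0, 5))), 1)
  expect_error(modulation_depth(fake(rep(0, 30))), "undefined")
})

test_that("the Rayleigh test is calibrated under the null and powerful under von Mises tuning", {
  expect_lt(rayleigh_test(rep(90, 50))$p, 1e-10)
  withr::with_seed(2, {
    null_p <- replicate(200, rayleigh_test(runif(50, 0, 360))$p)
  })
  ks <- suppressWarnings(stats::ks.test(null_p, "punif"))
  expect_gt(ks$p.value, 0.01)
  withr::with_seed(3, {
    vm <- replicate(50, {
      ang <- circ_vm_sample(200, mu = 120, kappa = 1)
      rayleigh_test(ang)$p < 0.05
    })
  })
  expect_gt(mean(vm), 0.9)
  expect_true(is.na(rayleigh_test(90)$p))
})

test_that("the concentration estimator recovers kappa and is monotone in narrowness", {
  withr::with_seed(4, {
    expect_lt(concentration(runif(2000, 0, 360)), 0.1)
    expect_equal(concentration(circ_vm_sample(1000, 0, 2)), 2, tolerance = 0.2)
    k_narrow <- concentration(circ_vm_sample(1000, 0, 6))
    k_wide <- concentration(circ_vm_sample(1000, 0, 1))
    expect_gt(k_narrow, k_wide)
  })
  # degenerate profile: capped, not infinite
  series <- tibble::tibble(time = (0:999) / 100, angle = runif(1000, 0, 360))
  prof <- tuning_curve(rep(0.05, 3), dplyr::mutate(series, angle = 5), 12)
  expect_lte(concentration(prof), 500)
})

test_that("a von Mises-tuned cell peaks at its preferred direction within one bin", {
  fs <- 100; dur <- 600
  withr::with_seed(5, {
    hd <- (cumsum(rnorm(dur * fs, 0, 2)) %% 360)
    series <- tibble::tibble(time = (0:(dur * fs - 1)) / fs, angle = hd)
    rate <- 8 * exp(2 * cos((hd - 90) * pi / 180)) / besselI(2, 0)
    spikes <- series$time[runif(dur * fs) < rate / fs]
  })
  prof <- tuning_curve(spikes, series, bin_width = 12, variable = "head_direction")
  peak <- prof$bins$bin_center[which.max(prof$bins$rate)]
  expect_lt(min(abs(c(peak - 90, peak - 90 + 360, peak - 90 - 360))), 13)
  expect_gt(concentration(prof), 1)
})

test_that("classification enforces the printed thresholds strictly", {
  vm_prof <- function(n = 400, kappa = 2, depth_rates = NULL, seed = 6) {
    withr::with_seed(seed, {
      ang <- circ_vm_sample(n, 180, kappa)
      series <- tibble::tibble(time = seq_len(72000) / 100,
                               angle = rep(seq(6, 354, by = 12), each = 2400))
      prof <- tuning_curve(numeric(0), series, 12)
      prof$spike_angles <- ang
      prof$n_spikes <- n
      prof$mean_rate <- 5
      if (is.null(depth_rates)) {
        prof$bins$rate <- 5 * exp(kappa * cos((prof$bins$bin_center - 180) * pi / 180))
      } else {
        prof$bins$rate <- depth_rates
      }
      prof
    })
  }
  flat_prof <- vm_prof(400, 0.01, rep(5, 30), seed = 7)
  # untuned cell -> other
  expect_equal(classify_cell(flat_prof, flat_prof)$class, "other")
  # HD-tuned: concentrated directional rates with significant Rayleigh
  hd <- vm_prof(400, 2)
  expect_equal(classify_cell(hd, flat_prof)$class, "HD")
  # theta boundary: significant phase nonuniformity but depth 0.09 fails;
  # depth exactly 0.10 passes ("at least 0.1")
  depth09 <- vm_prof(400, 2, depth_rates = c(10, rep(9.1, 29)))
  depth10 <- vm_prof(400, 2, depth_rates = c(10, rep(9.0, 29)))
  expect_equal(classify_cell(flat_prof, depth09)$class, "other")
  expect_equal(classify_cell(flat_prof, depth10)$class, "theta")
  # HD kappa boundary: significant but weakly concentrated rates fail
  weak <- vm_prof(400, 2)
  weak$bins$rate <- 5 * (1 + 0.3 * cos((weak$bins$bin_center - 180) * pi / 180))
  expect_lt(concentration(weak), 1)
  expect_equal(classify_cell(weak, flat_prof)$class, "other")
  # double qualifier follows the precedence flag
  both <- classify_cell(hd, depth10)
  expect_equal(both$class, "HD")
  expect_equal(classify_cell(hd, depth10, precedence = "theta")$class, "theta")
})

test_that("per-cell spike spectra are normalized to unit band mean; Poisson cells are flat", {
  ses <- base_session()
  ids <- unique(ses$spikes$cell_id)
  theta_ids <- ses$truth$cell_id[ses$truth$class == "theta"][1:4]
  other_ids <- ses$truth$cell_id[ses$truth$class == "other"][1:4]
  sp <- suppressMessages(
    spike_psd_by_speed(dplyr::filter(ses$spikes, cell_id %in% c(theta_ids, other_ids)),
                       ses$trajectory))
  # normalization identity: mean over the band is 1 for every cell and bin
  norm <- sp |>
    dplyr::group_by(cell_id, bin) |>
    dplyr::summarise(m = mean(power), .groups = "drop")
  expect_true(all(abs(norm$m - 1) < 1e-10))
  # theta cells: population peak near 8 Hz, above the 12-30 Hz floor
  th <- dplyr::filter(sp, cell_id %in% theta_ids)
  peak <- mean(th$power[th$frequency >= 7 & th$frequency <= 9])
  floor_ <- mean(th$power[th$frequency >= 12 & th$frequency <= 30])
  expect_gt(peak, floor_ * 1.05)
  # untuned Poisson cells: flat within sampling error
  ot <- dplyr::filter(sp, cell_id %in% other_ids, bin == "high")
  expect_lt(sd(ot$power) / mean(ot$power), 0.25)
})

test_that("the generator's depth-rate anticorrelation is recovered", {
  ses <- base_session()
  phase <- theta_phase(dplyr::filter(ses$lfp, region == "H"))
  cls <- classify_cells(ses$spikes, ses$trajectory, phase)
  hd <- dplyr::filter(cls, class == "HD")
  expect_lt(stats::cor(hd$mean_rate, hd$hd_depth), 0)
})
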