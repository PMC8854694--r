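test_that("pixel binning sums blocks, scales pixel size and conserves photons", {
  set.seed(4)
  decay <- array(rpois(11 * 13 * 16, 5), dim = c(11, 13, 16))
  st <- flim_stack(decay, pixel_size_nm = 135)
  expect_identical(bin_pixels(st, 1)$decay, st$decay)
  b5 <- bin_pixels(st, 5)
  expect_equal(dim(b5$decay), c(2, 2, 16))
  expect_equal(b5$pixel_size_nm, 675)
  # conservation over the retained area
  kept <- st$decay[1:10, 1:10, , drop = FALSE]
  expect_equal(sum(b5$decay), sum(kept))
  # explicit block check
  expect_equal(b5$decay[1, 2, 7], sum(st$decay[1:5, 6:10, 7]))
  # padding keeps all photons
  bp <- bin_pixels(st, 5, pad = TRUE)
  expect_equal(sum(bp$decay), sum(st$decay))
  expect_error(bin_pixels(st, 20), "exceeds")
})

test_that("background thresholding removes exactly the low-count pixels", {
  decay <- array(0, dim = c(4, 4, 16))
  decay[1, 1, ] <- 2   # 32 counts
  decay[2, 2, ] <- 1   # 16 counts
  st <- flim_stack(decay)
  thr0 <- threshold_background(st, 0)
  expect_true(all(thr0$mask))
  thr <- threshold_background(st, 25)
  expect_true(thr$mask[1, 1])
  expect_false(thr$mask[2, 2])
  expect_equal(sum(thr$mask), 1)
  # uniform 30-count image removed entirely at threshold 50
  st30 <- flim_stack(array(30 / 16, dim = c(3, 3, 16)))
  expect_equal(sum(threshold_background(st30, 50)$mask), 0)
})

test_that("phasor of a mono-exponential matches the closed form", {
  for (tau in c(0.5, 2.8, 4.0, 4.83, 7.0)) {
    st <- noiseless_stack(tau, ny = 2, nx = 2)
    ph <- phasor_transform(st)
    ideal <- phasor_mono(tau)
    expect_equal(ph$G[1, 1], unname(ideal["G"]), tolerance = 5e-3)
    expect_equal(ph$S[1, 1], unname(ideal["S"]), tolerance = 5e-3)
  }
  # delta-like decay (tau -> 0): all counts in the first bin -> (G,S) ~ (1,0)
  decay <- array(0, dim = c(2, 2, 512)); decay[, , 1] <- 1000
  ph0 <- phasor_transform(flim_stack(decay))
  expect_equal(ph0$G[1, 1], 1, tolerance = 1e-3)
  expect_equal(ph0$S[1, 1], 0, tolerance = 1e-2)
  # tau -> infinity: flat decay -> (G,S) ~ (0,0)
  phf <- phasor_transform(flim_stack(array(10, dim = c(2, 2, 512))))
  expect_equal(phf$G[1, 1], 0, tolerance = 1e-12)
  expect_equal(phf$S[1, 1], 0, tolerance = 1e-12)
})

test_that("a two-component mixture lies on the segment between component phasors", {
  rep_rate <- 20e6; n_bins <- 512
  f1 <- epiquant:::decay_bin_fractions(2e-9, rep_rate, n_bins)
  f2 <- epiquant:::decay_bin_fractions(5e-9, rep_rate, n_bins)
  for (w in c(0.25, 0.5, 0.8)) {
    mix <- 1e6 * (w * f1 + (1 - w) * f2)
    decay <- array(rep(mix, each = 1), dim = c(1, 1, n_bins))
    phm <- phasor_transform(flim_stack(decay))
    ph1 <- phasor_transform(flim_stack(array(1e6 * f1, dim = c(1, 1, n_bins))))
    ph2 <- phasor_transform(flim_stack(array(1e6 * f2, dim = c(1, 1, n_bins))))
    # intensity-weighted linear combination (equal total intensities here)
    expect_equal(phm$G[1, 1], w * ph1$G[1, 1] + (1 - w) * ph2$G[1, 1],
                 tolerance = 1e-10)
    expect_equal(phm$S[1, 1], w * ph1$S[1, 1] + (1 - w) * ph2$S[1, 1],
                 tolerance = 1e-10)
  }
})

test_that("phasors of simulated physical decays stay within the universal semicircle", {
  sim <- generate_flim_stack(flim_sim_config(
    image_shape = c(12, 12),
    regions = list(list(polygon = data.frame(x = c(0, 11, 11, 0),
                                             y = c(0, 0, 11, 11)),
                        tau_ns = 4)),
    photons_per_pixel_mean = 5000, background_count_level = 0, seed = 8
  ))
  ph <- phasor_transform(threshold_background(sim$stack, 50))
  r2 <- (ph$G - 0.5)^2 + ph$S^2
  expect_true(all(r2[!is.na(r2)] <= 0.25 + 0.02))
  expect_true(all(ph$S[!is.na(ph$S)] >= -0.02))
})

test_that("an unmasked zero-count pixel is an error, a masked one is NA", {
  decay <- array(5, dim = c(3, 3, 16))
  decay[2, 2, ] <- 0
  st <- flim_stack(decay)
  expect_error(phasor_transform(st), "zero total counts")
  thr <- threshold_background(st, 10)
  ph <- phasor_transform(thr)
  expect_true(is.na(ph$G[2, 2]))
  expect_false(anyNA(ph$G[-5]))
})

test_that("median filtering replaces outliers and respects undefined pixels", {
  ph_const <- phasor_transform(noiseless_stack(4, ny = 7, nx = 7))
  expect_equal(median_filter_phasor(ph_const, 1), ph_const)
  filt <- median_filter_phasor(ph_const, 5)
  expect_equal(filt$G, ph_const$G, tolerance = 1e-12)
  # single outlier in a constant patch is replaced by the constant
  ph <- ph_const
  g0 <- ph$G[1, 1]
  ph$G[4, 4] <- g0 + 0.3
  filt <- median_filter_phasor(ph, 5)
  expect_equal(filt$G[4, 4], g0, tolerance = 1e-12)
  # undefined pixels stay undefined and do not poison neighbours
  ph$G[2, 2] <- NA
  filt2 <- median_filter_phasor(ph, 5)
  expect_true(is.na(filt2$G[2, 2]))
  expect_false(anyNA(filt2$G[-(7 * 1 + 2)]))
  expect_error(median_filter_phasor(ph_const, 4), "odd")
})

test_that("phase lifetime round-trips noiseless decays within 0.5%", {
  for (tau in c(0.5, 2.8, 4.0, 4.83, 7.0)) {
    lt <- lifetime_map(phasor_transform(noiseless_stack(tau)))
    expect_equal(lt$tau_ns[1, 1], tau, tolerance = 5e-3)
  }
  # (G,S) = (1,0) maps to tau = 0
  decay <- array(0, dim = c(1, 1, 512)); decay[1, 1, 1] <- 100
  lt0 <- lifetime_map(phasor_transform(flim_stack(decay)))
  expect_lt(lt0$tau_ns[1, 1], 0.05)
})

test_that("modulation lifetime agrees with phase lifetime on mono-exponentials", {
  lt_p <- lifetime_map(phasor_transform(noiseless_stack(4.83)), "phase")
  lt_m <- lifetime_map(phasor_transform(noiseless_stack(4.83)), "modulation")
  expect_equal(lt_m$tau_ns[1, 1], lt_p$tau_ns[1, 1], tolerance = 1e-2)
})

test_that("single-reference calibration corrects an instrument timing offset", {
  # an instrument delay = circular shift of the decay bins rotates every
  # phasor by the same complex factor; calibrating with a known-lifetime
  # standard measured under the same delay must undo it
  shift_stack <- function(st, m) {
    nb <- st$n_bins
    idx <- ((seq_len(nb) - 1 + m) %% nb) + 1
    flim_stack(st$decay[, , idx, drop = FALSE], rep_rate = st$rep_rate)
  }
  standard <- shift_stack(noiseless_stack(4.0), 40)
  sample_st <- shift_stack(noiseless_stack(2.8), 40)
  measured <- phasor_transform(standard)
  cal <- list(tau_ns = 4.0, measured = c(measured$G[1, 1], measured$S[1, 1]))
  lt <- lifetime_map(phasor_transform(sample_st, calibration = cal))
  expect_equal(lt$tau_ns[1, 1], 2.8, tolerance = 5e-3)
  # without calibration the delayed measurement is badly biased
  lt_raw <- lifetime_map(phasor_transform(sample_st))
  expect_gt(abs(lt_raw$tau_ns[1, 1] - 2.8), 0.5)
})

test_that("ROI means honour the tension-sensitive window and polygon membership", {
  tau <- matrix(4.83, 6, 6)
  lt <- structure(list(tau_ns = tau, intensity = matrix(100, 6, 6),
                       pixel_size_nm = 675, estimator = "phase"),
                  class = "lifetime_image")
  roi <- list(patch = data.frame(x = c(0, 5, 5, 0), y = c(0, 0, 5, 5)))
  res <- roi_mean_lifetime(lt, roi)
  expect_equal(res$mean_ns, 4.83)
  expect_equal(res$sd_ns, 0)
  expect_equal(res$n_pixels, 36)

  # window filter: {2, 4, 8} ns -> only 4 ns eligible
  lt$tau_ns[1, 1:3] <- c(2, 4, 8)
  roi_row <- list(r = data.frame(x = c(-0.5, 2.5, 2.5, -0.5),
                                 y = c(-0.5, -0.5, 0.5, 0.5)))
  res2 <- roi_mean_lifetime(lt, roi_row, window = c(2.8, 7))
  expect_equal(res2$mean_ns, 4)
  expect_equal(res2$n_pixels, 1)
  expect_equal(res2$n_excluded_window, 2)

  # polygon membership equals a point-in-polygon oracle
  poly <- data.frame(x = c(0.2, 4.8, 2.5), y = c(0.2, 0.8, 4.9))
  res3 <- roi_mean_lifetime(lt, list(tri = poly))
  g <- expand.grid(x = 0:5, y = 0:5)
  inside <- pracma::inpolygon(g$x, g$y, poly$x, poly$y, boundary = TRUE)
  tau_vals <- lt$tau_ns[cbind(g$y + 1, g$x + 1)][inside]
  tau_ok <- tau_vals[tau_vals >= 2.8 & tau_vals <= 7]
  expect_equal(res3$n_pixels + res3$n_excluded_window, sum(inside))
  expect_equal(res3$mean_ns, mean(tau_ok))

  # empty ROI reported as undefined, not an error
  far <- list(out = data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)))
  lt_na <- lt; lt_na$tau_ns[] <- NA
  res4 <- roi_mean_lifetime(lt_na, far)
  expect_true(is.na(res4$mean_ns))
  expect_equal(res4$n_excluded_undefined, 4)
})

test_that("ROI means are invariant to joint translation of image and ROI", {
  set.seed(2)
  tau <- matrix(runif(100, 3, 6), 10, 10)
  mk <- function(m) structure(list(tau_ns = m, intensity = m * 0 + 1,
                                   pixel_size_nm = 675, estimator = "phase"),
                              class = "lifetime_image")
  roi <- data.frame(x = c(1, 5, 5, 1), y = c(1, 1, 5, 5))
  r1 <- roi_mean_lifetime(mk(tau), list(a = roi))
  shifted <- matrix(NA_real_, 10, 10)
  shifted[3:10, 3:10] <- tau[1:8, 1:8]
  roi2 <- data.frame(x = roi$x + 2, y = roi$y + 2)
  r2 <- roi_mean_lifetime(mk(shifted), list(a = roi2))
  expect_equal(r1$mean_ns, r2$mean_ns)
  expect_equal(r1$n_pixels, r2$n_pixels)
})

test_that("rendering clips to the display range without touching quantities", {
  tau <- matrix(c(3.0, 3.75, 4.25, 4.75, 5.5, NA), 2, 3)
  lt <- structure(list(tau_ns = tau, intensity = tau * 0 + 1,
                       pixel_size_nm = 675, estimator = "phase"),
                  class = "lifetime_image")
  rgb <- render_lifetime(lt, c(3.75, 4.75))
  # below-range equals the low end colour, above-range the high end
  expect_equal(rgb[1, 1, ], rgb[2, 1, ])   # 3.0 ns rendered as 3.75 ns
  expect_equal(rgb[2, 2, ], rgb[1, 3, ])   # 5.5 ns rendered as 4.75 ns
  # low end is blue-dominant, high end red-dominant
  expect_gt(rgb[1, 1, 3], rgb[1, 1, 1])
  expect_gt(rgb[1, 3, 1], rgb[1, 3, 3])
  # midpoint maps to the middle of the palette (green-ish: G highest)
  mid <- rgb[1, 2, ]
  expect_true(which.max(mid) == 2)
  # undefined pixels are black
  expect_equal(rgb[2, 3, ], c(0, 0, 0))
})

test_that("simulated two-region stacks recover the configured lifetime difference", {
  # regions mirroring the tissue contrast scale (4.83 vs 4.50 ns)
  sim <- generate_flim_stack(flim_sim_config(
    image_shape = c(20, 40),
    regions = list(
      list(polygon = data.frame(x = c(0, 18, 18, 0), y = c(0, 0, 19, 19)),
           tau_ns = 4.83),
      list(polygon = data.frame(x = c(21, 39, 39, 21), y = c(0, 0, 19, 19)),
           tau_ns = 4.50)
    ),
    photons_per_pixel_mean = 1e4, background_count_level = 5, seed = 31
  ))
  thr <- threshold_background(sim$stack, 50)
  lt <- lifetime_map(median_filter_phasor(phasor_transform(thr), 5))
  rois <- list(
    hi = data.frame(x = c(0, 18, 18, 0), y = c(0, 0, 19, 19)),
    lo = data.frame(x = c(21, 39, 39, 21), y = c(0, 0, 19, 19))
  )
  res <- roi_mean_lifetime(lt, rois)
  diff_ns <- res$mean_ns[res$roi == "hi"] - res$mean_ns[res$roi == "lo"]
  expect_equal(diff_ns, 0.33, tolerance = 0.05)
})

test_that("zero-photon stacks fall below any positive threshold", {
  sim <- generate_flim_stack(flim_sim_config(
    image_shape = c(6, 6),
    regions = list(list(polygon = data.frame(x = c(0, 5, 5, 0),
                                             y = c(0, 0, 5, 5)), tau_ns = 4)),
    photons_per_pixel_mean = 0, background_count_level = 0, seed = 1
  ))
  expect_equal(sum(threshold_background(sim$stack, 1)$mask), 0)
})

test_that("lifetimes beyond the aliasing limit trigger a warning", {
  cfg <- flim_sim_config(
    image_shape = c(4, 4),
    regions = list(list(polygon = data.frame(x = c(0, 3, 3, 0),
                                             y = c(0, 0, 3, 3)), tau_ns = 9)),
    photons_per_pixel_mean = 100, seed = 1
  )
  expect_warning(generate_flim_stack(cfg), "aliasing")
})
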