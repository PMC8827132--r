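test_that("phasor computation matches hand-evaluated sums", {
  expect_equal(unclass(compute_phasor(5, 0, 0.02)), 1 + 0i)
  # antiphase cancellation
  expect_equal(unclass(compute_phasor(c(1, 1), c(0, 25), 1 / 50)), 0 + 0i,
               tolerance = 1e-15)
  # 4-gate hand evaluation: (4 - 2) + (3 - 1) i over 10
  z <- compute_phasor(c(4, 3, 2, 1), c(0, 12.5, 25, 37.5), 1 / 50)
  expect_equal(unclass(z), 0.2 + 0.2i, tolerance = 1e-14)
  expect_error(compute_phasor(c(1, -1), c(0, 25), 0.02), "zero total")
  expect_error(compute_phasor(1:3, 1:2, 0.02))
})

test_that("phase lifetime inverts the phasor phase", {
  expect_equal(phase_lifetime(1 + 0i, 0.02), 0)
  expect_equal(phase_lifetime(0.5 + 0.5i, 0.02), 1 / (2 * pi * 0.02))
  expect_equal(phase_lifetime(0.5 + 0.5i, 0.02), 7.9577, tolerance = 1e-4)
  expect_equal(phase_lifetime(single_exp_phasor(2.8, 0.02), 0.02), 2.8)
  # second-quadrant and negative-phase phasors are flagged, not negative
  expect_true(is.na(phase_lifetime(-0.1 + 0.3i, 0.02)))
  expect_true(is.na(phase_lifetime(0.5 - 0.2i, 0.02)))
})

test_that("single-exponential phasors lie on the universal semicircle", {
  expect_equal(unclass(single_exp_phasor(0, 0.02)), 1 + 0i)
  expect_equal(Mod(single_exp_phasor(1e9, 0.02)), 0, tolerance = 1e-7)
  z <- single_exp_phasor(2.8, 0.02)
  u <- 2 * pi * 0.02 * 2.8
  expect_equal(Re(z), 1 / (1 + u^2))
  expect_equal(Im(z), u / (1 + u^2))
  taus <- c(0.1, 1, 2.8, 4.08, 10, 100)
  zz <- single_exp_phasor(taus, 0.02)
  expect_equal((Re(zz) - 0.5)^2 + Im(zz)^2, rep(0.25, length(taus)),
               tolerance = 1e-12)
})

test_that("calibration is exact for self- and ideal references", {
  f <- 0.02
  z_cal_theo <- single_exp_phasor(2.8, f)
  z_exp <- 0.3 + 0.4i
  # sample == calibration measurement: returns the theoretical reference
  expect_equal(unclass(calibrate_phasor(z_exp, z_exp, 2.8, f)),
               unclass(z_cal_theo))
  # ideal instrument: calibration is the identity
  expect_equal(unclass(calibrate_phasor(z_exp, z_cal_theo, 2.8, f)), z_exp)
  expect_error(calibrate_phasor(z_exp, 0 + 0i, 2.8, f), "zero")
})

test_that("phasor linearity: mixtures are intensity-weighted combinations", {
  set.seed(31)
  ts <- seq(0, 49, by = 1)
  for (i in 1:5) {
    I1 <- runif(50); I2 <- runif(50)
    z1 <- unclass(compute_phasor(I1, ts, 0.02))
    z2 <- unclass(compute_phasor(I2, ts, 0.02))
    w <- sum(I1) / (sum(I1) + sum(I2))
    zmix <- unclass(compute_phasor(I1 + I2, ts, 0.02))
    expect_equal(zmix, w * z1 + (1 - w) * z2, tolerance = 1e-12)
  }
})

test_that("ROI binning sums tiles and drops partial edges", {
  m <- matrix(2, 8, 8)
  expect_equal(bin_rois(m, 1), m)
  expect_equal(bin_rois(m, 4), matrix(32, 2, 2))
  # full sensor geometry: 472 x 256 binned 4x4 -> 118 x 64 ROIs
  big <- matrix(1, 472, 256)
  expect_equal(dim(bin_rois(big, 4)), c(118, 64))
  # partial tiles dropped
  odd <- matrix(1, 9, 10)
  expect_equal(dim(bin_rois(odd, 4)), c(2, 2))
  expect_error(bin_rois(matrix(1, 3, 3), 4), "larger")
  # stack binning preserves totals over kept region and scales i_max
  s <- sim_dye_stack(2.8, seed = 3, num_gates = 6, side = 8, brightness = 0.2)
  b <- bin_rois(s, 4)
  expect_equal(b$i_max, 255 * 16)
  expect_equal(sum(b$counts), sum(s$counts))
  expect_equal(b$counts[1, 1, 2], sum(s$counts[1:4, 1:4, 2]))
})

test_that("phasor images flag zero-intensity pixels instead of NaN", {
  s <- sim_dye_stack(2.8, seed = 17, num_gates = 10, side = 8,
                     brightness = 0.3)
  s$counts[1, 1, ] <- 0
  pim <- phasor_image(s)
  expect_false(pim$valid[1, 1])
  expect_true(all(pim$valid[-1, -1]))
  expect_true(all(is.finite(pim$g[pim$valid])))
  # scalar path agrees with the map path
  z11 <- compute_phasor(s$counts[2, 2, ], s$timestamps, 0.02)
  expect_equal(pim$z[2, 2], unclass(z11))
})

test_that("calibrating a sample with itself lands on the reference phasor", {
  s <- sim_dye_stack(2.8, seed = 19, num_gates = 20, side = 8,
                     brightness = 0.4)
  pim <- phasor_image(s)
  cal <- calibrate_phasor_image(pim, pim, 2.8, granularity = "pixel")
  target <- unclass(single_exp_phasor(2.8, 0.02))
  expect_true(all(abs(cal$z[cal$valid] - target) < 1e-12))
})

test_that("phasor ratio projects onto the reference segment and clamps", {
  z1 <- 0.2 + 0.4i; z2 <- 0.8 + 0.3i
  expect_equal(phasor_ratio(z1, z1, z2)$r1, 1)
  expect_equal(phasor_ratio(z2, z1, z2)$r1, 0)
  expect_equal(phasor_ratio((z1 + z2) / 2, z1, z2)$r1, 0.5)
  # off-segment point projects orthogonally
  mid <- (z1 + z2) / 2 + 0.1i * (z2 - z1) / Mod(z2 - z1)
  expect_equal(phasor_ratio(mid, z1, z2)$r1, 0.5, tolerance = 1e-12)
  # projection beyond an endpoint clamps
  beyond <- z2 + 2 * (z2 - z1)
  pr <- phasor_ratio(beyond, z1, z2)
  expect_equal(pr$r1, 0)
  expect_equal(pr$projection, z2)
  expect_error(phasor_ratio(0.5 + 0.1i, z1, z1), "coincide")
})

test_that("phasor ratio and volume fraction invert each other", {
  expect_equal(phasor_ratio_from_fraction(0.37, 1), 0.37)  # linear iff mu*chi = 1
  expect_equal(phasor_ratio_from_fraction(0.5, 5.51), 5.51 / 6.51)
  expect_equal(phasor_ratio_from_fraction(0.5, 5.51), 0.84639,
               tolerance = 1e-5)
  v <- seq(0.05, 0.95, by = 0.09)
  expect_equal(volume_fraction(phasor_ratio_from_fraction(v, 5.51), 5.51), v,
               tolerance = 1e-12)
  expect_equal(volume_fraction(c(0, 1), 5.51), c(0, 1))
})

test_that("mu*chi is recovered from noiseless and noisy dilution curves", {
  v <- seq(0.1, 0.9, by = 0.1)
  r <- phasor_ratio_from_fraction(v, 5.51)
  fit <- fit_mu_chi(v, r)
  expect_equal(fit$mu_chi, 5.51, tolerance = 1e-6)
  expect_equal(fit$se, 0, tolerance = 1e-6)
  set.seed(41)
  r_noisy <- pmin(pmax(r + rnorm(9, 0, 0.01), 0), 1)
  fit2 <- fit_mu_chi(v, r_noisy)
  expect_lt(abs(fit2$mu_chi - 5.51), 4 * fit2$se + 0.5)
  expect_error(fit_mu_chi(c(0, 1), c(0, 1)), "interior")
})

test_that("lifetime maps color by ratio and scale luminance by intensity", {
  z_red <- single_exp_phasor(13.9, 0.02)
  z_blue <- single_exp_phasor(16.7, 0.02)
  H <- 3; W <- 4
  pim <- structure(list(
    z = matrix(unclass(z_red), H, W),
    g = matrix(Re(z_red), H, W), s = matrix(Im(z_red), H, W),
    intensity = matrix(1, H, W), valid = matrix(TRUE, H, W),
    freq_per_ns = 0.02), class = "phasor_image")
  img <- lifetime_map(pim, ref_red = z_red, ref_blue = z_blue)
  expect_equal(dim(img), c(H, W, 3))
  # everything at the red reference: pure red, uniform
  expect_equal(img[, , 1], matrix(1, H, W), tolerance = 1e-9)
  expect_equal(img[, , 2], matrix(0, H, W), tolerance = 1e-9)
  expect_equal(img[, , 3], matrix(0, H, W), tolerance = 1e-9)
  expect_equal(attr(img, "ratio"), matrix(0, H, W), tolerance = 1e-12)
  # midpoint renders a mid-scale color (neither endpoint hue)
  pim$z[] <- unclass((z_red + z_blue) / 2)
  mid <- lifetime_map(pim, z_red, z_blue)
  expect_equal(attr(mid, "ratio"), matrix(0.5, H, W), tolerance = 1e-12)
  expect_false(any(mid[, , 1] == 1 & mid[, , 2] == 0 & mid[, , 3] == 0))
  # scaled mode: zero intensity -> black regardless of phasor
  pim$intensity[] <- 0; pim$intensity[1, 1] <- 5
  dark <- lifetime_map(pim, z_red, z_blue, mode = "scaled")
  expect_true(all(dark[2, , ] == 0))
  # invalid pixels take the designated null color
  pim$valid[3, 4] <- FALSE
  nc <- lifetime_map(pim, z_red, z_blue, null_color = c(0.1, 0.2, 0.3))
  expect_equal(as.numeric(nc[3, 4, ]), c(0.1, 0.2, 0.3))
})

test_that("2-D phasor histograms conserve mass and peak at the true phasor", {
  s <- sim_dye_stack(4.08, seed = 23, num_gates = 40, side = 24,
                     brightness = 1.5)
  cal <- sim_dye_stack(2.8, seed = 24, num_gates = 40, side = 24,
                       brightness = 1.5)
  res <- run_pipeline(s, cal_stack = cal, tau_cal_ns = 2.8, roi_bin = 1)
  h <- phasor_histogram2d(res$phasors, bins = 40)
  expect_equal(sum(h$counts), sum(res$phasors$valid))
  peak <- which(h$counts == max(h$counts), arr.ind = TRUE)[1, ]
  z0 <- single_exp_phasor(4.08, 0.02)
  expect_lt(abs(h$g_mid[peak[1]] - Re(z0)), 2 * (1 / 40))
  expect_lt(abs(h$s_mid[peak[2]] - Im(z0)), 2 * (0.75 / 40))
  # single valid pixel: one bin with count 1
  pim1 <- structure(list(
    z = matrix(0.6 + 0.3i, 1, 1), g = matrix(0.6, 1, 1),
    s = matrix(0.3, 1, 1), intensity = matrix(1, 1, 1),
    valid = matrix(TRUE, 1, 1), freq_per_ns = 0.02),
    class = "phasor_image")
  h1 <- phasor_histogram2d(pim1, bins = 10)
  expect_equal(sum(h1$counts), 1)
  expect_equal(max(h1$counts), 1)
})
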