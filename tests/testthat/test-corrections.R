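test_that("pile-up correction matches the closed form and its bounds", {
  expect_equal(as.numeric(pileup_correct(0, 255)), 0)
  expect_equal(as.numeric(pileup_correct(255 * (1 - exp(-1)), 255)), 255)
  expect_equal(as.numeric(pileup_correct(128, 255)), -255 * log(127 / 255))
  expect_equal(as.numeric(pileup_correct(128, 255)), 177.7545,
               tolerance = 1e-4)
  # monotone and never below the recorded count
  x <- seq(0, 254, by = 2)
  y <- as.numeric(pileup_correct(x, 255))
  expect_true(all(diff(y) > 0))
  expect_true(all(y >= x))
  expect_error(pileup_correct(256, 255), "exceed")
  expect_error(pileup_correct(-1, 255))
})

test_that("saturated bins are clamped and flagged rather than infinite", {
  out <- pileup_correct(c(10, 255), 255)
  expect_identical(attr(out, "saturated"), c(FALSE, TRUE))
  expect_true(is.finite(out[2]))
  expect_equal(out[2], -255 * log(0.5 / 255))
})

test_that("saturate followed by correct is the identity", {
  i_max <- 255
  i_true <- seq(0, 0.99, by = 0.01) * i_max
  rec <- pileup_saturate(i_true, i_max)
  back <- as.numeric(pileup_correct(rec, i_max))
  expect_equal(back, i_true, tolerance = 1e-9)
  # linear regime: correction factor -> 1 as counts -> 0
  expect_equal(as.numeric(pileup_correct(1e-6, 255)) / 1e-6, 1,
               tolerance = 1e-6)
})

test_that("tail-average background estimation recovers a known offset", {
  # constant stack: estimate equals the constant, any window
  cst <- gate_stack(array(7, c(4, 4, 10)), seq(0, 45, by = 5), i_max = 255,
                    bit_depth = 8, laser = laser20, gates = tiling_gates(10))
  expect_equal(estimate_background_tail(cst, c(20, 45)), matrix(7, 4, 4))
  expect_equal(estimate_background_tail(cst, c(0, 45)),
               matrix(mean(cst$counts), 4, 4))
  expect_error(estimate_background_tail(cst, c(46, 49)), "no gate")
  # simulated short-lifetime decay + dark offset: tail window estimate
  G <- 50
  s <- sim_dye_stack(1.2, seed = 77, num_gates = G, side = 24,
                     brightness = 0.4, width_ns = 4, dcr_cps = 3000)
  dark_per_gate <- 3000 * 1e-9 * 4 * 200 * 255  # rate * W * pulses * frames
  corr <- pileup_correct_stack(s)
  sel <- s$timestamps >= 25 & s$timestamps <= 45
  bg <- estimate_background_tail(corr, c(25, 45))
  # fluorescence in the tail is negligible for tau = 1.2 ns gates >= 25 ns
  se <- sd(bg) / sqrt(length(bg))
  expect_lt(abs(mean(bg) - dark_per_gate), 3 * se + 0.02 * dark_per_gate)
})

test_that("background subtraction is exact, unclamped, and shape-checked", {
  s <- sim_dye_stack(2.8, seed = 5, num_gates = 8, side = 8, brightness = 0.2)
  same <- subtract_background(s, matrix(0, 8, 8))
  expect_equal(same$values, s$counts + 0)
  zero <- subtract_background(cst <- gate_stack(array(3, c(2, 2, 4)),
                                                c(0, 1, 2, 3), 255, 8,
                                                laser20, tiling_gates(4)),
                              matrix(3, 2, 2))
  expect_true(all(zero$values == 0))
  # negative residuals are retained
  neg <- subtract_background(cst, matrix(5, 2, 2))
  expect_true(all(neg$values == -2))
  expect_error(subtract_background(s, matrix(0, 4, 4)), "shape")
  # residual mean ~ 0 on a flat noisy stack
  flat <- sim_dye_stack(2.8, seed = 9, num_gates = 12, side = 20,
                        brightness = 0, dcr_cps = 5000)
  bg <- estimate_background_tail(flat, c(0, 50))
  res <- subtract_background(flat, bg)
  expect_lt(abs(mean(res$values)), 3 * sd(res$values) / sqrt(length(res$values)))
})

test_that("hot-pixel masking flags the top intensity percentile", {
  img <- matrix(seq_len(100), 10, 10)
  expect_equal(sum(hot_pixel_mask(img, 0)), 0)
  expect_equal(sum(hot_pixel_mask(img, 1)), 1)
  expect_equal(which(hot_pixel_mask(img, 1)), 100L)
  # injected hot pixels in a flat image are all recovered at the true rate
  set.seed(2)
  flat <- matrix(100, 25, 20)
  hot_idx <- sample(length(flat), 10)
  flat[hot_idx] <- 100 + rpois(10, 400)
  mask <- hot_pixel_mask(flat, 100 * 10 / length(flat))
  expect_setequal(which(mask), hot_idx)
})

test_that("4-neighbor interpolation restores smooth fields", {
  cst <- matrix(4.2, 6, 6)
  m <- matrix(FALSE, 6, 6); m[3, 4] <- TRUE
  expect_equal(interpolate_masked(cst, m), cst)
  # linear ramp: interior 4-neighbor mean is exact
  ramp <- outer(1:8, 1:8, function(i, j) 2 * i + 3 * j)
  m2 <- matrix(FALSE, 8, 8); m2[4, 5] <- TRUE
  expect_equal(interpolate_masked(ramp, m2), ramp)
  # random case against an explicit brute-force oracle (isolated masks)
  set.seed(8)
  img <- matrix(rnorm(48), 6, 8)
  mask <- matrix(FALSE, 6, 8)
  mask[cbind(c(1, 3, 6, 4), c(1, 4, 8, 2))] <- TRUE
  got <- interpolate_masked(img, mask)
  for (idx in which(mask)) {
    rc <- arrayInd(idx, dim(img))
    nb <- rbind(rc + c(-1, 0), rc + c(1, 0), rc + c(0, -1), rc + c(0, 1))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= 6 & nb[, 2] >= 1 & nb[, 2] <= 8, ,
             drop = FALSE]
    vals <- img[nb][!mask[nb]]
    expect_equal(got[rc], mean(vals))
  }
  expect_error(interpolate_masked(img, matrix(TRUE, 6, 8)))
  # a fully-masked neighborhood resolves iteratively
  m3 <- matrix(FALSE, 6, 8); m3[2:3, 2:3] <- TRUE
  out <- interpolate_masked(matrix(1, 6, 8) + 0, m3)
  expect_true(all(is.finite(out)))
  expect_equal(out, matrix(1, 6, 8))
})

test_that("whole-stack hot pixel correction flags and fills", {
  s <- sim_dye_stack(2.8, seed = 13, num_gates = 6, side = 10,
                     brightness = 0.1)
  s$counts[2, 2, ] <- s$i_max  # burn one pixel
  fixed <- correct_hot_pixels(s, percentile = 1)
  expect_true(fixed$hot[2, 2])
  expect_lt(fixed$values[2, 2, 1], s$i_max)
})
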