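# Correction chain arithmetic: modal background, registration, bleedthrough,
# ratio images and region ratios.

test_that("modal background subtraction matches the histogram oracle", {
  img <- matrix(7, 5, 5)
  bc <- background_correct(img)
  expect_equal(bc$background, 7)
  expect_true(all(bc$corrected == 0))

  # noisy image with a known mode, checked against a brute-force histogram
  withr::with_seed(21, {
    img <- matrix(c(rep(100, 6000), sample(80:180, 4000, TRUE)), 100, 100)
  })
  oracle <- {
    tab <- table(round(as.vector(img)))
    as.numeric(names(tab))[which.max(tab)]
  }
  expect_equal(background_correct(img)$background, oracle)

  # equal-count tie breaks toward the lower intensity
  img <- matrix(c(rep(50, 10), rep(60, 10), 1:5), 5, 5)
  expect_equal(background_correct(img)$background, 50)

  img[1] <- NaN
  expect_error(background_correct(img), "finite")
})

test_that("registration recovers planted integer shifts exactly", {
  withr::with_seed(22, {
    base <- gaussian_smooth_ref <- matrix(runif(60 * 60), 60, 60)
  })
  expect_equal(register_channels(base, base, max_shift = 4)[c("dy", "dx")],
               list(dy = 0L, dx = 0L))

  # exhaustive property over all shifts in +/-3
  for (dy in -3:3) for (dx in -3:3) {
    shifted <- fretkit:::shift_image(base, dy, dx, fill = 0)
    est <- register_channels(base, shifted, max_shift = 5)
    expect_identical(c(est$dy, est$dx), c(dy, dx))
  }

  shifted <- fretkit:::shift_image(base, 6, 0, fill = 0)
  expect_error(register_channels(base, shifted, max_shift = 5), "max_shift")

  # apply_registration undoes the displacement on the interior
  shifted <- fretkit:::shift_image(base, 2, -1, fill = 0)
  est <- register_channels(base, shifted, max_shift = 4)
  aligned <- apply_registration(shifted, est)
  expect_equal(aligned[10:50, 10:50], base[10:50, 10:50])
})

test_that("bleedthrough subtraction is exact, linear, and validated", {
  a <- matrix(155, 3, 3); d <- matrix(100, 3, 3)
  expect_equal(correct_bleedthrough(a, d, 0.55), matrix(100, 3, 3))
  expect_equal(correct_bleedthrough(0.32 * d, d, 0.32), matrix(0, 3, 3))
  expect_identical(correct_bleedthrough(a, d, 0), a)

  withr::with_seed(23, {
    y <- matrix(runif(25, 50, 200), 5, 5)
    dd <- matrix(runif(25, 50, 200), 5, 5)
  })
  expect_equal(correct_bleedthrough(3.7 * y, 3.7 * dd, 0.55),
               3.7 * correct_bleedthrough(y, dd, 0.55))
  expect_error(correct_bleedthrough(a, matrix(1, 2, 2), 0.5), "dimensions")
  expect_error(correct_bleedthrough(a, d, 1), "alpha")
})

test_that("bleedthrough calibration recovers alpha from donor-only movies", {
  # noiseless: acceptor channel is exactly alpha x donor (ratio ~ 0)
  spec <- quiet_spec(n_cells = 1, n_frames = 2, ratio_baseline = 1e-9, alpha = 0.55)
  sim <- simulate_fret_movie(spec, seed = 31)
  mask <- sim$scene$masks[[1]]
  expect_equal(calibrate_bleedthrough(sim$movie, mask), 0.55, tolerance = 1e-7)

  expect_error(calibrate_bleedthrough(sim$movie, mask & FALSE), "empty")
  bg_only <- !mask & !fretkit:::dilate_once(mask)
  expect_error(
    calibrate_bleedthrough(sim$movie, bg_only, donor_floor = 100),
    "donor_floor")
})

test_that("ratio images respect the donor floor and match the quotient oracle", {
  s <- matrix(200, 4, 4); d <- matrix(100, 4, 4)
  ri <- ratio_image(s, d, donor_floor = 10)
  expect_true(all(ri$valid))
  expect_true(all(ri$values == 2))

  d[2, 2] <- 5
  ri <- ratio_image(s, d, donor_floor = 10)
  expect_false(ri$valid[2, 2])
  expect_true(is.na(ri$values[2, 2]))

  withr::with_seed(24, {
    s <- matrix(runif(100, 10, 300), 10, 10)
    d <- matrix(runif(100, 20, 200), 10, 10)
  })
  ri <- ratio_image(s, d, donor_floor = 25)
  oracle <- ifelse(d > 25, s / d, NA)
  expect_equal(ri$values, oracle)
  expect_warning(ratio_image(s, d, donor_floor = 1e6), "empty")
})

test_that("region ratio is the ratio of medians, not the mean of ratios", {
  s <- matrix(150, 11, 11); d <- matrix(100, 11, 11)
  mask <- matrix(TRUE, 11, 11)
  expect_equal(region_ratio(s, d, mask), 1.5)

  # a single extreme outlier leaves the median-based readout unchanged
  s2 <- s; s2[1, 1] <- 1e7
  expect_equal(region_ratio(s2, d, mask), 1.5)

  # skewed region where the two aggregations genuinely differ
  withr::with_seed(25, {
    d <- matrix(rexp(121, 1 / 100) + 10, 11, 11)
    s <- matrix(rexp(121, 1 / 150) + 10, 11, 11)
  })
  rom <- median(s[mask]) / median(d[mask])        # ratio-of-medians oracle
  mor <- mean(s[mask] / d[mask])                  # mean-of-ratios foil
  expect_false(isTRUE(all.equal(rom, mor, tolerance = 1e-3)))
  expect_equal(region_ratio(s, d, mask), rom)

  expect_error(region_ratio(s, d, mask & FALSE), "empty")
  expect_error(region_ratio(s, -d, mask), "not positive")
})

test_that("noiseless forward model inverts through the correction chain", {
  # background -> bleedthrough -> ratio recovers the planted ratio to 1e-9
  for (R in c(0.5, 2)) {
    for (alpha in c(0, 0.55)) {
      spec <- quiet_spec(n_cells = 1, n_frames = 2,
                         ratio_baseline = R, alpha = alpha)
      sim <- simulate_fret_movie(spec, seed = 41)
      fr <- corrected_frames(sim$movie, 1, alpha)
      mask <- sim$scene$masks[[1]]
      expect_equal(max(abs(fr$sensitized[mask] / fr$donor[mask] - R)), 0,
                   tolerance = 1e-9)
    }
  }
})
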