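# Watershed, threshold rules and morphology, each against a brute-force
# oracle where the rule has one.

test_that("sum_time_series equals the elementwise oracle", {
  expect_equal(sum_time_series(array(2, dim = c(3, 3, 3))), matrix(6, 3, 3))
  one <- matrix(1:12, 3, 4)
  expect_equal(sum_time_series(array(one, dim = c(3, 4, 1))), one)
  withr::with_seed(51, { stack <- array(runif(3 * 4 * 5), dim = c(3, 4, 5)) })
  oracle <- stack[, , 1] * 0
  for (t in 1:5) oracle <- oracle + stack[, , t]
  expect_equal(sum_time_series(stack), oracle)
})

test_that("seeded watershed separates blobs and honors barriers", {
  h <- w <- 64
  rr <- matrix(seq_len(h), h, w); cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  blob <- function(cy, cx, s) 1000 * exp(-((rr - cy)^2 + (cc - cx)^2) / (2 * s^2))

  # two disjoint Gaussian blobs, one seed each
  img <- blob(20, 20, 6) + blob(45, 45, 6) + 10
  labels <- seeded_watershed(img, seed_set(c(20, 45), c(20, 45)),
                             smoothing_sigma = 1)
  expect_setequal(unique(as.vector(labels)), c(0L, 1L, 2L))
  # each basin contains its blob's half-max core entirely, and the two
  # symmetric blobs yield areas within 5% of each other
  for (k in 1:2) {
    cyx <- c(20, 45)[k]
    core <- blob(cyx, cyx, 6) > 500
    expect_true(all(labels[core] == k))
  }
  expect_lt(abs(sum(labels == 1) - sum(labels == 2)) / sum(labels == 1), 0.05)

  # single blob, single seed
  img1 <- blob(32, 32, 8) + 10
  l1 <- seeded_watershed(img1, seed_set(32, 32), smoothing_sigma = 1)
  expect_setequal(unique(as.vector(l1)), c(0L, 1L))

  # a barrier across one blob with two seeds splits it into the unbarred
  # region minus the barrier pixels
  barrier <- cbind(seq(20, 44), 32)
  l2 <- seeded_watershed(img1, seed_set(c(32, 32), c(26, 38), 1:2,
                                        barriers = list(barrier)),
                         smoothing_sigma = 1)
  expect_setequal(unique(as.vector(l2)), c(0L, 1L, 2L))
  barrier_px <- matrix(FALSE, h, w)
  barrier_px[fretkit:::rasterize_polyline(barrier, h, w)] <- TRUE
  union2 <- (l2 == 1L) | (l2 == 2L)
  expect_identical(union2, (l1 == 1L) & !barrier_px)
  expect_true(all(l2[barrier_px] == 0L))
})

test_that("watershed labels partition the image with background", {
  spec <- quiet_spec(n_cells = 3, n_frames = 2)
  sim <- simulate_fret_movie(spec, seed = 52)
  labels <- starting_regions(sim$movie, sim$scene$seeds)
  expect_setequal(sort(unique(as.vector(labels))), 0:3)
  # regions are disjoint by construction of a label map; check each contains
  # its own seed
  s <- sim$scene$seeds
  for (i in seq_along(s$labels))
    expect_equal(labels[s$rows[i], s$cols[i]], s$labels[i])
})

test_that("threshold rules match their sort-and-count oracles", {
  withr::with_seed(53, { img <- matrix(runif(400, 0, 200), 20, 20) })
  region <- matrix(TRUE, 20, 20)
  img[3, 3] <- 200  # pin the max

  m <- apply_threshold(img, region, threshold_spec("fraction_of_max", fraction = 0.15))
  expect_identical(m, img > 30)

  bg <- list(mean = 10, sd = 2)
  m <- apply_threshold(img, region, threshold_spec("background_sd", sd_factor = 5),
                       background = bg)
  expect_identical(m, img > 20)

  # 1..100 region: P99 by linear interpolation, then 10% of it
  vals <- matrix(1:100, 10, 10)
  spec99 <- threshold_spec("fraction_of_percentile", fraction = 0.10, percentile = 99)
  m <- apply_threshold(vals, matrix(TRUE, 10, 10), spec99)
  p99 <- unname(quantile(1:100, 0.99, type = 7))    # independent oracle
  expect_equal(sum(m), sum(1:100 > 0.10 * p99))

  # restricted to region; outside pixels never survive
  region2 <- matrix(FALSE, 20, 20); region2[1:10, 1:10] <- TRUE
  m <- apply_threshold(img, region2, threshold_spec("fraction_of_max", fraction = 0.5))
  expect_true(all(!m[!region2]))
  cutoff <- 0.5 * max(img[region2])
  expect_identical(m[region2], img[region2] > cutoff)

  expect_warning(
    apply_threshold(img, region, threshold_spec("fraction_of_max", fraction = 1)),
    "empty")
})

test_that("threshold rules are monotone in their strictness parameter", {
  withr::with_seed(54, { img <- matrix(runif(256, 0, 100), 16, 16) })
  region <- matrix(TRUE, 16, 16)
  prev <- NULL
  for (f in c(0.1, 0.3, 0.5, 0.8)) {
    m <- suppressWarnings(
      apply_threshold(img, region, threshold_spec("fraction_of_max", fraction = f)))
    if (!is.null(prev)) expect_true(all(prev | !m))  # m subset of prev
    prev <- m
  }
})

test_that("erosion matches the brute-force oracle and is a semigroup", {
  sq <- matrix(FALSE, 50, 50); sq[5:45, 5:45] <- TRUE   # 41x41 square
  e9 <- erode_region(sq, 9)
  expect_equal(sum(e9), 23^2)
  expect_true(all(e9[14:36, 14:36]))

  expect_identical(erode_region(sq, 0), sq)

  disk <- fretkit:::rasterize_ellipse(20, 20, 10, 10, 4, 4)
  expect_warning(e <- erode_region(disk, 9), "empty")
  expect_false(any(e))

  withr::with_seed(55, {
    for (i in 1:8) {
      m <- random_mask(16, 16, p = 0.7)
      expect_identical(suppressWarnings(erode_region(m, 2)), erode_oracle(m, 2))
      a <- sample(0:2, 1); b <- sample(1:2, 1)
      expect_identical(
        suppressWarnings(erode_region(m, a + b)),
        suppressWarnings(erode_region(suppressWarnings(erode_region(m, a)), b)))
    }
  })
})

test_that("cortex band and body partition the mask", {
  disk <- fretkit:::rasterize_ellipse(50, 50, 25, 25, 20, 20)
  cb <- cortex_band(disk, 5)
  expect_identical(cb$cortex | cb$body, disk)
  expect_false(any(cb$cortex & cb$body))

  sq <- matrix(FALSE, 50, 50); sq[5:45, 5:45] <- TRUE
  cb <- cortex_band(sq, 5)
  expect_equal(sum(cb$body), 31^2)
  expect_equal(sum(cb$cortex), 41^2 - 31^2)       # 720 px ring

  thin <- fretkit:::rasterize_ellipse(20, 20, 10, 10, 4, 4)
  expect_error(cortex_band(thin, 5), "thinner")
})

test_that("segmented cell area tracks ground truth on clean scenes", {
  for (seed in c(61, 62)) {
    spec <- quiet_spec(n_cells = 2, n_frames = 2)
    sim <- simulate_fret_movie(spec, seed = seed)
    labels <- starting_regions(sim$movie, sim$scene$seeds)
    regions <- cell_region_series(sim$movie, labels)
    for (i in 1:2) {
      truth <- sum(sim$scene$masks[[i]])
      got <- sum(regions[[paste0("cell", i)]][[1]])
      expect_lt(abs(got - truth) / truth, 0.05)
    }
  }
})
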