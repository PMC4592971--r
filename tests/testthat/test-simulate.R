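# The forward-model generator itself: geometry, kinetics, determinism and
# conservation laws.

test_that("rasterized bodies match the analytic ellipse area", {
  # rasterizer against the analytic area pi*a*b for known semi-axes
  withr::with_seed(101, {
    for (i in 1:5) {
      a <- runif(1, 12, 18); b <- runif(1, 12, 18)
      m <- fretkit:::rasterize_ellipse(80, 80, 40.3, 39.6, a, b)
      expect_lt(abs(sum(m) - pi * a * b) / (pi * a * b), 0.02)
    }
  })
  # and scene bodies are ellipses of plausible area for the default axes
  body <- make_cell_scene(quiet_spec(n_cells = 1), 102)$body_masks[[1]]
  expect_gt(sum(body), pi * 15^2 * 0.95)
  expect_lt(sum(body), pi * 17^2 * 1.05)
})

test_that("scenes are deterministic and reject bad geometry", {
  spec <- quiet_spec(n_cells = 3)
  s1 <- make_cell_scene(spec, 104)
  s2 <- make_cell_scene(spec, 104)
  expect_identical(s1$masks, s2$masks)
  expect_identical(s1$seeds, s2$seeds)

  # a cell pushed against the border is rejected
  tight <- quiet_spec(n_cells = 1, image_size = c(40L, 40L))
  expect_error(make_cell_scene(tight, 105), "border|overlap")
})

test_that("response kinetics follow the two-event rise/decay form", {
  spec <- scene_spec(duration_s = 300, frame_interval_s = 1,
                     event_times_s = c(60, 200), ratio_baseline = 1.2,
                     amplitude = 0.4, k_on = log(2) / 20, k_off = log(2) / 50)
  tt <- scene_frame_times(spec)
  r <- simulate_response_kinetics(spec, tt)
  expect_equal(r[tt < 60], rep(1.2, sum(tt < 60)))
  # closed-form values at chosen times
  expect_equal(r[tt == 100], 1.2 * (1 + 0.4 * (1 - exp(-log(2) / 20 * 40))))
  lvl <- 0.4 * (1 - exp(-log(2) / 20 * 140))
  expect_equal(r[tt == 250], 1.2 * (1 + lvl * exp(-log(2) / 50 * 50)))
  # continuity at the antagonist
  expect_lt(abs(r[tt == 200] - r[tt == 199]), 0.01)

  # amplitude 0: flat
  spec0 <- scene_spec(duration_s = 100, event_times_s = c(30, 80), amplitude = 0)
  expect_equal(simulate_response_kinetics(spec0),
               rep(1, length(scene_frame_times(spec0))))

  # near-instant rise: jumps to R0(1+A) within one frame
  specj <- scene_spec(duration_s = 100, frame_interval_s = 5,
                      event_times_s = c(50, 95), amplitude = 0.4, k_on = 1e3)
  rj <- simulate_response_kinetics(specj)
  ttj <- scene_frame_times(specj)
  expect_equal(rj[ttj == 55], 1.4, tolerance = 1e-6)
})

test_that("rendered movies are reproducible and honor the forward model", {
  spec <- noisy_spec(n_cells = 1, n_frames = 2)
  m1 <- simulate_fret_movie(spec, seed = 106)$movie
  m2 <- simulate_fret_movie(spec, seed = 106)$movie
  expect_identical(m1$channels, m2$channels)
  m3 <- simulate_fret_movie(spec, seed = 107)$movie
  expect_false(identical(m1$channels, m3$channels))

  # zero noise, alpha 0, uniform R = 2: acceptor/donor = 2 exactly in cells
  spec2 <- quiet_spec(n_cells = 1, n_frames = 2, ratio_baseline = 2, alpha = 0)
  sim <- simulate_fret_movie(spec2, seed = 108)
  mask <- sim$scene$masks[[1]]
  d <- movie_frame(sim$movie, "donor", 1) - spec2$background_mean
  a <- movie_frame(sim$movie, "acceptor", 1) - spec2$background_mean
  expect_equal(a[mask] / d[mask], rep(2, sum(mask)), tolerance = 1e-12)
})

test_that("written movies and sidecars round-trip through the simulate stage", {
  out <- withr::local_tempdir()
  spec <- noisy_spec(n_cells = 1, n_frames = 2)
  r1 <- run_pipeline("simulate", out_dir = file.path(out, "a"), spec = spec, seed = 109)
  r2 <- run_pipeline("simulate", out_dir = file.path(out, "b"), spec = spec, seed = 109)
  f1 <- file.path(out, "a", "movie.tif"); f2 <- file.path(out, "b", "movie.tif")
  expect_identical(readBin(f1, "raw", file.info(f1)$size),
                   readBin(f2, "raw", file.info(f2)$size))
  truth <- jsonlite::read_json(file.path(out, "a", "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$seed, 109)
  expect_true(truth$snr > 0)
  seeds <- read_seeds(file.path(out, "a", "seeds.json"))
  expect_identical(seeds$labels, r1$sim$scene$seeds$labels)
  expect_identical(seeds$rows, r1$sim$scene$seeds$rows)
})

test_that("retraction schedules are honored by construction", {
  spec <- quiet_spec(n_cells = 1, n_frames = 11, event_times_s = 20,
                     retraction_fraction = 0.8, retraction_duration_s = 50)
  sim <- simulate_retraction_movie(spec, seed = 110)
  a <- sim$truth$areas_px[1, ]
  expect_equal(tail(a, 1) / a[1], 0.8, tolerance = 0.01)
  expect_true(all(diff(a) <= 0))

  # constant schedule: masks identical across frames
  spec1 <- quiet_spec(n_cells = 1, n_frames = 4, event_times_s = 10,
                      retraction_fraction = 1)
  sim1 <- simulate_retraction_movie(spec1, seed = 111)
  expect_true(all(sim1$truth$areas_px[1, ] == sim1$truth$areas_px[1, 1]))

  # infeasible schedule: target below the body area
  spec2 <- quiet_spec(n_cells = 1, n_frames = 4, event_times_s = 10,
                      retraction_fraction = 0.3, retraction_duration_s = 10)
  expect_error(simulate_retraction_movie(spec2, 112), "infeasible")
})

test_that("recruitment conserves total marker per frame before noise", {
  spec <- quiet_spec(n_cells = 2, n_frames = 9, frame_interval_s = 10,
                     duration_s = 80, event_times_s = 20,
                     recruitment_rate = log(2) / 25)
  sim <- simulate_recruitment_movie(spec, seed = 113)
  totals <- vapply(sim$truth$marker_fields, sum, numeric(1))
  expect_equal(totals / totals[1], rep(1, 9), tolerance = 1e-9)

  # rate 0: the partition never moves
  spec0 <- quiet_spec(n_cells = 1, n_frames = 3, event_times_s = 10,
                      recruitment_rate = 0)
  sim0 <- simulate_recruitment_movie(spec0, seed = 114)
  expect_identical(sim0$truth$marker_fields[[3]], sim0$truth$marker_fields[[1]])
})
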