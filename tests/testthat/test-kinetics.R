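# Trace extraction, normalisation, half-time estimation, the spatial
# cortex-minus-body statistic, gating and control normalisation.

test_that("extract_trace matches the per-frame median oracle", {
  spec <- quiet_spec(n_cells = 1, n_frames = 3, ratio_baseline = 2, alpha = 0.55)
  sim <- simulate_fret_movie(spec, seed = 71)
  mask <- sim$scene$masks[[1]]
  cfg <- acquisition_config(bleedthrough_alpha = 0.55)

  tr <- extract_trace(sim$movie, mask, "ratio", config = cfg)
  expect_equal(tr$values, rep(2, 3), tolerance = 1e-9)

  # intensity quantity against a direct median oracle
  tr_i <- extract_trace(sim$movie, mask, "intensity", channel = "marker",
                        config = cfg)
  oracle <- vapply(1:3, function(t) {
    img <- movie_frame(sim$movie, "marker", t)
    img <- img - background_correct(img)$background
    median(img[mask])
  }, numeric(1))
  expect_equal(tr_i$values, oracle)

  # an empty mask at one frame flags that frame missing
  masks <- list(mask, mask & FALSE, mask)
  tr_m <- extract_trace(sim$movie, masks, "ratio", config = cfg)
  expect_true(is.na(tr_m$values[2]))
  expect_false(anyNA(tr_m$values[c(1, 3)]))

  expect_error(extract_trace(sim$movie, mask & FALSE, "ratio", config = cfg),
               "empty")
})

test_that("baseline normalisation turns ratios into percent change", {
  tt <- seq(0, 50, by = 10)
  tr <- fret_trace(1, "ratio", c(2, 2, 2, 2.8, 2.8, 2.8), tt)
  norm <- normalize_trace(tr, stimulus_event(25))
  expect_equal(norm$values, c(0, 0, 0, 40, 40, 40))
  expect_identical(norm$quantity, "percent_change")

  flat <- fret_trace(1, "ratio", rep(1.7, 6), tt)
  expect_equal(normalize_trace(flat, stimulus_event(25))$values, rep(0, 6))

  expect_error(normalize_trace(tr, stimulus_event(5)), "pre-event")
})

test_that("t_half matches trivial and dense-grid oracles", {
  # linear ramp 0 -> 100% over 40 s after the event: t_half = 20 s
  tt <- seq(0, 100, by = 5)
  ramp <- pmin(pmax((tt - 40) / 40, 0), 1) * 100
  kin <- t_half(fret_trace(1, "percent_change", ramp, tt), stimulus_event(40))
  expect_equal(kin$t_half_s, 20)
  expect_equal(kin$amplitude_percent, 100)

  # exponential rises across a 10-fold rate range vs the dense-grid oracle
  for (k in log(2) / c(5, 15, 50)) {
    spec <- scene_spec(duration_s = 300, frame_interval_s = 5,
                       event_times_s = c(60, 280), amplitude = 0.4, k_on = k)
    times <- scene_frame_times(spec)
    r <- simulate_response_kinetics(spec, times)
    norm <- normalize_trace(fret_trace(1, "ratio", r, times), stimulus_event(60))
    kin <- t_half(norm, stimulus_event(60), window_end_s = 280)
    oracle <- dense_t_half_oracle(times, norm$values, 60, 280)
    expect_lt(abs(kin$t_half_s - oracle), 5 / 2)   # within half a frame
  }

  # monotone-decreasing post-event trace: flagged, not a number
  dec <- fret_trace(1, "percent_change", seq(0, -50, length.out = 21), tt)
  kin <- t_half(dec, stimulus_event(40))
  expect_true(kin$no_response)
  expect_true(is.na(kin$t_half_s))
})

test_that("t_half is invariant to unit scaling and time-origin shifts", {
  withr::with_seed(72, {
    tt <- seq(0, 200, by = 5)
    vals <- 40 * (1 - exp(-pmax(tt - 50, 0) / 30)) + rnorm(length(tt), sd = 0.5)
  })
  base <- t_half(fret_trace(1, "percent_change", vals, tt), stimulus_event(50))
  scaled <- t_half(fret_trace(1, "percent_change", vals / 100, tt),
                   stimulus_event(50))
  expect_equal(scaled$t_half_s, base$t_half_s)
  shifted <- t_half(fret_trace(1, "percent_change", vals, tt + 1000),
                    stimulus_event(1050))
  expect_equal(shifted$t_half_s, base$t_half_s)
})

test_that("cx_cb_statistic recovers constructed gradients and their sign", {
  disk <- fretkit:::rasterize_ellipse(60, 60, 30, 30, 22, 22)
  bands <- cortex_band(disk, 5)
  d <- matrix(100, 60, 60)

  # uniform field: delta exactly zero
  s <- matrix(0, 60, 60); s[disk] <- 150
  st <- cx_cb_statistic(s, d, disk)
  expect_equal(st$delta, 0)

  # cortex 2.0, body 1.5 by construction
  s2 <- matrix(0, 60, 60)
  s2[bands$cortex] <- 200; s2[bands$body] <- 150
  st2 <- cx_cb_statistic(s2, d, disk)
  expect_equal(st2$ratio_cx, 2.0)
  expect_equal(st2$ratio_cb, 1.5)
  expect_equal(st2$delta, 0.5)

  # inverted field: antisymmetric delta
  s3 <- matrix(0, 60, 60)
  s3[bands$cortex] <- 150; s3[bands$body] <- 200
  expect_equal(cx_cb_statistic(s3, d, disk)$delta, -0.5)
})

test_that("expression gate applies inclusive bounds on the marker mean", {
  mask <- matrix(TRUE, 5, 5)
  gate <- expression_gate_spec(50, 300)
  expect_true(expression_gate(matrix(100, 5, 5), mask, gate))
  expect_false(expression_gate(matrix(40, 5, 5), mask, gate))
  expect_true(expression_gate(matrix(300, 5, 5), mask, gate))
  expect_true(expression_gate(matrix(50, 5, 5), mask, gate))
  expect_false(expression_gate(matrix(300.5, 5, 5), mask, gate))
  expect_error(expression_gate(matrix(1, 5, 5), mask & FALSE, gate), "empty")
  expect_error(expression_gate_spec(300, 50), "lo < hi")
})

test_that("control normalisation reports fold changes over the control mean", {
  out <- normalize_to_control(c(200), c(100, 100))
  expect_equal(out$fold, 2)
  out <- normalize_to_control(c(100, 100), c(100, 100))
  expect_equal(out$fold, c(1, 1))
  expect_equal(out$group_mean, 1)
  expect_error(normalize_to_control(c(1), c(0)), "positive")
})
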