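# Forward-model synthetic movie generator. Renders multi-channel time-lapse
# movies of neuronal-like cells (elliptical bodies with thin neurites)
# carrying a ratiometric FRET biosensor, with known ground truth for every
# analysis stage: ratio fields, stimulus kinetics, marker recruitment,
# neurite retraction, bleedthrough, registration offsets and camera noise.
#
# Intensity model per in-cell pixel: the biosensor emits a fixed total budget
# T0 split by the local ratio R, donor = T0/(1+R) and sensitized =
# T0*R/(1+R), so acceptor/donor is exactly R before instrument effects. The
# recorded acceptor channel is sensitized + alpha*donor; background is added
# and shot (Poisson) plus read (Gaussian) noise applied, gain 1 count/photon.

#' Synthetic scene specification
#'
#' Describes one synthetic experiment: geometry, biosensor ratio pattern,
#' stimulus kinetics, marker behaviour, retraction schedule, noise and
#' instrument effects. Defaults emulate a widefield recording of 2-3
#' non-migrating neuronal cells: agonist at 60 s driving a 40% ratio rise
#' with a ~20 s half-time, antagonist at 240 s reversing it with a ~60 s
#' half-time, 5 s frame interval, camera background 100 counts with shot and
#' 2-count read noise, 55% donor bleedthrough.
#'
#' @param image_size `c(H, W)` in pixels.
#' @param n_cells number of cells (1-4, auto-laid-out on a safe grid).
#' @param total_intensity T0, the per-pixel donor+sensitized photon budget
#'   inside cells (camera counts).
#' @param ratio_baseline R0, the resting acceptor/donor ratio.
#' @param pattern spatial ratio pattern: `"uniform"`, `"cortex_enriched"` or
#'   `"body_enriched"`.
#' @param pattern_magnitude fractional ratio elevation of the enriched
#'   compartment (default 0.3, i.e. 30% higher).
#' @param pattern_band_width width in px of the cortical band used by the
#'   enriched patterns (default 5, matching the analysis band).
#' @param event_times_s stimulus times `c(agonist, antagonist)`; use a
#'   length-1 vector for single-stimulus scenes or `NULL` for none.
#' @param amplitude A, fractional peak ratio increase after the agonist
#'   (default 0.4 for a 40% response).
#' @param k_on,k_off rise and decay rate constants (1/s); defaults give
#'   half-times of ~20 s and ~60 s.
#' @param retraction_fraction final cell area as a fraction of baseline
#'   (1 = no retraction; 0.8-0.9 emulates the observed 10-20% loss).
#' @param retraction_duration_s time over which the area declines linearly
#'   after the stimulus.
#' @param recruitment_rate cytosol-to-compartment transfer rate (1/s) for the
#'   marker after the stimulus (0 = static marker).
#' @param recruitment_compartment `"rim"` (plasma-membrane band) or
#'   `"center"` (nuclear stand-in, the 9-px-eroded core).
#' @param marker_level mean marker intensity inside cells (counts; default
#'   150, inside the 50-300 expression gate).
#' @param background_mean,read_sd,shot_noise camera model.
#' @param alpha donor bleedthrough fraction (default 0.55, widefield).
#' @param registration_offset integer `c(dy, dx)` displacement applied to the
#'   acceptor channel.
#' @param frame_interval_s,duration_s time base (default 5 s frames, 400 s).
#' @param neurite_width,neurite_length neurite geometry in pixels.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = c(160L, 160L),
                       n_cells = 3L,
                       total_intensity = 1000,
                       ratio_baseline = 1.0,
                       pattern = c("uniform", "cortex_enriched", "body_enriched"),
                       pattern_magnitude = 0.3,
                       pattern_band_width = 5L,
                       event_times_s = c(60, 240),
                       amplitude = 0.4,
                       k_on = log(2) / 20,
                       k_off = log(2) / 60,
                       retraction_fraction = 1.0,
                       retraction_duration_s = 120,
                       recruitment_rate = 0,
                       recruitment_compartment = c("rim", "center"),
                       marker_level = 150,
                       background_mean = 100,
                       read_sd = 2,
                       shot_noise = TRUE,
                       alpha = 0.55,
                       registration_offset = c(0L, 0L),
                       frame_interval_s = 5,
                       duration_s = 400,
                       neurite_width = 5,
                       neurite_length = 26,
                       n_neurites = 2L) {
  pattern <- match.arg(pattern)
  recruitment_compartment <- match.arg(recruitment_compartment)
  if (alpha < 0 || alpha >= 1) stop_fretkit("alpha must lie in [0, 1)")
  if (retraction_fraction <= 0 || retraction_fraction > 1)
    stop_fretkit("retraction_fraction must lie in (0, 1]")
  if (k_on < 0 || k_off < 0 || recruitment_rate < 0)
    stop_fretkit("rates must be >= 0")
  if (!is.null(event_times_s) && any(event_times_s < 0 | event_times_s > duration_s))
    stop_fretkit("event times must lie within the movie")
  structure(as.list(environment()), class = "scene_spec")
}

#' Frame times of a scene
#' @param spec a [scene_spec()].
#' @export
scene_frame_times <- function(spec) seq(0, spec$duration_s, by = spec$frame_interval_s)

#' Rasterize the cell geometry of a scene
#'
#' Lays out `n_cells` elliptical bodies with one thin neurite each (pointing
#' toward the image centre so geometry never clips the border), rasterizes
#' body+neurite masks, and emits seed points at the body centroids.
#' Deterministic for a fixed seed. Cells must stay >= 5 px from the border
#' and must not touch each other.
#'
#' @param spec a [scene_spec()].
#' @param seed integer RNG seed.
#' @return list with `masks` (list of logical matrices, one per cell),
#'   `body_masks`, `seeds` (a [seed_set()]) and `label_map`.
#' @export
make_cell_scene <- function(spec, seed = 1L) {
  h <- spec$image_size[1L]; w <- spec$image_size[2L]
  centers <- list(c(0.22, 0.22), c(0.22, 0.78), c(0.78, 0.22), c(0.78, 0.78))
  if (spec$n_cells > length(centers))
    stop_fretkit("auto layout supports at most ", length(centers), " cells")
  with_seed(seed, {
    masks <- vector("list", spec$n_cells)
    body_masks <- vector("list", spec$n_cells)
    srow <- scol <- integer(spec$n_cells)
    for (i in seq_len(spec$n_cells)) {
      cy <- centers[[i]][1L] * h + stats::runif(1, -3, 3)
      cx <- centers[[i]][2L] * w + stats::runif(1, -3, 3)
      # semi-axes >= 15 keep a nonempty core under the 9-px (Chebyshev)
      # center erosion used for recruitment readouts
      ay <- stats::runif(1, 15, 17); ax <- stats::runif(1, 15, 17)
      body <- rasterize_ellipse(h, w, cy, cx, ay, ax)
      # neurites: fan out around the direction toward the image centre, so
      # geometry never clips the border or a neighbouring cell
      base_ang <- atan2(h / 2 - cy, w / 2 - cx)
      offsets <- if (spec$n_neurites == 1L) 0 else
        seq(-20, 20, length.out = spec$n_neurites) * pi / 180
      cell <- body
      for (ang_off in offsets) {
        ang <- base_ang + ang_off + stats::runif(1, -0.04, 0.04)
        dirv <- c(sin(ang), cos(ang))
        p0 <- c(cy, cx) + dirv * max(ay, ax) * 0.8
        p1 <- p0 + dirv * spec$neurite_length
        cell <- cell | rasterize_segment_band(h, w, p0, p1, spec$neurite_width / 2)
      }
      masks[[i]] <- cell
      body_masks[[i]] <- body
      srow[i] <- as.integer(round(cy)); scol[i] <- as.integer(round(cx))
    }
    label_map <- matrix(0L, h, w)
    for (i in seq_len(spec$n_cells)) {
      if (any(label_map[masks[[i]]] != 0L) ||
          any(dilate_once(masks[[i]]) & label_map > 0L))
        stop_fretkit("cells overlap or touch; supply explicit geometry/barriers")
      rr <- which(masks[[i]], arr.ind = TRUE)
      if (any(rr[, 1L] <= 5L | rr[, 1L] >= h - 4L | rr[, 2L] <= 5L | rr[, 2L] >= w - 4L))
        stop_fretkit("cell ", i, " is closer than 5 px to the image border")
      label_map[masks[[i]]] <- i
    }
    list(masks = masks, body_masks = body_masks,
         seeds = seed_set(srow, scol, seq_len(spec$n_cells)),
         label_map = label_map)
  })
}

rasterize_ellipse <- function(h, w, cy, cx, ay, ax) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((rr - cy) / ay)^2 + ((cc - cx) / ax)^2 <= 1
}

# pixels within `radius` of the segment p0-p1 ((row, col) coordinates)
rasterize_segment_band <- function(h, w, p0, p1, radius) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  v <- p1 - p0
  len2 <- sum(v^2)
  tt <- ((rr - p0[1L]) * v[1L] + (cc - p0[2L]) * v[2L]) / len2
  tt <- pmin(pmax(tt, 0), 1)
  d2 <- (rr - (p0[1L] + tt * v[1L]))^2 + (cc - (p0[2L] + tt * v[2L]))^2
  d2 <= radius^2
}

#' Stimulus-response ratio kinetics
#'
#' The scalar ratio trajectory: `R0` before the agonist; a saturating
#' exponential rise `R0 * (1 + A * (1 - exp(-k_on (t - t_on))))` between
#' agonist and antagonist; after the antagonist the elevated component decays
#' as `exp(-k_off (t - t_off))`, continuous at the boundary.
#'
#' @param spec a [scene_spec()].
#' @param frame_times numeric vector of times (defaults to the scene's).
#' @return numeric vector `R(t)`.
#' @export
simulate_response_kinetics <- function(spec, frame_times = scene_frame_times(spec)) {
  R0 <- spec$ratio_baseline
  ev <- spec$event_times_s
  if (is.null(ev) || !length(ev) || spec$amplitude == 0)
    return(rep(R0, length(frame_times)))
  t_on <- ev[1L]
  t_off <- if (length(ev) >= 2L) ev[2L] else Inf
  r <- rep(R0, length(frame_times))
  rise <- frame_times >= t_on & frame_times < t_off
  r[rise] <- R0 * (1 + spec$amplitude * (1 - exp(-spec$k_on * (frame_times[rise] - t_on))))
  if (is.finite(t_off)) {
    level_off <- spec$amplitude * (1 - exp(-spec$k_on * (t_off - t_on)))
    fall <- frame_times >= t_off
    r[fall] <- R0 * (1 + level_off * exp(-spec$k_off * (frame_times[fall] - t_off)))
  }
  r
}

# spatial ratio field for one cell at scalar ratio r_t
ratio_field_for_mask <- function(spec, mask, r_t) {
  field <- matrix(0, nrow(mask), ncol(mask))
  field[mask] <- r_t
  if (spec$pattern != "uniform") {
    bands <- tryCatch(cortex_band(mask, spec$pattern_band_width),
                      error = function(e) NULL)
    if (!is.null(bands)) {
      target <- if (spec$pattern == "cortex_enriched") bands$cortex else bands$body
      field[target] <- field[target] * (1 + spec$pattern_magnitude)
    }
  }
  field
}

#' Render a movie from ground-truth geometry and kinetics
#'
#' Applies the total-intensity forward model per pixel, the instrument model
#' (bleedthrough, acceptor registration offset, background, shot and read
#' noise), and assembles donor/acceptor/marker channels. Per-frame masks and
#' per-frame marker fields override the static geometry when supplied (used
#' by the retraction and recruitment generators).
#'
#' @param ground_truth output of [make_cell_scene()].
#' @param spec the [scene_spec()].
#' @param seed integer RNG seed (noise realisation).
#' @param masks_t optional list (cells) of lists (frames) of masks.
#' @param marker_fields optional list (frames) of marker intensity matrices
#'   (pre-noise, background-free).
#' @param ratio_t optional matrix (cells x frames) of scalar ratios
#'   (defaults to [simulate_response_kinetics()] for every cell).
#' @return list with `movie` (a [fret_movie()]) and `truth` (sidecar list:
#'   per-cell true ratio trajectory, true areas, seeds, SNR, the spec).
#' @export
render_fret_movie <- function(ground_truth, spec, seed = 1L, masks_t = NULL,
                              marker_fields = NULL, ratio_t = NULL) {
  h <- spec$image_size[1L]; w <- spec$image_size[2L]
  times <- scene_frame_times(spec)
  n_t <- length(times)
  n_c <- length(ground_truth$masks)
  if (is.null(ratio_t)) {
    r <- simulate_response_kinetics(spec, times)
    ratio_t <- matrix(rep(r, each = n_c), n_c, n_t)
  }
  donor <- array(0, dim = c(h, w, n_t))
  accept <- array(0, dim = c(h, w, n_t))
  marker <- array(0, dim = c(h, w, n_t))
  areas <- matrix(0, n_c, n_t)
  for (t in seq_len(n_t)) {
    d_f <- matrix(0, h, w); s_f <- matrix(0, h, w); m_f <- matrix(0, h, w)
    for (i in seq_len(n_c)) {
      m <- if (is.null(masks_t)) ground_truth$masks[[i]] else masks_t[[i]][[t]]
      areas[i, t] <- sum(m)
      if (!any(m)) next
      rf <- ratio_field_for_mask(spec, m, ratio_t[i, t])
      d_f[m] <- spec$total_intensity / (1 + rf[m])
      s_f[m] <- spec$total_intensity * rf[m] / (1 + rf[m])
      if (is.null(marker_fields)) m_f[m] <- spec$marker_level
    }
    if (!is.null(marker_fields)) m_f <- marker_fields[[t]]
    a_f <- s_f + spec$alpha * d_f
    off <- spec$registration_offset
    if (off[1L] != 0L || off[2L] != 0L)
      a_f <- shift_image(a_f, off[1L], off[2L], fill = 0)
    donor[, , t] <- d_f + spec$background_mean
    accept[, , t] <- a_f + spec$background_mean
    marker[, , t] <- m_f + spec$background_mean
  }
  add_noise <- function(x) {
    if (spec$shot_noise) x[] <- stats::rpois(length(x), lambda = x)
    if (spec$read_sd > 0) x <- x + stats::rnorm(length(x), sd = spec$read_sd)
    x
  }
  noisy <- with_seed(seed, list(donor = add_noise(donor),
                                acceptor = add_noise(accept),
                                marker = add_noise(marker)))
  donor <- noisy$donor; accept <- noisy$acceptor; marker <- noisy$marker
  sigma_bg <- sqrt((if (spec$shot_noise) spec$background_mean else 0) +
                     spec$read_sd^2)
  movie <- fret_movie(list(donor = donor, acceptor = accept, marker = marker),
                      times)
  truth <- list(spec = spec, seed = seed, frame_times_s = times,
                ratio_t = ratio_t, areas_px = areas,
                seeds = ground_truth$seeds,
                snr = if (sigma_bg > 0) spec$total_intensity / sigma_bg else Inf,
                sigma_bg = sigma_bg)
  list(movie = movie, truth = truth)
}

#' Simulate a complete stimulus-response FRET movie
#'
#' Convenience wrapper: geometry + kinetics + rendering in one call.
#'
#' @param spec a [scene_spec()].
#' @param seed integer RNG seed.
#' @return list with `movie`, `truth` and `scene` (the geometry).
#' @export
simulate_fret_movie <- function(spec, seed = 1L) {
  scene <- make_cell_scene(spec, seed)
  out <- render_fret_movie(scene, spec, seed)
  out$scene <- scene
  out
}

#' Simulate a neurite-retraction movie
#'
#' After the first stimulus the true cell area declines linearly to
#' `retraction_fraction` of baseline over `retraction_duration_s`, by
#' removing neurite pixels farthest (in dilation distance) from the cell
#' body first -- i.e. neurites retract from their tips; the body is
#' preserved. Per-frame true areas track the schedule to within one pixel.
#'
#' @param spec a [scene_spec()] with `retraction_fraction < 1` (a fraction of
#'   1 renders a static control scene).
#' @param seed integer RNG seed.
#' @return list with `movie`, `truth` (including `areas_px` ground truth) and
#'   `scene`.
#' @export
simulate_retraction_movie <- function(spec, seed = 1L) {
  scene <- make_cell_scene(spec, seed)
  times <- scene_frame_times(spec)
  t_on <- if (length(spec$event_times_s)) spec$event_times_s[1L] else Inf
  frac <- retraction_schedule(times, t_on, spec$retraction_fraction,
                              spec$retraction_duration_s)
  masks_t <- lapply(seq_along(scene$masks), function(i) {
    removal_order <- neurite_removal_order(scene$masks[[i]], scene$body_masks[[i]])
    a0 <- sum(scene$masks[[i]])
    body_area <- sum(scene$body_masks[[i]])
    lapply(seq_along(times), function(t) {
      target <- round(frac[t] * a0)
      if (target < body_area)
        stop_fretkit("retraction target below body area; schedule infeasible")
      m <- scene$masks[[i]]
      n_remove <- a0 - target
      if (n_remove > 0) m[removal_order[seq_len(n_remove)]] <- FALSE
      m
    })
  })
  out <- render_fret_movie(scene, spec, seed, masks_t = masks_t)
  out$truth$area_fraction <- frac
  out$scene <- scene
  out
}

retraction_schedule <- function(times, t_on, target, duration) {
  frac <- rep(1, length(times))
  if (target >= 1 || !is.finite(t_on)) return(frac)
  ramp <- times >= t_on & times < t_on + duration
  frac[ramp] <- 1 - (1 - target) * (times[ramp] - t_on) / duration
  frac[times >= t_on + duration] <- target
  frac
}

# neurite pixels ordered tip-first by dilation distance from the body
neurite_removal_order <- function(mask, body) {
  neur <- mask & !body
  if (!any(neur)) return(integer(0))
  dist <- matrix(NA_integer_, nrow(mask), ncol(mask))
  reached <- body
  d <- 0L
  while (any(neur & is.na(dist))) {
    d <- d + 1L
    reached <- dilate_once(reached) & mask
    newly <- neur & reached & is.na(dist)
    if (!any(newly)) { dist[neur & is.na(dist)] <- d; break }
    dist[newly] <- d
  }
  idx <- which(neur)
  idx[order(-dist[idx], -idx)]
}

#' Simulate a marker recruitment / translocation movie
#'
#' The marker is partitioned between a uniform cytosolic pool and a target
#' compartment (plasma-membrane rim band, or the eroded center as a nuclear
#' stand-in). After the stimulus the cytosolic fraction decays exponentially
#' with `recruitment_rate`; total marker per cell is conserved every frame.
#' FRET channels are rendered as usual (set `amplitude = 0` for an inert
#' sensor).
#'
#' @param spec a [scene_spec()] with `recruitment_rate > 0`.
#' @param seed integer RNG seed.
#' @return list with `movie`, `truth` (including `cytosol_fraction` ground
#'   truth) and `scene`.
#' @export
simulate_recruitment_movie <- function(spec, seed = 1L) {
  scene <- make_cell_scene(spec, seed)
  times <- scene_frame_times(spec)
  t_on <- if (length(spec$event_times_s)) spec$event_times_s[1L] else Inf
  f_cyt <- rep(1, length(times))
  after <- times >= t_on
  f_cyt[after] <- exp(-spec$recruitment_rate * (times[after] - t_on))
  h <- spec$image_size[1L]; w <- spec$image_size[2L]
  comp_masks <- lapply(seq_along(scene$masks), function(i) {
    m <- scene$masks[[i]]
    if (spec$recruitment_compartment == "rim")
      cortex_band(scene$body_masks[[i]], spec$pattern_band_width)$cortex
    else erode_region(scene$body_masks[[i]], 9)
  })
  marker_fields <- lapply(seq_along(times), function(t) {
    fld <- matrix(0, h, w)
    for (i in seq_along(scene$masks)) {
      m <- scene$masks[[i]]
      comp <- comp_masks[[i]]
      total <- spec$marker_level * sum(m)   # budget scales with cell size
      fld[m] <- fld[m] + total * f_cyt[t] / sum(m)
      if (any(comp)) fld[comp] <- fld[comp] + total * (1 - f_cyt[t]) / sum(comp)
    }
    fld
  })
  out <- render_fret_movie(scene, spec, seed, marker_fields = marker_fields)
  out$truth$cytosol_fraction <- f_cyt
  out$truth$marker_fields <- marker_fields
  out$truth$compartment_masks <- comp_masks
  out$scene <- scene
  out
}

#' Simulate FLIM samples and emission spectra
#'
#' FLIM: phases generated by the forward model `phi = arctan(2 pi f tau)`
#' plus Gaussian jitter, one sample per simulated cell, for each target
#' lifetime (defaults 2.9 and 2.4 ns, the bound/unbound donor lifetimes at
#' 75.1 MHz). Spectra: weighted mixtures of two-peak donor (475 nm) and
#' acceptor (530 nm) emission templates with additive noise, plus the
#' acceptor-band reference intensity for expression normalisation.
#'
#' @param n_cells samples per group.
#' @param lifetimes_ns vector of target lifetimes.
#' @param frequency_hz modulation frequency (default 75.1 MHz).
#' @param phase_jitter_sd_rad Gaussian phase jitter (default 0.002 rad).
#' @param acceptor_weight relative acceptor peak weight in the spectrum
#'   (higher = more FRET).
#' @param spectrum_noise_sd additive spectral noise s.d.
#' @param seed integer RNG seed.
#' @return list with `flim` (data.frame: tau_true_ns, phase_rad,
#'   tau_est_ns), `spectra` (list of [emission_spectrum()]),
#'   `yfp_reference` (per-cell reference intensities), `wavelengths_nm`,
#'   `template` (noise-free mixture).
#' @export
simulate_flim_and_spectra <- function(n_cells = 20L,
                                      lifetimes_ns = c(2.9, 2.4),
                                      frequency_hz = 75.1e6,
                                      phase_jitter_sd_rad = 0.002,
                                      acceptor_weight = 0.8,
                                      spectrum_noise_sd = 0.02,
                                      seed = 1L) {
  wl <- seq(450, 600, by = 2)
  donor_tpl <- exp(-((wl - 475)^2) / (2 * 15^2)) + 0.35 * exp(-((wl - 501)^2) / (2 * 20^2))
  accept_tpl <- exp(-((wl - 530)^2) / (2 * 14^2))
  template <- donor_tpl + acceptor_weight * accept_tpl
  yfp_band <- wl >= 520 & wl <= 540
  with_seed(seed, {
    flim <- do.call(rbind, lapply(lifetimes_ns, function(tau) {
      phi <- phase_from_lifetime(tau, frequency_hz) +
        stats::rnorm(n_cells, sd = phase_jitter_sd_rad)
      data.frame(tau_true_ns = tau, phase_rad = phi,
                 tau_est_ns = phase_lifetime(phi, frequency_hz))
    }))
    spectra <- vector("list", n_cells)
    yfp_reference <- numeric(n_cells)
    for (i in seq_len(n_cells)) {
      expression_scale <- stats::runif(1, 0.5, 2)   # cell-to-cell expression
      raw <- expression_scale * template +
        stats::rnorm(length(wl), sd = spectrum_noise_sd * expression_scale)
      spectra[[i]] <- emission_spectrum(wl, raw)
      yfp_reference[i] <- mean(raw[yfp_band])
    }
    list(flim = flim, spectra = spectra, yfp_reference = yfp_reference,
         wavelengths_nm = wl, template = template)
  })
}

#' Write a ground-truth sidecar as JSON
#'
#' Serialises the scalar ground truth of a simulated scene (spec, seed, frame
#' times, per-cell ratio trajectories and areas, SNR, seed points) next to
#' the movie so analyses can be validated without re-running the generator.
#' Pixel masks are not serialised; they are reproducible from (spec, seed).
#'
#' @param truth the `truth` element returned by the simulators.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- list(
    spec = unclass(truth$spec),
    seed = truth$seed,
    frame_times_s = truth$frame_times_s,
    ratio_t = truth$ratio_t,
    areas_px = truth$areas_px,
    area_fraction = truth$area_fraction,
    cytosol_fraction = truth$cytosol_fraction,
    snr = truth$snr,
    sigma_bg = truth$sigma_bg,
    seeds = list(rows = truth$seeds$rows, cols = truth$seeds$cols,
                 labels = truth$seeds$labels))
  jsonlite::write_json(out[!vapply(out, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
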