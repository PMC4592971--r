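# Shared fixtures: small fast scenes and independent oracles used across
# test files. Everything is generated in code; no binary fixtures.

# a compact noiseless scene: 1-2 cells, few frames, no instrument effects
quiet_spec <- function(n_cells = 1, n_frames = 2, ...) {
  args <- list(...)
  defaults <- list(n_cells = n_cells,
                   duration_s = (n_frames - 1) * 10, frame_interval_s = 10,
                   event_times_s = NULL, amplitude = 0,
                   shot_noise = FALSE, read_sd = 0, background_mean = 50)
  do.call(scene_spec, utils::modifyList(defaults, args))
}

# default camera noise, otherwise like quiet_spec
noisy_spec <- function(n_cells = 1, n_frames = 2, ...) {
  quiet_spec(n_cells, n_frames, shot_noise = TRUE, read_sd = 2,
             background_mean = 100, ...)
}

# corrected donor + sensitized frames for one frame of a movie
corrected_frames <- function(movie, t, alpha) {
  d <- background_correct(movie_frame(movie, "donor", t))$corrected
  a <- background_correct(movie_frame(movie, "acceptor", t))$corrected
  list(donor = d, sensitized = correct_bleedthrough(a, d, alpha))
}

# independent dense-grid half-rise oracle: resample the trace on a grid of
# step dt/1000 by linear interpolation and report the first crossing of half
# the post-event maximum, relative to the event time
dense_t_half_oracle <- function(times, values, event_time, window_end = max(times)) {
  dt <- min(diff(times)) / 1000
  grid <- seq(min(times), window_end, by = dt)
  vg <- stats::approx(times, values, xout = grid)$y
  in_win <- grid > event_time & grid <= window_end
  peak <- max(vg[in_win], na.rm = TRUE)
  if (peak <= 0) return(NA_real_)
  cross <- grid[in_win][which(vg[in_win] >= peak / 2)[1L]]
  cross - event_time
}

# brute-force 3x3 8-connected erosion oracle (single iteration)
erode_oracle_once <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    keep <- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; c2 <- cc + dc
      inside <- rr >= 1 && rr <= h && c2 >= 1 && c2 <= w
      if (!inside || !mask[rr, c2]) { keep <- FALSE; break }
    }
    out[r, cc] <- keep
  }
  out
}

erode_oracle <- function(mask, iterations) {
  for (i in seq_len(iterations)) mask <- erode_oracle_once(mask)
  mask
}

random_mask <- function(h = 16, w = 16, p = 0.6) {
  matrix(stats::runif(h * w) < p, h, w)
}
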