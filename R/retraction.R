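# Neurite-retraction analysis for non-migrating neuronal cells: starting
# regions from the summed time series, per-frame thresholded cell regions,
# the area/retraction trace, and localised FRET + recruitment traces.

#' Starting regions from the summed time series
#'
#' Because the cells do not migrate over the experiment, one watershed of the
#' time-summed segmentation channel yields a fixed starting region per cell.
#' A seed that floods only the background basin is dropped with a warning.
#'
#' @param movie a `fret_movie`.
#' @param seeds a [seed_set()].
#' @param channel segmentation channel: `"donor+acceptor"` (default, sum of
#'   both) or a single channel name.
#' @param smoothing_sigma Gaussian sigma for the watershed landscape.
#' @return integer label map.
#' @export
starting_regions <- function(movie, seeds, channel = "donor+acceptor",
                             smoothing_sigma = 2) {
  img <- if (channel == "donor+acceptor") {
    sum_time_series(movie$channels$donor) + sum_time_series(movie$channels$acceptor)
  } else sum_time_series(movie$channels[[channel]])
  labels <- seeded_watershed(img, seeds, smoothing_sigma = smoothing_sigma)
  present <- sort(unique(labels[labels > 0L]))
  missing <- setdiff(seeds$labels, present)
  if (length(missing))
    warning("seed label(s) ", paste(missing, collapse = ", "),
            " flooded no region (seed in background basin?); excluded")
  labels
}

#' Per-frame cell regions via the fivefold-background-s.d. threshold
#'
#' For every time point, pixels inside the starting region brighter than
#' `bg_mean + 5 * bg_sd` form the cell region; background statistics are
#' taken from pixels outside all starting regions (recomputed per frame by
#' default). Empty frames are kept as empty masks.
#'
#' @param movie a `fret_movie`.
#' @param starting_regions integer label map.
#' @param channel intensity channel for thresholding (default
#'   `"donor+acceptor"`).
#' @param sd_factor threshold multiple of the background s.d. (default 5).
#' @param per_frame_background recompute background stats each frame
#'   (default `TRUE`); otherwise frame-1 statistics are reused.
#' @return named list, one element per cell label, each a list of `T` logical
#'   masks.
#' @export
cell_region_series <- function(movie, starting_regions, channel = "donor+acceptor",
                               sd_factor = 5, per_frame_background = TRUE) {
  labs <- sort(unique(starting_regions[starting_regions > 0L]))
  if (!length(labs)) stop_fretkit("label map contains no cells")
  n_t <- n_frames(movie)
  spec <- threshold_spec("background_sd", sd_factor = sd_factor)
  frame_img <- function(t) {
    if (channel == "donor+acceptor")
      movie_frame(movie, "donor", t) + movie_frame(movie, "acceptor", t)
    else movie_frame(movie, channel, t)
  }
  bg0 <- background_stats(frame_img(1L), exclude = starting_regions)
  out <- stats::setNames(vector("list", length(labs)), paste0("cell", labs))
  for (ci in seq_along(labs)) out[[ci]] <- vector("list", n_t)
  for (t in seq_len(n_t)) {
    img <- frame_img(t)
    bg <- if (per_frame_background)
      background_stats(img, exclude = starting_regions) else bg0
    for (ci in seq_along(labs)) {
      region <- starting_regions == labs[ci]
      out[[ci]][[t]] <- suppressWarnings(
        apply_threshold(img, region, spec, background = bg))
    }
  }
  out
}

#' Cell-area time series with the 10%-of-99th-percentile refinement
#'
#' Within each frame's cell region, only pixels above 10% of the region's
#' 99th-percentile intensity count towards the cell area; this captures
#' retraction of dim thin neurites robustly. `area_percent` is relative to
#' the mean area over the pre-event baseline frames.
#'
#' @param movie a `fret_movie`.
#' @param cell_regions list of per-frame masks for one cell
#'   (from [cell_region_series()]).
#' @param event the stimulus [stimulus_event()] defining the baseline window
#'   (all frames strictly before it); `NULL` uses all frames as baseline.
#' @param channel intensity channel (default `"donor+acceptor"`).
#' @param percentile,fraction threshold parameters (defaults 99 and 0.10).
#' @return list with `area_px` and `area_percent` [fret_trace()]s and the
#'   per-frame refined masks (`masks`).
#' @export
area_series <- function(movie, cell_regions, event = NULL,
                        channel = "donor+acceptor",
                        percentile = 99, fraction = 0.10) {
  n_t <- n_frames(movie)
  if (length(cell_regions) != n_t) stop_fretkit("need one region per frame")
  spec <- threshold_spec("fraction_of_percentile", fraction = fraction,
                         percentile = percentile)
  area <- rep(NA_real_, n_t)
  masks <- vector("list", n_t)
  for (t in seq_len(n_t)) {
    region <- cell_regions[[t]]
    if (!any(region)) { masks[[t]] <- region; area[t] <- 0; next }
    img <- if (channel == "donor+acceptor")
      movie_frame(movie, "donor", t) + movie_frame(movie, "acceptor", t)
    else movie_frame(movie, channel, t)
    masks[[t]] <- suppressWarnings(apply_threshold(img, region, spec))
    area[t] <- sum(masks[[t]])
  }
  tt <- movie$frame_times_s
  base_idx <- if (is.null(event)) seq_len(n_t) else which(tt < event$time_s)
  if (!length(base_idx)) stop_fretkit("no baseline frames before the event")
  baseline <- mean(area[base_idx], na.rm = TRUE)
  if (!is.finite(baseline) || baseline <= 0)
    stop_fretkit("baseline area is zero; cannot express retraction in percent")
  list(area_px = fret_trace(1L, "area_px", area, tt),
       area_percent = fret_trace(1L, "area_percent", 100 * area / baseline, tt),
       masks = masks)
}

#' Localized FRET ratio and recruitment traces for one cell
#'
#' Per frame: the FRET ratio (ratio of medians) over the thresholded cell
#' region, and the recruitment readout as the median marker intensity over
#' the cell center, obtained by eroding the cell region by `center_erosion`
#' pixels. Frames whose center erodes away are flagged missing.
#'
#' @param movie a `fret_movie`.
#' @param cell_regions list of per-frame masks for one cell.
#' @param config an [acquisition_config()].
#' @param center_erosion erosion depth for the center mask (default 9 px).
#' @param correct apply background/bleedthrough corrections (default `TRUE`).
#' @return list with `fret_ratio` and `recruitment` [fret_trace()]s.
#' @export
retraction_fret_series <- function(movie, cell_regions,
                                   config = acquisition_config(),
                                   center_erosion = 9, correct = TRUE) {
  n_t <- n_frames(movie)
  if (length(cell_regions) != n_t) stop_fretkit("need one region per frame")
  ratio <- rep(NA_real_, n_t)
  recruit <- rep(NA_real_, n_t)
  has_marker <- "marker" %in% names(movie$channels)
  for (t in seq_len(n_t)) {
    region <- cell_regions[[t]] > 0
    if (!any(region)) next
    d <- movie_frame(movie, "donor", t)
    a <- movie_frame(movie, "acceptor", t)
    if (correct) {
      d <- background_correct(d)$corrected
      a <- background_correct(a)$corrected
    }
    s <- correct_bleedthrough(a, d, config$bleedthrough_alpha)
    ratio[t] <- region_ratio(s, d, region)
    if (has_marker) {
      center <- suppressWarnings(erode_region(region, center_erosion))
      if (any(center)) {
        mk <- movie_frame(movie, "marker", t)
        if (correct) mk <- background_correct(mk)$corrected
        recruit[t] <- stats::median(mk[center])
      }
    }
  }
  tt <- movie$frame_times_s
  list(fret_ratio = fret_trace(1L, "ratio", ratio, tt),
       recruitment = fret_trace(1L, "intensity", recruit, tt))
}
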