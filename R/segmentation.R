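# Seeded watershed segmentation and the local threshold rules that carve
# per-frame cell regions, plus the morphological sub-regions (cortex band,
# eroded center) the spatial statistics are built on.

#' Sum a channel stack over time
#'
#' The summed time series is the segmentation landscape: cells that are dim in
#' single frames accumulate contrast, and non-migrating cells stay in place.
#'
#' @param stack `H x W x T` numeric array (or an `H x W` matrix).
#' @return `H x W` matrix of pixelwise sums.
#' @export
sum_time_series <- function(stack) {
  if (is.matrix(stack)) return(stack)
  if (!is.array(stack) || length(dim(stack)) != 3L)
    stop_fretkit("stack must be an H x W x T array")
  apply_sum <- rowSums(matrix(stack, nrow = prod(dim(stack)[1:2])))
  matrix(apply_sum, dim(stack)[1L], dim(stack)[2L])
}

#' Seed set for watershed segmentation
#'
#' @param rows,cols 1-based pixel coordinates of seed points.
#' @param labels unique positive integer labels, one per seed (defaults to
#'   `1..n`). Multiple seeds may share a label only if they land in the same
#'   basin.
#' @param barriers optional list of polylines (each an `n x 2` matrix of
#'   (row, col) vertices) drawn to separate touching cells; barrier pixels are
#'   excluded from flooding.
#' @export
seed_set <- function(rows, cols, labels = seq_along(rows), barriers = NULL) {
  if (length(rows) != length(cols) || length(rows) != length(labels))
    stop_fretkit("rows, cols and labels must have equal length")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 labels = as.integer(labels), barriers = barriers),
            class = "seed_set")
}

#' Seeded watershed segmentation
#'
#' Floods the inverted, Gaussian-smoothed intensity landscape from the seed
#' markers plus an automatic background marker (pixels below
#' `bg_mean + bg_sd_factor * bg_sd`, estimated on the full image), following
#' Meyer's priority-flood with a quantised bucket queue. Barrier polylines are
#' excluded from flooding, so labels cannot leak across them; barrier pixels
#' end up as background.
#'
#' @param intensity `H x W` matrix (typically a summed time series).
#' @param seeds a [seed_set()].
#' @param smoothing_sigma Gaussian sigma in pixels applied before inversion
#'   (default 2; 0 disables).
#' @param bg_sd_factor multiple of the background s.d. defining the automatic
#'   background marker (default 5).
#' @param n_levels quantisation levels for the flooding priority (default 64;
#'   label assignments are insensitive to the quantisation on smoothed
#'   landscapes, while runtime scales with it).
#' @return integer label map (`H x W`), 0 = background.
#' @export
seeded_watershed <- function(intensity, seeds, smoothing_sigma = 2,
                             bg_sd_factor = 5, n_levels = 64L) {
  check_matrix(intensity)
  h <- nrow(intensity); w <- ncol(intensity)
  if (!length(seeds$rows)) stop_fretkit("at least one seed is required")
  if (any(seeds$rows < 1L | seeds$rows > h | seeds$cols < 1L | seeds$cols > w))
    stop_fretkit("seed points must lie inside the image")

  sm <- gaussian_smooth(intensity, smoothing_sigma)
  elev <- -sm   # bright cells become basins
  rng <- range(elev)
  level <- if (diff(rng) > 0) {
    pmin(as.integer(floor((elev - rng[1L]) / diff(rng) * (n_levels - 1L))) + 1L,
         n_levels)
  } else matrix(1L, h, w)

  labels <- matrix(0L, h, w)
  barrier <- matrix(FALSE, h, w)
  for (poly in seeds$barriers %||% list()) {
    px <- rasterize_polyline(poly, h, w, width = 1)
    barrier[px] <- TRUE
  }

  bg_label <- max(seeds$labels) + 1L
  # background marker: pixels statistically indistinguishable from background.
  # The mode estimates the background level; its spread comes from the pixels
  # at or below the mode (cells only add bright pixels). On noiseless data the
  # s.d. collapses to 0, so a small fraction of the dynamic range keeps the
  # marker from degenerating to an exact-equality test.
  bg_mode <- modal_value(intensity)
  bg_sd <- stats::sd(intensity[intensity <= bg_mode])
  if (!is.finite(bg_sd)) bg_sd <- 0
  floor_band <- 0.02 * (max(intensity) - bg_mode)
  bg_marker <- sm < (bg_mode + max(bg_sd_factor * bg_sd, floor_band)) & !barrier

  seed_idx <- seeds$rows + (seeds$cols - 1L) * h
  if (any(barrier[seed_idx])) stop_fretkit("a seed lies on a barrier")
  # seeds sitting on background-marker pixels are in the background basin:
  # exclude them with a warning rather than flooding a one-pixel region
  on_bg <- bg_marker[seed_idx]
  if (any(on_bg)) {
    warning("seed label(s) ", paste(seeds$labels[on_bg], collapse = ", "),
            " lie in the background basin; excluded")
    seed_idx <- seed_idx[!on_bg]
    seeds$labels <- seeds$labels[!on_bg]
    if (!length(seed_idx)) stop_fretkit("all seeds lie in the background basin")
  }
  labels[seed_idx] <- seeds$labels
  labels[bg_marker & labels == 0L] <- bg_label

  # level-synchronous flood: at each quantised level, repeatedly assign every
  # still-unlabelled pixel of level <= cur that touches a labelled pixel
  # (8-connectivity), taking the smallest neighbouring label so cell seeds win
  # ridge ties over the background marker; equivalent to Meyer's clamped
  # priority flood and fully vectorised
  shifts <- expand.grid(dy = -1:1, dx = -1:1)
  shifts <- shifts[!(shifts$dy == 0 & shifts$dx == 0), ]
  for (cur in seq_len(n_levels)) {
    if (!any(labels == 0L & !barrier & level <= cur)) next
    repeat {
      candidate <- labels == 0L & !barrier & level <= cur
      if (!any(candidate)) break
      best_nb <- matrix(Inf, h, w)
      for (s in seq_len(nrow(shifts))) {
        nb <- shift_image(labels, shifts$dy[s], shifts$dx[s], fill = 0L)
        nb[nb == 0L] <- Inf
        best_nb <- pmin(best_nb, nb)
      }
      grow <- candidate & is.finite(best_nb)
      if (!any(grow)) break
      labels[grow] <- as.integer(best_nb[grow])
    }
  }

  labels[labels == bg_label] <- 0L
  # a label split across disconnected basins means two same-label seeds
  # flooded separate cells -- reject rather than silently merge
  for (lab in unique(seeds$labels)) {
    region <- labels == lab
    if (!any(region)) next
    comp <- connected_components(region)
    if (max(comp) > 1L) {
      n_seed_comps <- length(unique(comp[seed_idx[seeds$labels == lab]]))
      if (n_seed_comps > 1L)
        stop_fretkit("seeds sharing label ", lab, " landed in disconnected basins")
    }
  }
  labels
}

#' Rasterize a polyline into pixel indices
#'
#' Walks each segment at sub-pixel steps and collects covered pixels;
#' `width > 1` dilates the chain. Used for manual separation barriers.
#'
#' @param poly `n x 2` matrix of (row, col) vertices.
#' @param h,w image dimensions.
#' @param width chain thickness in pixels.
#' @return integer vector of linear pixel indices.
#' @keywords internal
rasterize_polyline <- function(poly, h, w, width = 1) {
  poly <- as.matrix(poly)
  pts <- NULL
  for (i in seq_len(nrow(poly) - 1L)) {
    p0 <- poly[i, ]; p1 <- poly[i + 1L, ]
    n_steps <- max(2L, ceiling(2 * max(abs(p1 - p0))) + 1L)
    tt <- seq(0, 1, length.out = n_steps)
    pts <- rbind(pts, cbind(p0[1L] + tt * (p1[1L] - p0[1L]),
                            p0[2L] + tt * (p1[2L] - p0[2L])))
  }
  rr <- pmin(pmax(round(pts[, 1L]), 1L), h)
  cc <- pmin(pmax(round(pts[, 2L]), 1L), w)
  idx <- unique(rr + (cc - 1L) * h)
  if (width > 1) {
    mask <- matrix(FALSE, h, w); mask[idx] <- TRUE
    for (i in seq_len(width - 1L)) mask <- dilate_once(mask)
    idx <- which(mask)
  }
  as.integer(idx)
}

dilate_once <- function(mask) {
  out <- mask
  for (dy in -1:1) for (dx in -1:1)
    if (dy || dx) out <- out | shift_image(mask, dy, dx, fill = FALSE)
  out
}

#' Threshold specification
#'
#' The three local threshold rules used to carve cell regions:
#' * `fraction_of_max`: keep pixels above `fraction` times the region maximum
#'   (the 15%-of-max rule).
#' * `background_sd`: keep pixels above `bg_mean + sd_factor * bg_sd`
#'   (the fivefold-background-s.d. rule).
#' * `fraction_of_percentile`: keep pixels above `fraction` times the region's
#'   `percentile` (linearly interpolated; the 10%-of-99th-percentile rule).
#'
#' @param rule one of `fraction_of_max`, `background_sd`,
#'   `fraction_of_percentile`.
#' @param fraction fraction in `(0, 1]` (rules 1 and 3).
#' @param sd_factor positive multiplier of the background s.d. (rule 2).
#' @param percentile percentile in `(0, 100]` (rule 3).
#' @export
threshold_spec <- function(rule = c("fraction_of_max", "background_sd",
                                    "fraction_of_percentile"),
                           fraction = 0.15, sd_factor = 5, percentile = 99) {
  rule <- match.arg(rule)
  if (fraction <= 0 || fraction > 1) stop_fretkit("fraction must be in (0, 1]")
  if (sd_factor <= 0) stop_fretkit("sd_factor must be > 0")
  if (percentile <= 0 || percentile > 100)
    stop_fretkit("percentile must be in (0, 100]")
  structure(list(rule = rule, fraction = fraction, sd_factor = sd_factor,
                 percentile = percentile), class = "threshold_spec")
}

#' Apply a local threshold rule inside a region
#'
#' @param intensity `H x W` matrix.
#' @param region logical (or labelled) matrix; thresholding is restricted to
#'   `region > 0`.
#' @param spec a [threshold_spec()].
#' @param background list with `mean` and `sd` (required for the
#'   `background_sd` rule; see [background_stats()]).
#' @return logical mask, subset of `region`. An empty result raises a warning,
#'   not an error (a retracting cell may vanish).
#' @export
apply_threshold <- function(intensity, region, spec, background = NULL) {
  check_matrix(intensity)
  region <- region > 0
  if (!any(region)) stop_fretkit("region is empty")
  vals <- intensity[region]
  cutoff <- switch(spec$rule,
    fraction_of_max = spec$fraction * max(vals),
    background_sd = {
      if (is.null(background))
        stop_fretkit("background stats required for the background_sd rule")
      background$mean + spec$sd_factor * background$sd
    },
    fraction_of_percentile =
      spec$fraction * stats::quantile(vals, spec$percentile / 100,
                                      names = FALSE, type = 7))
  out <- region & intensity > cutoff
  if (!any(out)) warning("threshold left an empty mask")
  out
}

#' Binary erosion by repeated single-pixel steps
#'
#' `iterations` applications of 3x3 (8-connected) erosion; "eroding by N
#' pixels" means N iterations. Pixels beyond the image border count as
#' background, so masks erode inwards from the frame edge too.
#'
#' @param mask logical matrix.
#' @param iterations non-negative integer.
#' @return eroded logical mask (warns if empty).
#' @export
erode_region <- function(mask, iterations) {
  if (iterations < 0) stop_fretkit("iterations must be >= 0")
  mask <- mask > 0
  for (i in seq_len(iterations)) {
    out <- mask
    for (dy in -1:1) for (dx in -1:1)
      if (dy || dx) out <- out & shift_image(mask, dy, dx, fill = FALSE)
    mask <- out
    if (!any(mask)) break
  }
  if (iterations > 0 && !any(mask)) warning("erosion left an empty mask")
  mask
}

#' Split a cell mask into cortex band and body
#'
#' The cortex is the `width`-pixel-wide outer band of the cell mask (mask
#' minus its `width`-fold erosion); the body is the erosion itself. The two
#' are disjoint and their union is the mask.
#'
#' @param cell_mask logical matrix.
#' @param width band width in pixels (`>= 1`).
#' @return list with logical masks `cortex` and `body`.
#' @export
cortex_band <- function(cell_mask, width = 5) {
  if (width < 1) stop_fretkit("width must be >= 1")
  cell_mask <- cell_mask > 0
  if (!any(cell_mask)) stop_fretkit("cell mask is empty")
  body <- suppressWarnings(erode_region(cell_mask, width))
  if (!any(body))
    stop_fretkit("cell thinner than twice the band width; no body region left")
  list(cortex = cell_mask & !body, body = body)
}
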