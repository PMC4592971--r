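# Stage-chaining entry points: the run_pipeline() dispatcher the CLI wraps,
# plus the per-analysis drivers. Every run writes a JSON log of the exact
# parameters used, so a run can be reproduced from its output directory.

#' Run an analysis pipeline stage
#'
#' Dispatches one of the five pipeline subcommands and writes its outputs
#' (traces CSV, per-cell statistics CSV, ratio-image TIFFs, ground truth and
#' a parameter log) into `out_dir`:
#'
#' * `simulate` -- render a synthetic movie from a [scene_spec()]; writes
#'   `movie.tif`, `truth.json`, `seeds.json` and a ready-to-run
#'   `config.json`.
#' * `calibrate-bleedthrough` -- estimate alpha from a donor-only movie and a
#'   mask TIFF; writes `calibration.json`.
#' * `analyze-gpcr` -- segmentation + per-cell ratio traces, normalisation
#'   and t-half per stimulus; writes `traces.csv` and `cells.csv`.
#' * `analyze-spatial` -- cortex-minus-body statistic per cell with
#'   expression gating; writes `cells.csv`.
#' * `analyze-retraction` -- the summed-series segmentation, per-frame
#'   thresholded regions, area/FRET/recruitment traces; writes `traces.csv`,
#'   `cells.csv` and ratio images.
#'
#' @param subcommand one of `simulate`, `calibrate-bleedthrough`,
#'   `analyze-gpcr`, `analyze-spatial`, `analyze-retraction`.
#' @param out_dir output directory (created if needed).
#' @param movie path to a movie TIFF, or a `fret_movie` (analysis stages).
#' @param config path to a JSON config, or the list from [load_config()].
#' @param seeds path to a seeds JSON, or a [seed_set()].
#' @param mask path to a mask TIFF, or a logical matrix
#'   (`calibrate-bleedthrough`).
#' @param spec a [scene_spec()] (`simulate`).
#' @param seed integer RNG seed (`simulate`).
#' @return invisibly, a list of the in-memory results written to disk.
#' @export
run_pipeline <- function(subcommand = c("simulate", "calibrate-bleedthrough",
                                        "analyze-gpcr", "analyze-spatial",
                                        "analyze-retraction"),
                         out_dir, movie = NULL, config = NULL, seeds = NULL,
                         mask = NULL, spec = NULL, seed = 1L) {
  subcommand <- match.arg(subcommand)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- resolve_config(config)
  log <- list(subcommand = subcommand, seed = seed,
              acquisition = unclass(cfg$acquisition),
              params = lapply(cfg$params, function(p)
                if (inherits(p, "expression_gate")) unclass(p) else p),
              events = lapply(cfg$events, unclass),
              package_version = as.character(utils::packageVersion("fretkit")))
  result <- switch(subcommand,
    "simulate" = pipeline_simulate(spec, seed, out_dir, cfg),
    "calibrate-bleedthrough" = pipeline_calibrate(movie, mask, cfg, out_dir),
    "analyze-gpcr" = pipeline_gpcr(movie, cfg, seeds, out_dir),
    "analyze-spatial" = pipeline_spatial(movie, cfg, seeds, out_dir),
    "analyze-retraction" = pipeline_retraction(movie, cfg, seeds, out_dir))
  log$outputs <- result$files
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(result)
}

resolve_config <- function(config) {
  if (is.null(config)) {
    list(acquisition = acquisition_config(), events = list(),
         params = list(cortex_band_width = 5L, center_erosion = 9L,
                       expression_gate = expression_gate_spec(),
                       smoothing_sigma = 2, region_statistic = "median"))
  } else if (is.character(config)) load_config(config) else config
}

resolve_movie <- function(movie, cfg) {
  if (is.null(movie)) stop_fretkit("this stage requires a movie (missing artifact: movie)")
  if (inherits(movie, "fret_movie")) return(movie)
  read_movie(movie, CHANNEL_NAMES,
             frame_interval_s = cfg$acquisition$frame_interval_s)
}

resolve_seeds <- function(seeds) {
  if (is.null(seeds))
    stop_fretkit("this stage requires seed points and auto-seeding is disabled ",
                 "(missing artifact: seeds)")
  if (inherits(seeds, "seed_set")) return(seeds)
  read_seeds(seeds)
}

#' Read a seeds/barriers JSON sidecar
#'
#' Expects `{"seeds": [{"label": k, "row": r, "col": c}, ...],
#' "barriers": [[[r, c], ...], ...]}` (0-based coordinates in the file,
#' converted to this package's 1-based convention).
#'
#' @param path JSON path.
#' @return a [seed_set()].
#' @export
read_seeds <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  s <- raw$seeds
  barriers <- NULL
  if (!is.null(raw$barriers) && length(raw$barriers))
    barriers <- lapply(raw$barriers, function(b) as.matrix(b) + 1)
  seed_set(s$row + 1L, s$col + 1L, s$label, barriers = barriers)
}

#' Write a seeds JSON sidecar (0-based coordinates)
#'
#' @param seeds a [seed_set()].
#' @param path output path.
#' @export
write_seeds <- function(seeds, path) {
  out <- list(seeds = data.frame(label = seeds$labels,
                                 row = seeds$rows - 1L,
                                 col = seeds$cols - 1L))
  if (!is.null(seeds$barriers))
    out$barriers <- lapply(seeds$barriers, function(b) unname(as.matrix(b) - 1))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

pipeline_simulate <- function(spec, seed, out_dir, cfg) {
  if (is.null(spec)) spec <- scene_spec()
  sim <- if (spec$retraction_fraction < 1) simulate_retraction_movie(spec, seed)
    else if (spec$recruitment_rate > 0) simulate_recruitment_movie(spec, seed)
    else simulate_fret_movie(spec, seed)
  files <- c(movie = file.path(out_dir, "movie.tif"),
             truth = file.path(out_dir, "truth.json"),
             seeds = file.path(out_dir, "seeds.json"),
             config = file.path(out_dir, "config.json"))
  write_movie(sim$movie, files[["movie"]])
  write_ground_truth(sim$truth, files[["truth"]])
  write_seeds(sim$scene$seeds, files[["seeds"]])
  events <- if (length(spec$event_times_s))
    lapply(seq_along(spec$event_times_s), function(i)
      list(time_s = spec$event_times_s[i],
           label = c("agonist", "antagonist")[min(i, 2L)]))
  else list()
  jsonlite::write_json(
    list(modality = "widefield", bleedthrough_alpha = spec$alpha,
         frame_interval_s = spec$frame_interval_s, events = events),
    files[["config"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(files = as.list(files), sim = sim)
}

pipeline_calibrate <- function(movie, mask, cfg, out_dir) {
  mv <- resolve_movie(movie, cfg)
  if (is.null(mask)) stop_fretkit("calibration requires a mask (missing artifact: mask)")
  if (is.character(mask)) mask <- read_tiff_stack(mask)[[1L]] > 0
  alpha <- calibrate_bleedthrough(mv, mask,
                                  donor_floor = cfg$acquisition$donor_floor)
  f <- file.path(out_dir, "calibration.json")
  jsonlite::write_json(list(bleedthrough_alpha = alpha), f,
                       auto_unbox = TRUE, digits = NA)
  list(files = list(calibration = f), alpha = alpha)
}

# shared front end: segment, then per-frame thresholded regions per cell
segment_movie <- function(mv, cfg, seeds) {
  labels <- starting_regions(mv, seeds,
                             smoothing_sigma = cfg$params$smoothing_sigma)
  regions <- cell_region_series(mv, labels)
  list(labels = labels, regions = regions)
}

pipeline_gpcr <- function(movie, cfg, seeds, out_dir) {
  mv <- resolve_movie(movie, cfg)
  seg <- segment_movie(mv, cfg, resolve_seeds(seeds))
  traces <- list(); rows <- list()
  for (nm in names(seg$regions)) {
    cid <- sub("^cell", "", nm)
    tr <- extract_trace(mv, seg$regions[[nm]], "ratio",
                        config = cfg$acquisition, cell_id = cid,
                        statistic = cfg$params$region_statistic)
    traces[[length(traces) + 1L]] <- tr
    if (length(cfg$events)) {
      norm <- normalize_trace(tr, cfg$events[[1L]])
      traces[[length(traces) + 1L]] <- norm
      for (ev_i in seq_along(cfg$events)) {
        ev <- cfg$events[[ev_i]]
        end_s <- if (ev_i < length(cfg$events))
          cfg$events[[ev_i + 1L]]$time_s else max(mv$frame_times_s)
        kin <- t_half(norm, ev, window_end_s = end_s)
        rows[[length(rows) + 1L]] <- data.frame(
          cell_id = cid, event = ev$label, t_half_s = kin$t_half_s,
          amplitude_percent = kin$amplitude_percent,
          no_response = kin$no_response)
      }
    }
  }
  files <- list(traces = file.path(out_dir, "traces.csv"))
  write_traces(traces, files$traces)
  stats_df <- if (length(rows)) do.call(rbind, rows) else data.frame()
  if (nrow(stats_df)) {
    files$cells <- file.path(out_dir, "cells.csv")
    utils::write.csv(stats_df, files$cells, row.names = FALSE)
  }
  list(files = files, traces = traces, cells = stats_df,
       labels = seg$labels)
}

pipeline_spatial <- function(movie, cfg, seeds, out_dir) {
  mv <- resolve_movie(movie, cfg)
  seg <- segment_movie(mv, cfg, resolve_seeds(seeds))
  acq <- cfg$acquisition
  rows <- list()
  for (nm in names(seg$regions)) {
    cid <- sub("^cell", "", nm)
    deltas <- cxs <- cbs <- c(); gate_ok <- NA
    for (t in seq_len(n_frames(mv))) {
      m <- seg$regions[[nm]][[t]]
      if (!any(m)) next
      d <- background_correct(movie_frame(mv, "donor", t))$corrected
      a <- background_correct(movie_frame(mv, "acceptor", t))$corrected
      s <- correct_bleedthrough(a, d, acq$bleedthrough_alpha)
      st <- tryCatch(cx_cb_statistic(s, d, m,
                                     band_width = cfg$params$cortex_band_width,
                                     statistic = cfg$params$region_statistic),
                     error = function(e) NULL)
      if (is.null(st)) next
      deltas <- c(deltas, st$delta); cxs <- c(cxs, st$ratio_cx)
      cbs <- c(cbs, st$ratio_cb)
      if (t == 1L && "marker" %in% names(mv$channels)) {
        mk <- background_correct(movie_frame(mv, "marker", t))$corrected
        gate_ok <- expression_gate(mk, m, cfg$params$expression_gate)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = cid, gated_in = gate_ok,
      ratio_cx = mean(cxs), ratio_cb = mean(cbs), delta = mean(deltas))
  }
  df <- do.call(rbind, rows)
  f <- file.path(out_dir, "cells.csv")
  utils::write.csv(df, f, row.names = FALSE)
  list(files = list(cells = f), cells = df, labels = seg$labels)
}

pipeline_retraction <- function(movie, cfg, seeds, out_dir) {
  mv <- resolve_movie(movie, cfg)
  seg <- segment_movie(mv, cfg, resolve_seeds(seeds))
  first_event <- if (length(cfg$events)) cfg$events[[1L]] else NULL
  traces <- list(); rows <- list(); ratio_tifs <- list()
  for (nm in names(seg$regions)) {
    cid <- sub("^cell", "", nm)
    ar <- area_series(mv, seg$regions[[nm]], event = first_event)
    fr <- retraction_fret_series(mv, seg$regions[[nm]], config = cfg$acquisition,
                                 center_erosion = cfg$params$center_erosion)
    for (tr in list(ar$area_px, ar$area_percent, fr$fret_ratio, fr$recruitment)) {
      tr$cell_id <- cid
      traces[[length(traces) + 1L]] <- tr
    }
    final <- ar$area_percent$values[n_frames(mv)]
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = cid, final_area_percent = final,
      mean_fret_ratio = mean(fr$fret_ratio$values, na.rm = TRUE))
  }
  # ratio image of the final frame for display
  d <- background_correct(movie_frame(mv, "donor", n_frames(mv)))$corrected
  a <- background_correct(movie_frame(mv, "acceptor", n_frames(mv)))$corrected
  s <- correct_bleedthrough(a, d, cfg$acquisition$bleedthrough_alpha)
  ri <- ratio_image(s, d, donor_floor = cfg$acquisition$donor_floor)
  files <- list(traces = file.path(out_dir, "traces.csv"),
                cells = file.path(out_dir, "cells.csv"),
                ratio = file.path(out_dir, "ratio_final.tif"),
                ratio_valid = file.path(out_dir, "ratio_final_valid.tif"))
  vals <- ri$values; vals[!ri$valid] <- 0
  write_tiff_stack(vals, files$ratio, type = "float32")
  write_tiff_stack(ri$valid * 1, files$ratio_valid, type = "uint8")
  write_traces(traces, files$traces)
  df <- do.call(rbind, rows)
  utils::write.csv(df, files$cells, row.names = FALSE)
  list(files = files, traces = traces, cells = df, labels = seg$labels)
}
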