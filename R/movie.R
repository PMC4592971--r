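# Domain containers and file plumbing: multi-channel movies, traces, configs.

CHANNEL_NAMES <- c("donor", "acceptor", "marker")

#' Construct a multi-channel fluorescence movie
#'
#' A movie is a named list of `H x W x T` intensity stacks (one per channel,
#' e.g. donor/CFP, acceptor/YFP, marker/RFP) plus a strictly increasing vector
#' of frame times in seconds. All channels must share dimensions; intensities
#' must be finite and non-negative.
#'
#' @param channels named list of `H x W x T` numeric arrays (or `H x W`
#'   matrices for single-frame movies).
#' @param frame_times_s numeric vector of length `T`, strictly increasing.
#' @return an object of class `fret_movie`.
#' @export
fret_movie <- function(channels, frame_times_s) {
  if (!length(channels) || is.null(names(channels)) || any(!nzchar(names(channels))))
    stop_fretkit("`channels` must be a non-empty named list")
  channels <- lapply(channels, function(ch) {
    if (is.matrix(ch)) ch <- array(ch, dim = c(dim(ch), 1L))
    if (!is.array(ch) || length(dim(ch)) != 3L)
      stop_fretkit("each channel must be an H x W x T array")
    if (!all(is.finite(ch))) stop_fretkit("channel intensities must be finite")
    ch
  })
  d0 <- dim(channels[[1L]])
  for (ch in channels)
    if (!identical(dim(ch), d0)) stop_fretkit("all channels must share T, H, W")
  if (length(frame_times_s) != d0[3L])
    stop_fretkit("frame_times_s length must equal frame count")
  if (d0[3L] > 1L && any(diff(frame_times_s) <= 0))
    stop_fretkit("frame_times_s must be strictly increasing")
  structure(list(channels = channels, frame_times_s = as.numeric(frame_times_s)),
            class = "fret_movie")
}

#' @export
print.fret_movie <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("<fret_movie> %d x %d px, %d frames, channels: %s\n",
              d[1L], d[2L], d[3L], paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Number of frames in a movie
#' @param movie a `fret_movie`.
#' @export
n_frames <- function(movie) dim(movie$channels[[1L]])[3L]

#' Extract a single frame of one channel as a matrix
#' @param movie a `fret_movie`.
#' @param channel channel name.
#' @param t frame index (1-based).
#' @export
movie_frame <- function(movie, channel, t) {
  if (!channel %in% names(movie$channels))
    stop_fretkit("no channel named '", channel, "'")
  movie$channels[[channel]][, , t]
}

#' Read a movie from a multi-page TIFF
#'
#' Pages are expected interleaved per frame in `channel_order`
#' (frame 1: ch1..chk, frame 2: ch1..chk, ...). Frame times come from
#' `frame_interval_s` (or explicit `frame_times_s`), since plain TIFF carries
#' no time base.
#'
#' @param path TIFF path.
#' @param channel_order character vector of channel names.
#' @param frame_interval_s seconds between frames (default 1).
#' @param frame_times_s explicit frame times, overrides `frame_interval_s`.
#' @return a `fret_movie`.
#' @export
read_movie <- function(path, channel_order, frame_interval_s = 1,
                       frame_times_s = NULL) {
  pages <- read_tiff_stack(path)
  k <- length(channel_order)
  if (length(pages) %% k != 0L)
    stop_fretkit(sprintf(
      "page count %d is not divisible by %d channels (%s)",
      length(pages), k, paste(channel_order, collapse = ", ")))
  n_t <- length(pages) %/% k
  h <- nrow(pages[[1L]]); w <- ncol(pages[[1L]])
  channels <- stats::setNames(vector("list", k), channel_order)
  for (ci in seq_len(k)) {
    stack <- array(0, dim = c(h, w, n_t))
    for (t in seq_len(n_t)) stack[, , t] <- pages[[(t - 1L) * k + ci]]
    channels[[ci]] <- stack
  }
  if (is.null(frame_times_s)) frame_times_s <- (seq_len(n_t) - 1) * frame_interval_s
  fret_movie(channels, frame_times_s)
}

#' Write a movie as an interleaved multi-page TIFF
#'
#' @param movie a `fret_movie`.
#' @param path output path.
#' @param channel_order channel order for page interleaving (defaults to the
#'   movie's channel order).
#' @param type pixel type passed to [write_tiff_stack()].
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path, channel_order = names(movie$channels),
                        type = "float32") {
  pages <- list()
  for (t in seq_len(n_frames(movie)))
    for (ch in channel_order)
      pages[[length(pages) + 1L]] <- movie_frame(movie, ch, t)
  write_tiff_stack(pages, path, type = type)
}

#' Construct a per-cell time trace
#'
#' @param cell_id cell identifier (integer or string).
#' @param quantity one of `ratio`, `percent_change`, `area_px`,
#'   `area_percent`, `intensity`.
#' @param values numeric vector aligned to `times_s`; `NA` marks frames where
#'   the quantity is undefined (e.g. empty mask).
#' @param times_s frame times in seconds.
#' @return object of class `fret_trace`.
#' @export
fret_trace <- function(cell_id, quantity, values, times_s) {
  quantity <- match.arg(quantity,
    c("ratio", "percent_change", "area_px", "area_percent", "intensity"))
  if (length(values) != length(times_s))
    stop_fretkit("trace values and times must have equal length")
  structure(list(cell_id = cell_id, quantity = quantity,
                 values = as.numeric(values), times_s = as.numeric(times_s)),
            class = "fret_trace")
}

#' Write traces to CSV
#'
#' One `time_s` column plus one column per (cell, quantity), named
#' `cell<id>_<quantity>`. Missing values become empty fields. Full double
#' precision is preserved on round trip.
#'
#' @param traces list of [fret_trace()] objects sharing a time base.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "fret_trace")) traces <- list(traces)
  if (!length(traces)) stop_fretkit("no traces to write")
  t0 <- traces[[1L]]$times_s
  for (tr in traces) {
    if (length(tr$values) != length(t0) || any(abs(tr$times_s - t0) > 0))
      stop_fretkit("all traces must share the same time base")
  }
  df <- data.frame(time_s = t0, check.names = FALSE)
  for (tr in traces)
    df[[sprintf("cell%s_%s", tr$cell_id, tr$quantity)]] <- tr$values
  # format() at 17 significant digits keeps doubles exact on round trip
  fmt <- as.data.frame(lapply(df, function(col)
    ifelse(is.na(col), "", formatC(col, digits = 17, format = "g"))),
    check.names = FALSE)
  utils::write.table(fmt, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read traces written by [write_traces()]
#'
#' @param path CSV path.
#' @return list of `fret_trace` objects.
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  times <- df[["time_s"]]
  traces <- list()
  for (nm in setdiff(names(df), "time_s")) {
    m <- regmatches(nm, regexec(
      "^cell(.+)_(ratio|percent_change|area_px|area_percent|intensity)$", nm))[[1L]]
    if (length(m) != 3L) stop_fretkit("unrecognised trace column: ", nm)
    traces[[length(traces) + 1L]] <-
      fret_trace(m[2L], m[3L], as.numeric(df[[nm]]), times)
  }
  traces
}

#' Acquisition configuration
#'
#' Bundles the correction parameters for one imaging modality. The donor
#' bleedthrough fraction defaults to the modality's calibrated value: 0.55 for
#' widefield, 0.32 for confocal.
#'
#' @param modality `"widefield"` or `"confocal"`.
#' @param bleedthrough_alpha fraction of donor emission detected in the
#'   acceptor channel, in `[0, 1)`.
#' @param donor_floor donor intensity (camera units) below which ratio pixels
#'   are invalid.
#' @param max_registration_shift channel-alignment search radius in pixels.
#' @param frame_interval_s frame spacing used when a movie has no time base.
#' @return object of class `acquisition_config`.
#' @export
acquisition_config <- function(modality = c("widefield", "confocal"),
                               bleedthrough_alpha = NULL,
                               donor_floor = 0,
                               max_registration_shift = 10,
                               frame_interval_s = 1) {
  modality <- match.arg(modality)
  if (is.null(bleedthrough_alpha))
    bleedthrough_alpha <- if (modality == "widefield") 0.55 else 0.32
  if (!is.numeric(bleedthrough_alpha) || bleedthrough_alpha < 0 ||
      bleedthrough_alpha >= 1)
    stop_fretkit("bleedthrough_alpha must lie in [0, 1)")
  if (donor_floor < 0) stop_fretkit("donor_floor must be >= 0")
  structure(list(modality = modality,
                 bleedthrough_alpha = bleedthrough_alpha,
                 donor_floor = donor_floor,
                 max_registration_shift = max_registration_shift,
                 frame_interval_s = frame_interval_s),
            class = "acquisition_config")
}

#' Stimulus event
#'
#' @param time_s event time in seconds.
#' @param label free-text label (`agonist`, `antagonist`, `rapamycin`, ...).
#' @export
stimulus_event <- function(time_s, label = "agonist") {
  structure(list(time_s = as.numeric(time_s), label = as.character(label)),
            class = "stimulus_event")
}

#' Expression gate on marker intensity
#'
#' Cells are retained when the background-corrected mean marker (RFP)
#' intensity falls inside `[lo, hi]` (inclusive), the standard 50-300 a.u.
#' expression bin.
#'
#' @param lo,hi intensity bounds in camera units, `0 <= lo < hi`.
#' @export
expression_gate_spec <- function(lo = 50, hi = 300) {
  if (lo < 0 || lo >= hi) stop_fretkit("gate requires 0 <= lo < hi")
  structure(list(lo = lo, hi = hi), class = "expression_gate")
}

#' Load an analysis configuration file
#'
#' JSON document with optional fields `modality`, `bleedthrough_alpha`,
#' `donor_floor`, `max_registration_shift`, `frame_interval_s`, `events`
#' (list of `{time_s, label}`), and analysis parameters (`cortex_band_width`,
#' `center_erosion`, `expression_gate` as `[lo, hi]`, `threshold_*`).
#' Missing values take the documented defaults.
#'
#' @param path JSON config path.
#' @return list with elements `acquisition` ([acquisition_config()]),
#'   `events` (list of [stimulus_event()]) and `params` (named list).
#' @export
load_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    stop_fretkit("YAML configs are not supported in this build; use JSON")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  modality <- raw$modality %||% "widefield"
  acq <- acquisition_config(
    modality = modality,
    bleedthrough_alpha = raw$bleedthrough_alpha,
    donor_floor = raw$donor_floor %||% 0,
    max_registration_shift = raw$max_registration_shift %||% 10,
    frame_interval_s = raw$frame_interval_s %||% 1)
  events <- list()
  if (!is.null(raw$events)) {
    ev <- raw$events
    if (is.data.frame(ev)) ev <- split(ev, seq_len(nrow(ev)))
    events <- lapply(ev, function(e) stimulus_event(e$time_s, e$label %||% "event"))
    names(events) <- NULL
    tt <- vapply(events, `[[`, numeric(1), "time_s")
    if (length(tt) > 1L && any(diff(tt) <= 0))
      stop_fretkit("event times must be strictly increasing")
  }
  gate_raw <- raw$expression_gate %||% c(50, 300)
  params <- list(
    cortex_band_width = raw$cortex_band_width %||% 5L,
    center_erosion = raw$center_erosion %||% 9L,
    expression_gate = expression_gate_spec(gate_raw[[1L]], gate_raw[[2L]]),
    smoothing_sigma = raw$smoothing_sigma %||% 2,
    region_statistic = raw$region_statistic %||% "median")
  list(acquisition = acq, events = events, params = params)
}
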