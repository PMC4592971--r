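# Per-cell trace extraction, baseline normalisation, response half-times,
# the cortex-minus-body spatial statistic, expression gating and
# control-normalised intensities.

#' Extract a per-cell time trace from a movie
#'
#' For `quantity = "ratio"` the per-frame value is the region FRET ratio
#' (ratio of medians of sensitized over donor) computed after background,
#' registration and bleedthrough corrections. For `"intensity"` it is the
#' median (or mean) of a single channel over the mask. Frames with an empty
#' mask are flagged missing (`NA`).
#'
#' @param movie a `fret_movie`.
#' @param regions a static logical mask, or a list of per-frame masks
#'   (length `T`).
#' @param quantity `"ratio"` or `"intensity"`.
#' @param channel channel used for `"intensity"` (default `"marker"`).
#' @param config an [acquisition_config()] supplying alpha and donor_floor.
#' @param cell_id identifier stored on the trace.
#' @param statistic `"median"` (default) or `"mean"`.
#' @param correct apply background/bleedthrough corrections per frame
#'   (default `TRUE`; set `FALSE` if the movie is already corrected).
#' @return a [fret_trace()].
#' @export
extract_trace <- function(movie, regions, quantity = c("ratio", "intensity"),
                          channel = "marker", config = acquisition_config(),
                          cell_id = 1L, statistic = "median", correct = TRUE) {
  quantity <- match.arg(quantity)
  n_t <- n_frames(movie)
  masks <- if (is.list(regions)) regions else rep(list(regions), n_t)
  if (length(masks) != n_t) stop_fretkit("need one mask per frame")
  if (!any(vapply(masks, function(m) any(m > 0), logical(1))))
    stop_fretkit("mask is empty at every frame")
  vals <- rep(NA_real_, n_t)
  for (t in seq_len(n_t)) {
    m <- masks[[t]] > 0
    if (!any(m)) next
    if (quantity == "ratio") {
      d <- movie_frame(movie, "donor", t)
      a <- movie_frame(movie, "acceptor", t)
      if (correct) {
        d <- background_correct(d)$corrected
        a <- background_correct(a)$corrected
      }
      s <- correct_bleedthrough(a, d, config$bleedthrough_alpha)
      vals[t] <- region_ratio(s, d, m, statistic = statistic)
    } else {
      img <- movie_frame(movie, channel, t)
      if (correct) img <- background_correct(img)$corrected
      agg <- if (statistic == "median") stats::median else mean
      vals[t] <- agg(img[m])
    }
  }
  fret_trace(cell_id, if (quantity == "ratio") "ratio" else "intensity",
             vals, movie$frame_times_s)
}

#' Normalise a trace to its pre-stimulus baseline
#'
#' The baseline is the mean of all values strictly before the first stimulus;
#' the output is the percent change `100 * (value - baseline) / baseline`.
#'
#' @param trace a [fret_trace()].
#' @param first_event a [stimulus_event()]; at least two frames must precede
#'   it.
#' @return a `percent_change` trace.
#' @export
normalize_trace <- function(trace, first_event) {
  pre <- trace$times_s < first_event$time_s
  pre_vals <- trace$values[pre & !is.na(trace$values)]
  if (length(pre_vals) < 2L)
    stop_fretkit("need >= 2 pre-event frames to estimate the baseline")
  baseline <- mean(pre_vals)
  if (baseline <= 0) stop_fretkit("baseline must be positive")
  fret_trace(trace$cell_id, "percent_change",
             100 * (trace$values - baseline) / baseline, trace$times_s)
}

#' Response half-time (t-half)
#'
#' The half-time is the interval between stimulus addition and the moment the
#' response first reaches 50% of its post-stimulus maximum. The maximum is
#' taken over the unsmoothed trace inside `(event, window_end_s]`; the
#' crossing time is linearly interpolated between the two frames bracketing
#' half-maximum, first crossing wins.
#'
#' @param trace a normalised (`percent_change`) [fret_trace()].
#' @param event the stimulus [stimulus_event()].
#' @param window_end_s end of the response window (default: last frame).
#' @param smooth_width optional moving-average width (frames) applied before
#'   the search; default 0 (off).
#' @return list with `t_half_s`, `amplitude_percent`, `baseline_value`,
#'   `event_label`, and `no_response` (TRUE when the trace never rises above
#'   baseline in the window, in which case `t_half_s` is `NA`).
#' @export
t_half <- function(trace, event, window_end_s = NULL, smooth_width = 0) {
  tt <- trace$times_s
  vv <- trace$values
  if (smooth_width > 1) {
    k <- rep(1 / smooth_width, smooth_width)
    vv <- as.numeric(stats::filter(vv, k, sides = 2))
  }
  if (is.null(window_end_s)) window_end_s <- max(tt)
  in_win <- which(tt > event$time_s & tt <= window_end_s & !is.na(vv))
  if (length(in_win) < 2L)
    stop_fretkit("response window must contain at least two frames")
  peak <- max(vv[in_win])
  out <- list(t_half_s = NA_real_, amplitude_percent = peak,
              baseline_value = 0, event_label = event$label,
              no_response = FALSE)
  if (peak <= 0) { out$no_response <- TRUE; return(out) }
  half <- peak / 2
  for (j in in_win) {
    if (is.na(vv[j]) || vv[j] < half) next
    if (j == 1L) { cross <- tt[j]; out$t_half_s <- max(0, cross - event$time_s); return(out) }
    v0 <- vv[j - 1L]; t0 <- tt[j - 1L]
    cross <- if (is.na(v0) || v0 >= half) tt[j] else
      t0 + (half - v0) / (vv[j] - v0) * (tt[j] - t0)
    out$t_half_s <- max(0, cross - event$time_s)
    return(out)
  }
  out$no_response <- TRUE
  out
}

#' Cortex-minus-body spatial statistic
#'
#' Splits the cell mask into a fixed-width cortical band and the eroded body,
#' computes the region FRET ratio in each, and reports their difference
#' `delta = ratio_cx - ratio_cb`. Positive delta means activity is enriched
#' at the cortex, negative in the cell body; zero for a spatially uniform
#' field.
#'
#' @param sensitized,donor corrected matrices.
#' @param cell_mask logical cell mask.
#' @param band_width cortical band width in pixels (default 5).
#' @param statistic region statistic, `"median"` (default) or `"mean"`.
#' @return list with `ratio_cx`, `ratio_cb`, `delta`.
#' @export
cx_cb_statistic <- function(sensitized, donor, cell_mask, band_width = 5,
                            statistic = "median") {
  bands <- cortex_band(cell_mask, band_width)
  ratio_cx <- region_ratio(sensitized, donor, bands$cortex, statistic = statistic)
  ratio_cb <- region_ratio(sensitized, donor, bands$body, statistic = statistic)
  list(ratio_cx = ratio_cx, ratio_cb = ratio_cb, delta = ratio_cx - ratio_cb)
}

#' Expression gate decision
#'
#' A cell passes when its mean background-corrected marker intensity over the
#' mask lies inside the gate (inclusive bounds), the standard way of binning
#' cells to comparable expression levels.
#'
#' @param marker background-corrected marker matrix.
#' @param mask logical cell mask (nonempty).
#' @param gate an [expression_gate_spec()].
#' @return `TRUE`/`FALSE`.
#' @export
expression_gate <- function(marker, mask, gate = expression_gate_spec()) {
  mask <- mask > 0
  if (!any(mask)) stop_fretkit("mask is empty")
  m <- mean(marker[mask])
  m >= gate$lo && m <= gate$hi
}

#' Normalise cell intensities to untransfected controls
#'
#' Per-cell fold change relative to the mean of control-cell intensities from
#' the same experiment, plus group summary statistics. Downstream two-sample
#' comparison is delegated to standard tests ([stats::wilcox.test()] /
#' [stats::t.test()]), not re-derived here.
#'
#' @param cell_intensities numeric vector.
#' @param control_intensities numeric vector, nonempty with positive mean.
#' @return list with `fold` (per-cell fold changes), `group_mean`, `group_sd`,
#'   `n`.
#' @export
normalize_to_control <- function(cell_intensities, control_intensities) {
  if (!length(control_intensities)) stop_fretkit("control list is empty")
  ctrl <- mean(control_intensities)
  if (ctrl <= 0) stop_fretkit("control mean must be positive")
  fold <- cell_intensities / ctrl
  list(fold = fold, group_mean = mean(fold), group_sd = stats::sd(fold),
       n = length(fold))
}
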