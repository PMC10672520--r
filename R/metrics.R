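#' Configuration for network activity metrics
#'
#' @param interval_s Analysis window length in seconds for the windowed
#'   metrics (network spike rate and peak). The recording is tiled into
#'   consecutive non-overlapping windows of this length; a trailing
#'   partial window is kept when it covers at least half a window.
#' @param nsd_threshold Fraction of simultaneously active units (strict
#'   `>`) that defines a network spike for the duration metric, in (0, 1).
#'
#' @return An object of class `metric_config`.
#' @export
metric_config <- function(interval_s = 3, nsd_threshold = 0.1) {
  if (!is.numeric(interval_s) || interval_s <= 0)
    stop("'interval_s' must be positive")
  if (!is.numeric(nsd_threshold) || nsd_threshold <= 0 || nsd_threshold >= 1)
    stop("'nsd_threshold' must lie in (0, 1)")
  structure(list(interval_s = as.numeric(interval_s),
                 nsd_threshold = as.numeric(nsd_threshold)),
            class = "metric_config")
}

# window boundaries (half-open, 0-based) for consecutive tiling
metric_windows <- function(n_frames, interval_s, fps) {
  w <- as.integer(round(interval_s * fps))
  if (w < 1L) stop("analysis window is shorter than one frame")
  if (w > n_frames) stop("analysis window is longer than the recording")
  n_full <- n_frames %/% w
  starts <- (seq_len(n_full) - 1L) * w
  ends <- starts + w
  rem <- n_frames - n_full * w
  if (rem * 2L >= w && rem > 0L) {
    starts <- c(starts, n_full * w)
    ends <- c(ends, n_frames)
  }
  data.frame(start = starts, end = ends)
}

#' Per-unit burst rate (activations per minute)
#'
#' Counts each unit's distinct active intervals and divides by the
#' recording duration in minutes.
#'
#' @param mask An `activity_mask`.
#' @return Data frame with `unit_id`, `n_events`, `rate_per_min`. The mean
#'   rate across units is attached as attribute `mean_rate`.
#' @export
#'
#' @examples
#' m <- activity_mask(matrix(c(0L,1L,1L,0L,1L,0L), nrow = 1), fps = 20)
#' burst_rate(m)
burst_rate <- function(mask) {
  stopifnot(inherits(mask, "activity_mask"))
  minutes <- n_frames(mask) / mask$fps / 60
  if (minutes <= 0) stop("zero-length recording")
  nev <- vapply(mask$intervals, nrow, integer(1))
  out <- data.frame(unit_id = mask$unit_ids, n_events = nev,
                    rate_per_min = nev / minutes)
  attr(out, "mean_rate") <- mean(out$rate_per_min)
  out
}

#' Network spike rate per analysis window
#'
#' Percentage of units active at one or more frames of each window
#' (union semantics within the window).
#'
#' @param mask An `activity_mask`.
#' @param cfg A [metric_config()].
#' @return Data frame with `window`, `start_frame`, `end_frame`, `nsr_pct`.
#' @export
network_spike_rate <- function(mask, cfg = metric_config()) {
  stopifnot(inherits(mask, "activity_mask"), inherits(cfg, "metric_config"))
  wnd <- metric_windows(n_frames(mask), cfg$interval_s, mask$fps)
  nsr <- vapply(seq_len(nrow(wnd)), function(i) {
    cols <- (wnd$start[i] + 1L):wnd$end[i]
    100 * sum(rowSums(mask$active[, cols, drop = FALSE]) > 0) / n_units(mask)
  }, numeric(1))
  data.frame(window = seq_len(nrow(wnd)) - 1L, start_frame = wnd$start,
             end_frame = wnd$end, nsr_pct = nsr)
}

#' Network spike peak per analysis window
#'
#' Maximal percentage of simultaneously active units over the frames of
#' each window.
#'
#' @inheritParams network_spike_rate
#' @return Data frame with `window`, `start_frame`, `end_frame`, `nsp_pct`.
#' @export
network_spike_peak <- function(mask, cfg = metric_config()) {
  stopifnot(inherits(mask, "activity_mask"), inherits(cfg, "metric_config"))
  wnd <- metric_windows(n_frames(mask), cfg$interval_s, mask$fps)
  frac <- colSums(mask$active) / n_units(mask)
  nsp <- vapply(seq_len(nrow(wnd)), function(i)
    100 * max(frac[(wnd$start[i] + 1L):wnd$end[i]]), numeric(1))
  data.frame(window = seq_len(nrow(wnd)) - 1L, start_frame = wnd$start,
             end_frame = wnd$end, nsp_pct = nsp)
}

#' Network spike duration
#'
#' Percentage of recording time during which the fraction of
#' simultaneously active units strictly exceeds `nsd_threshold`.
#'
#' @inheritParams network_spike_rate
#' @return Scalar percentage in \[0, 100\].
#' @export
network_spike_duration <- function(mask, cfg = metric_config()) {
  stopifnot(inherits(mask, "activity_mask"), inherits(cfg, "metric_config"))
  frac <- colSums(mask$active) / n_units(mask)
  100 * mean(frac > cfg$nsd_threshold)
}
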