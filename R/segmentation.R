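#' Segmentation parameters for active-state detection
#'
#' Active states are phases of rapid fluorescence growth. Detection runs
#' per unit: the trace is smoothed with a centered moving average
#' ([smooth_trace()]), differenced ([trace_derivative()]), and frames where
#' the derivative exceeds an adaptive threshold (median plus mean absolute
#' deviation, [adaptive_threshold()]) are marked active. Two refinement
#' parameters clean the result: gaps shorter than `warm` frames are merged
#' and intervals shorter than `cold` frames are dropped.
#'
#' @param wnd_size Smoothing window width in frames (>= 1). The effective
#'   centered window spans `floor(wnd_size/2)` frames on each side.
#' @param warm Minimum duration of the passive phase, frames: two active
#'   states separated by a gap shorter than this are combined into one.
#' @param cold Minimum duration of the active phase, frames: shorter
#'   intervals are excluded.
#' @param mode `"spike"` keeps only the rising phase of each calcium
#'   transient; `"full"` extends each detected rise through the decay
#'   until the smoothed intensity falls back to its level at the
#'   interval's onset.
#'
#' @return An object of class `seg_params`.
#' @export
#'
#' @examples
#' seg_params()                      # defaults: wnd 10, warm 15, cold 0, spike
#' seg_params(mode = "full", warm = 20)
seg_params <- function(wnd_size = 10L, warm = 15L, cold = 0L,
                       mode = c("spike", "full")) {
  mode <- match.arg(mode)
  wnd_size <- as.integer(wnd_size)
  warm <- as.integer(warm); cold <- as.integer(cold)
  if (is.na(wnd_size) || wnd_size < 1L) stop("'wnd_size' must be >= 1")
  if (is.na(warm) || warm < 0L) stop("'warm' must be >= 0")
  if (is.na(cold) || cold < 0L) stop("'cold' must be >= 0")
  structure(list(wnd_size = wnd_size, warm = warm, cold = cold, mode = mode),
            class = "seg_params")
}

#' Centered moving-average smoothing
#'
#' Averages each sample with its neighbours up to `floor(wnd_size/2)`
#' frames away. At the series edges the window is truncated and
#' renormalized by the number of samples actually inside it, so a constant
#' series maps to itself for any window width.
#'
#' @param x Numeric series.
#' @param wnd_size Window width in frames (>= 1); `1` is the identity.
#'
#' @return Smoothed series of the same length.
#' @export
#'
#' @examples
#' smooth_trace(c(0, 0, 3, 0, 0), 3)   # c(0, 1, 1, 1, 0)
smooth_trace <- function(x, wnd_size) {
  x <- as.numeric(x)
  if (length(x) < 1L) stop("series must have length >= 1")
  wnd_size <- as.integer(wnd_size)
  if (is.na(wnd_size) || wnd_size < 1L) stop("'wnd_size' must be >= 1")
  k <- wnd_size %/% 2L
  if (k == 0L) return(x)
  n <- length(x)
  cs <- c(0, cumsum(x))
  hi <- pmin(seq_len(n) + k, n)
  lo <- pmax(seq_len(n) - k, 1L)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Discrete derivative of a trace
#'
#' First differences `x[t] - x[t-1]`; the first element is set to 0 so the
#' output aligns frame-for-frame with the input.
#'
#' @param x Numeric series of length >= 2.
#' @return Numeric series of the same length.
#' @export
trace_derivative <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("series must have length >= 2")
  c(0, diff(x))
}

#' Adaptive activity threshold
#'
#' `median(x) + mad(x)` where the deviation term is the *mean* absolute
#' deviation about the median. Applied to the derivative series, the
#' median captures the unit's baseline drift and the deviation term its
#' permissible variability; derivative excursions above the sum mark
#' calcium-transient rises.
#'
#' @param deriv Numeric series (normally a trace derivative), length >= 2.
#' @return Scalar threshold.
#' @export
#'
#' @examples
#' adaptive_threshold(c(0, 0, 10, 0, 0))  # median 0 + mad 2 = 2
adaptive_threshold <- function(deriv) {
  deriv <- as.numeric(deriv)
  if (length(deriv) < 2L) stop("series must have length >= 2")
  m <- stats::median(deriv)
  m + mean(abs(deriv - m))
}

#' Merge-and-drop refinement of active intervals
#'
#' First any passive gap shorter than `warm` frames between consecutive
#' intervals is merged into one active state; then any resulting interval
#' shorter than `cold` frames is excluded. Both comparisons are strict, so
#' `warm = 0, cold = 0` leaves the input unchanged.
#'
#' @param intervals Data frame with integer columns `start`, `end`:
#'   half-open `[start, end)` 0-based frame intervals, sorted, disjoint.
#' @param warm,cold Refinement parameters in frames (see [seg_params()]).
#'
#' @return Refined interval data frame.
#' @export
refine_intervals <- function(intervals, warm, cold) {
  intervals <- as_intervals(intervals)
  warm <- as.integer(warm); cold <- as.integer(cold)
  if (nrow(intervals) > 1L && warm > 0L) {
    starts <- intervals$start; ends <- intervals$end
    keep_s <- starts[1]
    out_s <- integer(0); out_e <- integer(0)
    cur_e <- ends[1]
    for (i in seq_len(nrow(intervals) - 1L) + 1L) {
      gap <- starts[i] - cur_e
      if (gap < warm) {
        cur_e <- ends[i]
      } else {
        out_s <- c(out_s, keep_s); out_e <- c(out_e, cur_e)
        keep_s <- starts[i]; cur_e <- ends[i]
      }
    }
    out_s <- c(out_s, keep_s); out_e <- c(out_e, cur_e)
    intervals <- data.frame(start = out_s, end = out_e)
  }
  if (cold > 0L && nrow(intervals) > 0L)
    intervals <- intervals[intervals$end - intervals$start >= cold, ,
                           drop = FALSE]
  rownames(intervals) <- NULL
  intervals
}

# validate/coerce an interval table: integer start/end, sorted, disjoint
as_intervals <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L))
    return(data.frame(start = integer(0), end = integer(0)))
  x <- as.data.frame(x)
  if (!all(c("start", "end") %in% names(x)))
    stop("intervals need 'start' and 'end' columns")
  out <- data.frame(start = as.integer(x$start), end = as.integer(x$end))
  if (any(out$end <= out$start)) stop("every interval must have length >= 1")
  if (is.unsorted(out$start, strictly = TRUE) ||
      any(out$start[-1] < out$end[-nrow(out)]))
    stop("intervals must be sorted and disjoint")
  out
}

# half-open 0-based intervals -> 0/1 vector of length n_frames
intervals_to_binary <- function(intervals, n_frames) {
  v <- integer(n_frames)
  if (nrow(intervals) > 0L)
    for (i in seq_len(nrow(intervals)))
      v[(intervals$start[i] + 1L):intervals$end[i]] <- 1L
  v
}

# 0/1 vector -> half-open 0-based interval table
binary_to_intervals <- function(v) {
  r <- rle(as.integer(v) != 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Segment one trace into active states
#'
#' Runs the full detection chain on a single fluorescence trace: smoothing,
#' differencing, adaptive thresholding (strict `>`), merging of consecutive
#' supra-threshold frames into intervals, optional full-mode decay
#' extension, then warm/cold refinement.
#'
#' In `"full"` mode each detected rise interval is extended forward while
#' the smoothed intensity stays above its value at the interval's first
#' frame, capped at the next interval's onset and the end of the recording.
#'
#' @param x Numeric trace, length >= 2.
#' @param params A [seg_params()] object.
#'
#' @return List with `intervals` (half-open 0-based data frame) and
#'   `active` (0/1 integer vector, one per frame), consistent with each
#'   other.
#' @export
segment_trace <- function(x, params = seg_params()) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("trace must have length >= 2")
  stopifnot(inherits(params, "seg_params"))
  s <- smooth_trace(x, params$wnd_size)
  d <- trace_derivative(s)
  thr <- adaptive_threshold(d)
  iv <- binary_to_intervals(d > thr)
  if (params$mode == "full" && nrow(iv) > 0L) {
    n <- length(x)
    for (i in seq_len(nrow(iv))) {
      base <- s[iv$start[i] + 1L]
      cap <- if (i < nrow(iv)) iv$start[i + 1L] else n
      e <- iv$end[i]
      while (e < cap && s[e + 1L] > base) e <- e + 1L
      iv$end[i] <- e
    }
  }
  iv <- refine_intervals(iv, params$warm, params$cold)
  list(intervals = iv, active = intervals_to_binary(iv, length(x)))
}

#' Segment every unit of a recording
#'
#' Applies [segment_trace()] to each unit with a per-unit adaptive
#' threshold (never a global one) and assembles the results into an
#' activity mask. Deterministic: no randomness is involved.
#'
#' @param rec A [recording()].
#' @param params A [seg_params()] object.
#'
#' @return An object of class `activity_mask`: list with `active` (0/1
#'   integer matrix, units x frames), `intervals` (one interval data frame
#'   per unit, in trace-matrix row order), `unit_ids`, `fps`, `mode`,
#'   `params`.
#' @export
#'
#' @examples
#' rec <- generate_recording(synth_config(n_units = 5, n_frames = 600,
#'                                        seed = 1))$recording
#' mask <- segment_recording(rec, seg_params())
#' mask
segment_recording <- function(rec, params = seg_params()) {
  stopifnot(inherits(rec, "recording"))
  nu <- n_units(rec); nf <- n_frames(rec)
  active <- matrix(0L, nu, nf)
  intervals <- vector("list", nu)
  for (i in seq_len(nu)) {
    res <- tryCatch(segment_trace(rec$traces[i, ], params),
                    error = function(e)
                      stop(sprintf("unit %d: %s", unit_ids(rec)[i],
                                   conditionMessage(e)), call. = FALSE))
    active[i, ] <- res$active
    intervals[[i]] <- res$intervals
  }
  activity_mask(active, intervals, unit_ids(rec), fps(rec),
                mode = params$mode, params = params)
}

#' Construct an activity mask
#'
#' Low-level constructor pairing a binary active/inactive matrix with its
#' per-unit interval lists. The two representations must agree exactly.
#'
#' @param active 0/1 integer matrix, units x frames.
#' @param intervals List of interval data frames (one per unit, `start`,
#'   `end`, half-open 0-based). Recomputed from `active` when `NULL`.
#' @param unit_ids Integer unit labels.
#' @param fps Frames per second.
#' @param mode Segmentation mode label ("spike" or "full").
#' @param params Optional `seg_params` provenance.
#'
#' @return An `activity_mask` object.
#' @export
activity_mask <- function(active, intervals = NULL, unit_ids = NULL,
                          fps = 20, mode = "spike", params = NULL) {
  active <- as.matrix(active)
  storage.mode(active) <- "integer"
  if (!all(active %in% c(0L, 1L))) stop("'active' must be binary")
  nu <- nrow(active); nf <- ncol(active)
  if (is.null(unit_ids)) unit_ids <- seq_len(nu) - 1L
  if (is.null(intervals)) {
    intervals <- lapply(seq_len(nu), function(i)
      binary_to_intervals(active[i, ]))
  } else {
    stopifnot(length(intervals) == nu)
    intervals <- lapply(intervals, as_intervals)
    for (i in seq_len(nu))
      if (!all(intervals_to_binary(intervals[[i]], nf) == active[i, ]))
        stop(sprintf("unit %d: intervals inconsistent with binary mask",
                     unit_ids[i]))
  }
  structure(list(active = active, intervals = intervals,
                 unit_ids = as.integer(unit_ids), fps = as.numeric(fps),
                 mode = mode, params = params),
            class = "activity_mask")
}

#' @export
print.activity_mask <- function(x, ...) {
  nev <- vapply(x$intervals, nrow, integer(1))
  cat(sprintf("<activity_mask (%s)>: %d units x %d frames @ %g fps\n",
              x$mode, n_units(x), n_frames(x), x$fps))
  cat(sprintf("  events/unit: median %g (range %d-%d); active fraction %.3f\n",
              stats::median(nev), min(nev), max(nev), mean(x$active)))
  invisible(x)
}

#' Per-unit interval table of an activity mask
#'
#' @param mask An `activity_mask`.
#' @return Data frame with `unit_id`, `start_frame`, `end_frame` (half-open,
#'   0-based) and `start_s`, `end_s` in seconds.
#' @export
interval_table <- function(mask) {
  stopifnot(inherits(mask, "activity_mask"))
  rows <- lapply(seq_along(mask$intervals), function(i) {
    iv <- mask$intervals[[i]]
    if (nrow(iv) == 0L) return(NULL)
    data.frame(unit_id = mask$unit_ids[i], start_frame = iv$start,
               end_frame = iv$end, start_s = iv$start / mask$fps,
               end_s = iv$end / mask$fps)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(unit_id = integer(0), start_frame = integer(0),
                      end_frame = integer(0), start_s = numeric(0),
                      end_s = numeric(0))
  rownames(out) <- NULL
  out
}
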