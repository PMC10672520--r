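#' Per-neuron fluorescence trace matrix
#'
#' Container for CNMF-style extracted calcium traces: one row per neuron
#' (unit), one column per movie frame, plus the acquisition frame rate.
#' Frame indices are 0-based throughout the package, matching the upstream
#' Python extraction tooling these traces come from.
#'
#' @param intensities Numeric matrix, units in rows, frames in columns.
#'   Arbitrary fluorescence units. Must be free of missing values.
#' @param fps Frames per second of the recording (positive scalar).
#' @param unit_ids Integer labels for the units, unique, one per row.
#'   Defaults to `0:(n_units - 1)`.
#'
#' @return An object of class `trace_matrix`: the intensity matrix with
#'   `fps` and `unit_ids` attributes.
#' @export
#'
#' @examples
#' tm <- trace_matrix(matrix(rnorm(200), nrow = 2), fps = 20)
#' n_units(tm)
#' n_frames(tm)
trace_matrix <- function(intensities, fps, unit_ids = NULL) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (nrow(intensities) < 1L)
    stop("trace matrix needs at least one unit")
  if (ncol(intensities) < 2L)
    stop("trace matrix needs at least two frames")
  if (anyNA(intensities) || any(!is.finite(intensities)))
    stop("trace matrix contains missing or non-finite values")
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("'fps' must be a single positive number")
  if (is.null(unit_ids)) unit_ids <- seq_len(nrow(intensities)) - 1L
  unit_ids <- as.integer(unit_ids)
  if (length(unit_ids) != nrow(intensities))
    stop("'unit_ids' must have one entry per unit")
  if (anyDuplicated(unit_ids))
    stop("'unit_ids' must be unique")
  dimnames(intensities) <- NULL
  structure(intensities, fps = as.numeric(fps), unit_ids = unit_ids,
            class = c("trace_matrix", "matrix", "array"))
}

#' Neuron centroid positions in pixels
#'
#' @param unit_ids Integer unit labels.
#' @param x,y Pixel coordinates, finite and non-negative, one per unit.
#'
#' @return A data frame of class `neuron_positions` with columns
#'   `unit_id`, `x`, `y`.
#' @export
neuron_positions <- function(unit_ids, x, y) {
  unit_ids <- as.integer(unit_ids)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(unit_ids) || length(y) != length(unit_ids))
    stop("'x' and 'y' must have one entry per unit")
  if (anyDuplicated(unit_ids)) stop("'unit_ids' must be unique")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("positions must be finite")
  out <- data.frame(unit_id = unit_ids, x = x, y = y)
  class(out) <- c("neuron_positions", "data.frame")
  out
}

#' A single miniscope recording
#'
#' Bundles a [trace_matrix()] with optional [neuron_positions()] and a
#' human-readable name. Positions, when present, must cover exactly the
#' units of the trace matrix.
#'
#' @param traces A `trace_matrix`.
#' @param positions A `neuron_positions` table or `NULL`.
#' @param name Text label for the recording.
#'
#' @return An object of class `recording` (a list with elements `traces`,
#'   `positions`, `name`).
#' @export
recording <- function(traces, positions = NULL, name = "recording") {
  if (!inherits(traces, "trace_matrix"))
    stop("'traces' must be a trace_matrix")
  if (!is.null(positions)) {
    if (!inherits(positions, "neuron_positions"))
      stop("'positions' must be a neuron_positions table")
    if (!setequal(positions$unit_id, unit_ids(traces)))
      stop("positions must cover exactly the units of the trace matrix")
    # align ordering with the trace matrix
    positions <- positions[match(unit_ids(traces), positions$unit_id), ,
                           drop = FALSE]
    rownames(positions) <- NULL
  }
  structure(list(traces = traces, positions = positions,
                 name = as.character(name)[1]),
            class = "recording")
}

#' @rdname trace_matrix
#' @param x A `trace_matrix`, `recording` or `activity_mask`.
#' @export
n_units <- function(x) UseMethod("n_units")
#' @export
n_units.trace_matrix <- function(x) nrow(x)
#' @export
n_units.recording <- function(x) nrow(x$traces)
#' @export
n_units.activity_mask <- function(x) nrow(x$active)

#' @rdname trace_matrix
#' @export
n_frames <- function(x) UseMethod("n_frames")
#' @export
n_frames.trace_matrix <- function(x) ncol(x)
#' @export
n_frames.recording <- function(x) ncol(x$traces)
#' @export
n_frames.activity_mask <- function(x) ncol(x$active)

#' @rdname trace_matrix
#' @export
unit_ids <- function(x) UseMethod("unit_ids")
#' @export
unit_ids.trace_matrix <- function(x) attr(x, "unit_ids")
#' @export
unit_ids.recording <- function(x) attr(x$traces, "unit_ids")
#' @export
unit_ids.activity_mask <- function(x) x$unit_ids

#' @rdname trace_matrix
#' @export
fps <- function(x) UseMethod("fps")
#' @export
fps.trace_matrix <- function(x) attr(x, "fps")
#' @export
fps.recording <- function(x) attr(x$traces, "fps")
#' @export
fps.activity_mask <- function(x) x$fps

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording '%s'>: %d units x %d frames @ %g fps (%.1f s)\n",
              x$name, n_units(x), n_frames(x), fps(x),
              n_frames(x) / fps(x)))
  cat(if (is.null(x$positions)) "  positions: absent\n"
      else "  positions: present (pixels)\n")
  invisible(x)
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("<trace_matrix>: %d units x %d frames @ %g fps\n",
              nrow(x), ncol(x), fps(x)))
  invisible(x)
}
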