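#' Center of mass of a neuron layout
#'
#' Unweighted mean of the unit centroid coordinates, computed per
#' recording.
#'
#' @param pos A [neuron_positions()] table.
#' @return Numeric vector `c(x, y)`.
#' @export
center_of_mass <- function(pos) {
  stopifnot(inherits(pos, "neuron_positions"))
  if (nrow(pos) < 1L) stop("no units")
  c(x = mean(pos$x), y = mean(pos$y))
}

#' Polar distance to the population center (rho)
#'
#' Euclidean distance of each unit to the layout's center of mass, in
#' pixels.
#'
#' @inheritParams center_of_mass
#' @return Numeric vector, one value per unit (named by `unit_id`).
#' @export
polar_rho <- function(pos) {
  cm <- center_of_mass(pos)
  rho <- sqrt((pos$x - cm["x"])^2 + (pos$y - cm["y"])^2)
  names(rho) <- pos$unit_id
  rho
}

#' Pairwise unit distances
#'
#' `euclidean` is the straight-line pixel distance between the two units;
#' `radial` is the absolute difference of their distances to the
#' population center of mass (so `radial <= euclidean` always, by the
#' reverse triangle inequality).
#'
#' @inheritParams center_of_mass
#' @param kind `"euclidean"` or `"radial"`.
#' @return Data frame with `unit_i`, `unit_j` (unit ids, i < j in layout
#'   order) and `distance` in pixels, one row per unordered pair.
#' @export
pair_distances <- function(pos, kind = c("euclidean", "radial")) {
  kind <- match.arg(kind)
  stopifnot(inherits(pos, "neuron_positions"))
  n <- nrow(pos)
  if (n < 2L) stop("need at least 2 units")
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- if (kind == "euclidean") {
    sqrt((pos$x[idx[, 1]] - pos$x[idx[, 2]])^2 +
         (pos$y[idx[, 1]] - pos$y[idx[, 2]])^2)
  } else {
    rho <- polar_rho(pos)
    abs(rho[idx[, 1]] - rho[idx[, 2]])
  }
  data.frame(unit_i = pos$unit_id[idx[, 1]], unit_j = pos$unit_id[idx[, 2]],
             distance = as.numeric(d))
}

#' Distance factor
#'
#' Maps a pair distance into `[0, 1)` via `k = dist / (dist + d0)`:
#' 0 at distance 0, 0.5 at `d0`, approaching 1 for far pairs. The scale
#' `d0` defaults to the 25th percentile of the recording's Euclidean
#' pair-distance distribution (see [default_d0()]); pass `d0 = 100` to use
#' a fixed 100-pixel scale instead.
#'
#' @param dist Non-negative distance(s) in pixels.
#' @param d0 Positive distance scale in pixels.
#' @return Value(s) in `[0, 1)`, strictly increasing in `dist`.
#' @export
distance_factor <- function(dist, d0) {
  if (!is.numeric(d0) || length(d0) != 1L || !is.finite(d0) || d0 <= 0)
    stop("'d0' must be a single positive number")
  if (any(dist < 0)) stop("'dist' must be >= 0")
  dist / (dist + d0)
}

#' Default distance-factor scale for a layout
#'
#' 25th percentile of the Euclidean pair-distance distribution.
#'
#' @inheritParams center_of_mass
#' @return Scalar, pixels.
#' @export
default_d0 <- function(pos) {
  stats::quantile(pair_distances(pos, "euclidean")$distance, 0.25,
                  names = FALSE)
}

#' Correlation-versus-distance analysis
#'
#' Relates co-activity and signal properties to the spatial layout:
#' \enumerate{
#'   \item per unit, mean fluorescence against rho (distance to the
#'     population center), with their Pearson coefficient;
#'   \item per unit, active-state ratio (active frames / total frames)
#'     against rho, with their Pearson coefficient;
#'   \item per unordered pair, the correlation coefficient against the
#'     pair distance of the chosen kind, optionally with the distance
#'     factor `k` and the distance-weighted coefficient `r * k`.
#' }
#' Zero-variance regressors (e.g. all units at one point) yield a 0
#' coefficient with a warning.
#'
#' @param rec A [recording()] with positions.
#' @param mask The `activity_mask` segmented from `rec`.
#' @param corr A `correlation_matrix` for the same units.
#' @param kind Pair-distance kind, `"euclidean"` or `"radial"`.
#' @param d0 Distance-factor scale; default the layout's [default_d0()].
#' @param weighted Add `k` and `weighted_r = r * k` columns to the pair
#'   table.
#' @return List with `per_unit` (data frame: `unit_id`,
#'   `mean_fluorescence`, `active_ratio`, `rho`), `fluorescence_r`,
#'   `active_ratio_r`, `pairs` (data frame with `unit_i`, `unit_j`, `r`,
#'   `distance`, optionally `k`, `weighted_r`), `corr_distance_r`, and
#'   `d0`.
#' @export
correlation_vs_distance <- function(rec, mask, corr,
                                    kind = c("euclidean", "radial"),
                                    d0 = NULL, weighted = FALSE) {
  kind <- match.arg(kind)
  stopifnot(inherits(rec, "recording"), inherits(mask, "activity_mask"))
  if (is.null(rec$positions))
    stop("distance analysis requires positions")
  pos <- rec$positions
  rho <- polar_rho(pos)
  guard_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("zero-variance series in dependence: correlation set to 0",
              call. = FALSE)
      return(0)
    }
    stats::cor(a, b)
  }
  per_unit <- data.frame(unit_id = pos$unit_id,
                         mean_fluorescence = rowMeans(rec$traces),
                         active_ratio = rowMeans(mask$active),
                         rho = as.numeric(rho))
  pairs <- pair_distances(pos, kind)
  n <- nrow(pos)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs$r <- corr[idx]
  pairs <- pairs[, c("unit_i", "unit_j", "r", "distance")]
  if (is.null(d0)) d0 <- default_d0(pos)
  if (weighted) {
    pairs$k <- distance_factor(pairs$distance, d0)
    pairs$weighted_r <- pairs$r * pairs$k
  }
  list(per_unit = per_unit,
       fluorescence_r = guard_cor(per_unit$mean_fluorescence, per_unit$rho),
       active_ratio_r = guard_cor(per_unit$active_ratio, per_unit$rho),
       pairs = pairs,
       corr_distance_r = guard_cor(pairs$r, pairs$distance),
       d0 = d0)
}
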