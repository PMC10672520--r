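#' Configuration for activity shuffling
#'
#' The surrogate null model randomizes the *timing* of each shuffled
#' unit's active states while conserving its number of activations
#' exactly: new interval durations are drawn with the original durations
#' as their means, and the intervals are re-placed uniformly at random
#' without overlap. Differences between metrics on original and shuffled
#' data indicate that the metrics capture network structure rather than
#' independent activity.
#'
#' @param ratio Fraction of units shuffled, in \[0, 1\]; `ceil(ratio * n)`
#'   units are drawn uniformly (afresh each iteration).
#' @param num_of_shuffles Number of independent surrogate iterations.
#' @param seed RNG seed for full reproducibility (`NULL` = use current
#'   RNG state).
#' @param respect_positions Indicator recorded in reports, stating whether
#'   cell placement was taken into account downstream.
#'
#' @return An object of class `shuffle_config`.
#' @export
shuffle_config <- function(ratio = 1, num_of_shuffles = 10L, seed = NULL,
                           respect_positions = FALSE) {
  if (!is.numeric(ratio) || ratio < 0 || ratio > 1)
    stop("'ratio' must lie in [0, 1]")
  num_of_shuffles <- as.integer(num_of_shuffles)
  if (is.na(num_of_shuffles) || num_of_shuffles < 1L)
    stop("'num_of_shuffles' must be >= 1")
  structure(list(ratio = as.numeric(ratio),
                 num_of_shuffles = num_of_shuffles,
                 seed = if (!is.null(seed)) as.integer(seed),
                 respect_positions = isTRUE(respect_positions)),
            class = "shuffle_config")
}

#' Shuffle one unit's active intervals
#'
#' Draws a surrogate interval list with exactly the same number of
#' intervals. Each new duration is sampled uniformly from
#' `{1, ..., 2 d - 1}` where `d` is the original duration (so durations
#' keep their original means and total active time is conserved in
#' expectation), and the intervals are placed at uniformly random
#' non-overlapping positions (at least one passive frame between
#' consecutive intervals). Uses the current RNG stream.
#'
#' @param intervals Interval data frame (`start`, `end`, half-open,
#'   0-based).
#' @param n_frames Recording length in frames.
#' @return A sorted, disjoint interval data frame with `nrow(intervals)`
#'   rows inside `[0, n_frames)`.
#' @export
shuffle_unit <- function(intervals, n_frames) {
  intervals <- as_intervals(intervals)
  k <- nrow(intervals)
  if (k == 0L) return(intervals)
  n_frames <- as.integer(n_frames)
  if (any(intervals$end > n_frames)) stop("intervals exceed n_frames")
  dur <- intervals$end - intervals$start
  for (try in 1:100) {
    new_dur <- vapply(dur, function(d)
      if (d == 1L) 1L else sample.int(2L * d - 1L, 1L), integer(1))
    if (sum(new_dur) + (k - 1L) <= n_frames) break
    if (try == 100L) new_dur <- dur
  }
  # near-saturated masks (adjacent originals) may still not fit with the
  # mandatory 1-frame gaps: trim the longest durations until they do
  while (sum(new_dur) + (k - 1L) > n_frames) {
    j <- which.max(new_dur)
    if (new_dur[j] == 1L) stop("cannot place intervals: mask too dense")
    new_dur[j] <- new_dur[j] - 1L
  }
  new_dur <- new_dur[sample.int(k)]  # random assignment to slots
  free <- n_frames - sum(new_dur) - (k - 1L)
  # uniform composition of `free` spare frames into k + 1 gaps (>= 0)
  gaps <- if (free == 0L) integer(k + 1L) else {
    cuts <- sort(sample.int(free + k, k))
    diff(c(0L, cuts, free + k + 1L)) - 1L
  }
  starts <- integer(k)
  pos <- gaps[1]
  for (i in seq_len(k)) {
    starts[i] <- pos
    pos <- pos + new_dur[i] + 1L + gaps[i + 1L]
  }
  data.frame(start = starts, end = starts + new_dur)
}

#' Generate surrogate activity masks
#'
#' Produces `num_of_shuffles` independent surrogates of `mask`. In each
#' iteration `ceil(ratio * n_units)` units are chosen uniformly and their
#' intervals re-drawn with [shuffle_unit()]; the remaining units are left
#' untouched. Fully reproducible from `cfg$seed`.
#'
#' @param mask An `activity_mask`.
#' @param cfg A [shuffle_config()].
#' @return List of `activity_mask` surrogates, length
#'   `cfg$num_of_shuffles`.
#' @export
#'
#' @examples
#' m <- segment_recording(generate_recording(synth_config(
#'   n_units = 10, n_frames = 1200, seed = 2))$recording)
#' surr <- shuffle_network(m, shuffle_config(ratio = 1, num_of_shuffles = 3,
#'                                           seed = 42))
#' length(surr)
shuffle_network <- function(mask, cfg = shuffle_config()) {
  stopifnot(inherits(mask, "activity_mask"), inherits(cfg, "shuffle_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  nu <- n_units(mask); nf <- n_frames(mask)
  n_pick <- ceiling(cfg$ratio * nu)
  lapply(seq_len(cfg$num_of_shuffles), function(it) {
    picked <- if (n_pick > 0L) sample.int(nu, n_pick) else integer(0)
    intervals <- mask$intervals
    active <- mask$active
    for (i in picked) {
      intervals[[i]] <- shuffle_unit(intervals[[i]], nf)
      active[i, ] <- intervals_to_binary(intervals[[i]], nf)
    }
    activity_mask(active, intervals, mask$unit_ids, mask$fps,
                  mode = mask$mode, params = mask$params)
  })
}

#' Compare metrics between original and surrogate masks
#'
#' For the original mask and every surrogate, computes the mean pairwise
#' coefficient (mask-based method), the correlation range (max minus min),
#' and the mean network spike rate and peak. Only mask-based correlation
#' methods are meaningful here: shuffling perturbs activity masks, not
#' traces, so trace-based Pearson would be unchanged by construction.
#'
#' @param mask The original `activity_mask`.
#' @param surrogates List of surrogate masks from [shuffle_network()].
#' @param method Correlation method: `"active"`, `"full"` or
#'   `"active_acc"`.
#' @param cfg A [metric_config()] for the windowed metrics.
#' @param lag Correlation lag, frames.
#' @return Data frame with one row for the original and one per surrogate
#'   (`source`, `mean_corr`, `corr_range`, `mean_nsr`, `mean_nsp`), with
#'   the across-surrogate mean and SEM of each metric attached as
#'   attribute `summary`.
#' @export
compare_metrics <- function(mask, surrogates, method = "active",
                            cfg = metric_config(), lag = 0L) {
  stopifnot(inherits(mask, "activity_mask"), length(surrogates) >= 1L)
  if (!method %in% c("active", "full", "active_acc"))
    stop("shuffle comparison needs a mask-based method ",
         "('active', 'full' or 'active_acc')")
  one <- function(m) {
    cm <- suppressWarnings(pearson_matrix(mask = m, method = method,
                                          lag = lag))
    cs <- correlation_summary(cm)
    c(mean_corr = cs$mean, corr_range = cs$range,
      mean_nsr = mean(network_spike_rate(m, cfg)$nsr_pct),
      mean_nsp = mean(network_spike_peak(m, cfg)$nsp_pct))
  }
  rows <- rbind(one(mask), t(vapply(surrogates, one, numeric(4))))
  out <- data.frame(source = c("original",
                               paste0("shuffle_", seq_along(surrogates))),
                    rows, row.names = NULL)
  sh <- out[-1, c("mean_corr", "corr_range", "mean_nsr", "mean_nsp")]
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
  attr(out, "summary") <- data.frame(
    metric = names(sh), original = as.numeric(out[1, -1]),
    shuffled_mean = colMeans(sh),
    shuffled_sem = vapply(sh, sem, numeric(1)), row.names = NULL)
  out
}
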