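#' Pairwise co-activity matrix
#'
#' Computes the symmetric unit-by-unit co-activity matrix in one of five
#' modes:
#' \describe{
#'   \item{`signal`}{Pearson correlation of the raw intensity traces.}
#'   \item{`diff`}{Pearson correlation of the intensity derivatives.}
#'   \item{`active`, `full`}{Pearson correlation of the binarized active
#'     states (the supplied mask should have been segmented in the matching
#'     mode).}
#'   \item{`active_acc`}{Coactivity ratio: simultaneously-active time over
#'     the summed individual active times (see [active_acc()]); values in
#'     \[0, 0.5\].}
#' }
#' With `lag > 0` the reported coefficient for each pair is the maximum
#' Pearson correlation over integer shifts in `[-lag, +lag]` frames
#' (truncated overlap), which reduces exactly to the plain coefficient at
#' `lag = 0`. Zero-variance series yield 0 with a warning rather than NA,
#' so downstream thresholding is total.
#'
#' @param rec A [recording()] (required for `signal`/`diff`; optional
#'   otherwise).
#' @param mask An `activity_mask` (required for `active`, `full`,
#'   `active_acc`).
#' @param method One of `"signal"`, `"diff"`, `"active"`, `"full"`,
#'   `"active_acc"`.
#' @param lag Maximal shift between the two series in frames (>= 0).
#'   Ignored for `active_acc`.
#'
#' @return An object of class `correlation_matrix`: symmetric numeric
#'   matrix with attributes `method`, `lag`, `unit_ids`. Diagonal is 1 for
#'   the Pearson modes, 0.5 (or 0 for silent units) for `active_acc`.
#' @export
#'
#' @examples
#' sim <- generate_recording(synth_config(n_units = 6, n_frames = 1200,
#'                                        n_correlated_groups = 2, seed = 4))
#' mask <- segment_recording(sim$recording)
#' cm <- pearson_matrix(sim$recording, mask, method = "active")
#' round(cm[1:3, 1:3], 2)
pearson_matrix <- function(rec = NULL, mask = NULL,
                           method = c("signal", "diff", "active", "full",
                                      "active_acc"),
                           lag = 0L) {
  method <- match.arg(method)
  lag <- as.integer(lag)
  if (is.na(lag) || lag < 0L) stop("'lag' must be >= 0")
  if (method %in% c("signal", "diff")) {
    if (is.null(rec)) stop(sprintf("method '%s' needs a recording", method))
    stopifnot(inherits(rec, "recording"))
    X <- unclass(rec$traces)
    ids <- unit_ids(rec)
    if (method == "diff") X <- t(apply(X, 1L, trace_derivative))
  } else {
    if (is.null(mask))
      stop(sprintf("method '%s' needs an activity mask", method))
    stopifnot(inherits(mask, "activity_mask"))
    X <- mask$active * 1.0
    ids <- mask$unit_ids
  }
  if (nrow(X) < 2L) stop("need at least 2 units")
  if (method == "active_acc") {
    vals <- active_acc_matrix(X)
  } else {
    vals <- lagged_pearson(X, lag)
  }
  dimnames(vals) <- list(ids, ids)
  structure(vals, method = method, lag = lag, unit_ids = ids,
            class = c("correlation_matrix", "matrix", "array"))
}

# max-over-shifts Pearson matrix; shift 0 is plain cor(t(X))
lagged_pearson <- function(X, lag) {
  n <- ncol(X)
  guard_cor <- function(A, B = NULL) {
    r <- suppressWarnings(if (is.null(B)) stats::cor(A) else stats::cor(A, B))
    bad <- !is.finite(r)
    if (any(bad)) {
      warning("zero-variance series: correlation set to 0", call. = FALSE)
      r[bad] <- 0
    }
    r
  }
  best <- guard_cor(t(X))
  if (lag > 0L) {
    for (s in seq_len(min(lag, n - 2L))) {
      rs <- guard_cor(t(X[, 1:(n - s), drop = FALSE]),
                      t(X[, (1 + s):n, drop = FALSE]))
      best <- pmax(best, rs, t(rs))
    }
  }
  best <- pmax(best, t(best))    # covers negative shifts; exact symmetry
  diag(best) <- 1
  best
}

# coactivity-ratio matrix from a binary units x frames matrix
active_acc_matrix <- function(A) {
  inter <- A %*% t(A)
  s <- rowSums(A)
  denom <- outer(s, s, "+")
  vals <- ifelse(denom > 0, inter / denom, 0)
  vals
}

#' Coactivity ratio of two binary activity series
#'
#' Time both units are simultaneously active divided by the sum of their
#' individual active times: `|X & Y| / (|X| + |Y|)`, at most 0.5 (two
#' identical series), 0 for disjoint activity, and defined as 0 when both
#' series are entirely inactive.
#'
#' @param mask_x,mask_y Binary (0/1) vectors of equal length.
#' @return Scalar in \[0, 0.5\].
#' @export
active_acc <- function(mask_x, mask_y) {
  mask_x <- as.integer(mask_x != 0); mask_y <- as.integer(mask_y != 0)
  if (length(mask_x) != length(mask_y)) stop("series lengths differ")
  denom <- sum(mask_x) + sum(mask_y)
  if (denom == 0L) return(0)
  sum(mask_x & mask_y) / denom
}

#' @export
print.correlation_matrix <- function(x, ...) {
  v <- upper_tri_values(x)
  cat(sprintf(
    "<correlation_matrix '%s', lag %d>: %d units; off-diag mean %.3f [%.3f, %.3f]\n",
    attr(x, "method"), attr(x, "lag"), nrow(x), mean(v), min(v), max(v)))
  invisible(x)
}

upper_tri_values <- function(corr) corr[upper.tri(corr)]

#' Network degree curve
#'
#' Percentage of unordered unit pairs whose coefficient strictly exceeds
#' each threshold on the grid 0, 0.05, ..., 1.
#'
#' @param corr A `correlation_matrix` (or plain symmetric matrix).
#' @return Data frame of class `network_degree` with `threshold`,
#'   `percent`; `percent` is non-increasing in `threshold`.
#' @export
network_degree <- function(corr) {
  if (nrow(corr) < 2L) stop("need at least 2 units")
  v <- upper_tri_values(corr)
  thr <- seq(0, 1, by = 0.05)
  pct <- vapply(thr, function(t) 100 * mean(v > t), numeric(1))
  out <- data.frame(threshold = thr, percent = pct)
  class(out) <- c("network_degree", "data.frame")
  out
}

#' Per-unit connectivity shares
#'
#' For each unit, the percentage of its `n - 1` possible partners whose
#' pairwise coefficient strictly exceeds `threshold`. The mean over units
#' equals the network degree at the same threshold exactly (each pair is
#' counted twice in both normalizations).
#'
#' @param corr A `correlation_matrix`.
#' @param threshold Correlation threshold (default 0.3).
#' @return Data frame with `unit_id`, `n_partners`, `connectivity_pct`.
#' @export
connectivity <- function(corr, threshold = 0.3) {
  n <- nrow(corr)
  if (n < 2L) stop("need at least 2 units")
  above <- corr > threshold
  diag(above) <- FALSE
  cnt <- rowSums(above)
  ids <- attr(corr, "unit_ids")
  if (is.null(ids)) ids <- seq_len(n) - 1L
  data.frame(unit_id = ids, n_partners = cnt,
             connectivity_pct = 100 * cnt / (n - 1))
}

#' Percentile-based correlation clustering
#'
#' Two units are connected when their coefficient strictly exceeds the
#' `percentile` quantile (default 80th) of all off-diagonal values;
#' clusters are the connected components of that graph. Units with no
#' supra-percentile partner form singleton clusters.
#'
#' @param corr A `correlation_matrix`.
#' @param percentile Quantile of off-diagonal values used as the edge cut,
#'   in (0, 1).
#' @return Data frame with `unit_id`, `cluster` (1-based component label);
#'   the cut value is attached as attribute `cut`.
#' @export
correlation_clusters <- function(corr, percentile = 0.8) {
  n <- nrow(corr)
  if (n < 2L) stop("need at least 2 units")
  v <- upper_tri_values(corr)
  cut <- stats::quantile(v, percentile, names = FALSE)
  adj <- corr > cut
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  ids <- attr(corr, "unit_ids")
  if (is.null(ids)) ids <- seq_len(n) - 1L
  out <- data.frame(unit_id = ids, cluster = as.integer(comp))
  attr(out, "cut") <- cut
  out
}

#' Transfer entropy between two series
#'
#' Plug-in (maximum-likelihood histogram) estimate, in bits, of the
#' reduction in uncertainty about the receiver's next value gained from
#' the source's past `L` values beyond the receiver's own past `L` values:
#' `H(Y_t | Y_hist) - H(Y_t | Y_hist, X_hist)`. Continuous inputs are
#' discretized into `n_bins` quantile bins; series with at most `n_bins`
#' distinct values (e.g. binary activity) are used as-is. The estimate is
#' clamped at 0.
#'
#' @param source,receiver Numeric series of equal length `>= L + 2`.
#' @param L History length in frames (>= 1).
#' @param n_bins Number of quantile bins for continuous inputs.
#' @return Non-negative scalar, bits.
#' @export
#'
#' @examples
#' set.seed(1)
#' x <- rbinom(5000, 1, 0.5)
#' y <- c(0L, x[-5000])            # y is x delayed one frame
#' transfer_entropy(x, y, L = 1)   # close to 1 bit
transfer_entropy <- function(source, receiver, L = 1L, n_bins = 3L) {
  L <- as.integer(L)
  if (is.na(L) || L < 1L) stop("'L' must be >= 1")
  n <- length(source)
  if (length(receiver) != n) stop("series lengths differ")
  if (n < L + 2L) stop("series too short for history length L")
  xs <- discretize_series(source, n_bins)
  ys <- discretize_series(receiver, n_bins)
  t_idx <- (L + 1L):n
  yt <- ys[t_idx]
  yh <- history_symbols(ys, t_idx, L)
  xh <- history_symbols(xs, t_idx, L)
  H <- function(...) {
    p <- table(...)
    p <- p / sum(p)
    -sum(p[p > 0] * log2(p[p > 0]))
  }
  te <- H(yt, yh) - H(yh) - H(yt, yh, xh) + H(yh, xh)
  max(te, 0)
}

discretize_series <- function(x, n_bins) {
  ux <- unique(x)
  if (length(ux) <= n_bins) return(match(x, sort(ux)))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 2L) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

history_symbols <- function(s, t_idx, L) {
  h <- s[t_idx - 1L]
  if (L > 1L)
    for (l in 2:L)
      h <- paste(h, s[t_idx - l], sep = ".")
  h
}

#' Directed transfer-entropy matrix
#'
#' [transfer_entropy()] for every ordered unit pair (row = source,
#' column = receiver). The diagonal is set to 0.
#'
#' @param rec A [recording()] (continuous traces) or `NULL`.
#' @param mask An `activity_mask` to use binary activity instead of raw
#'   traces. Exactly one of `rec`/`mask` is used; `mask` wins.
#' @inheritParams transfer_entropy
#' @return Matrix of class `transfer_entropy_matrix`, bits.
#' @export
transfer_entropy_matrix <- function(rec = NULL, mask = NULL, L = 1L,
                                    n_bins = 3L) {
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "activity_mask"))
    X <- mask$active
    ids <- mask$unit_ids
  } else if (!is.null(rec)) {
    stopifnot(inherits(rec, "recording"))
    X <- unclass(rec$traces)
    ids <- unit_ids(rec)
  } else stop("provide a recording or an activity mask")
  nu <- nrow(X)
  out <- matrix(0, nu, nu, dimnames = list(ids, ids))
  for (i in seq_len(nu)) for (j in seq_len(nu)) if (i != j)
    out[i, j] <- transfer_entropy(X[i, ], X[j, ], L = L, n_bins = n_bins)
  structure(out, L = as.integer(L), unit_ids = ids,
            class = c("transfer_entropy_matrix", "matrix", "array"))
}

#' Summary statistics of a correlation matrix
#'
#' Mean, minimum, maximum and range (max minus min) of the off-diagonal
#' upper-triangle coefficients.
#'
#' @param corr A `correlation_matrix`.
#' @return Named list with `mean`, `min`, `max`, `range`.
#' @export
correlation_summary <- function(corr) {
  if (nrow(corr) < 2L) stop("need at least 2 units")
  v <- upper_tri_values(corr)
  list(mean = mean(v), min = min(v), max = max(v),
       range = max(v) - min(v))
}
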