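#' Standard per-recording metric feature vector
#'
#' Convenience aggregation of the package's metric families into one named
#' numeric vector per recording, suitable for [assemble_features()]:
#' burst-rate mean and median, mean network spike rate, mean network spike
#' peak, network spike duration, mean pairwise coefficient for each
#' requested correlation method, network degree at fixed thresholds,
#' correlation range, and (when positions are present) median rho and
#' median Euclidean / radial pair distances; optionally the mean transfer
#' entropy.
#'
#' @param rec A [recording()].
#' @param mask Its `activity_mask`.
#' @param cfg A [metric_config()].
#' @param corr_methods Correlation methods to summarize.
#' @param degree_thresholds Thresholds at which the network-degree curve
#'   is sampled.
#' @param include_te Add mean directed transfer entropy (binary activity,
#'   `L = 1`); off by default, it is the slowest metric.
#' @return Named numeric vector.
#' @export
recording_features <- function(rec, mask, cfg = metric_config(),
                               corr_methods = c("signal", "active"),
                               degree_thresholds = c(0.1, 0.3, 0.5),
                               include_te = FALSE) {
  out <- c()
  br <- burst_rate(mask)
  out["burst_rate_mean"] <- mean(br$rate_per_min)
  out["burst_rate_median"] <- stats::median(br$rate_per_min)
  out["nsr_mean"] <- mean(network_spike_rate(mask, cfg)$nsr_pct)
  out["nsp_mean"] <- mean(network_spike_peak(mask, cfg)$nsp_pct)
  out["nsd"] <- network_spike_duration(mask, cfg)
  for (m in corr_methods) {
    cm <- suppressWarnings(pearson_matrix(rec, mask, method = m))
    cs <- correlation_summary(cm)
    out[paste0("corr_mean_", m)] <- cs$mean
    out[paste0("corr_range_", m)] <- cs$range
    if (m == corr_methods[length(corr_methods)]) {
      nd <- network_degree(cm)
      for (t in degree_thresholds)
        out[sprintf("degree_at_%g", t)] <-
          nd$percent[which.min(abs(nd$threshold - t))]
    }
  }
  if (!is.null(rec$positions)) {
    out["rho_median"] <- stats::median(polar_rho(rec$positions))
    out["dist_euclidean_median"] <-
      stats::median(pair_distances(rec$positions, "euclidean")$distance)
    out["dist_radial_median"] <-
      stats::median(pair_distances(rec$positions, "radial")$distance)
  }
  if (include_te)
    out["te_mean"] <- {
      tm <- transfer_entropy_matrix(mask = mask, L = 1L)
      mean(tm[row(tm) != col(tm)])
    }
  out
}

#' Assemble a recording-by-metric feature matrix
#'
#' Binds per-recording named metric vectors into a matrix with a
#' deterministic column order (that of the first recording), and retains a
#' standardized (z-scored) copy alongside the raw values. Constant columns
#' cannot be standardized and are dropped with a warning.
#'
#' @param results Named list: one named numeric vector (e.g. from
#'   [recording_features()]) per recording.
#' @return An object of class `feature_matrix`: list with `raw`, `scaled`,
#'   `center`, `scale`, `dropped`.
#' @export
assemble_features <- function(results) {
  if (length(results) < 1L) stop("no recordings")
  if (is.null(names(results)) || any(names(results) == ""))
    names(results) <- paste0("recording_", seq_along(results))
  cols <- names(results[[1]])
  if (is.null(cols) || anyDuplicated(cols))
    stop("feature vectors must have unique names")
  for (nm in names(results)) {
    v <- results[[nm]]
    missing <- setdiff(cols, names(v))
    if (length(missing))
      stop(sprintf("recording '%s' is missing metric '%s'", nm, missing[1]))
    if (anyNA(v[cols]))
      stop(sprintf("recording '%s' has a missing value for metric '%s'",
                   nm, cols[which(is.na(v[cols]))[1]]))
  }
  raw <- do.call(rbind, lapply(results, function(v) v[cols]))
  dimnames(raw) <- list(names(results), cols)
  ctr <- colMeans(raw)
  scl <- apply(raw, 2L, stats::sd)
  scl[is.na(scl)] <- 1   # single recording: sd undefined, leave unscaled
  constant <- scl == 0
  if (any(constant))
    warning("dropping constant feature(s): ",
            paste(cols[constant], collapse = ", "), call. = FALSE)
  keep <- !constant
  scaled <- sweep(sweep(raw[, keep, drop = FALSE], 2L, ctr[keep]),
                  2L, scl[keep], "/")
  structure(list(raw = raw, scaled = scaled, center = ctr[keep],
                 scale = scl[keep], dropped = cols[constant]),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix>: %d recordings x %d features (%d dropped)\n",
              nrow(x$raw), ncol(x$scaled), length(x$dropped)))
  invisible(x)
}

#' PCA embedding of recording feature profiles
#'
#' Singular value decomposition of the standardized (column mean 0, sd 1)
#' feature matrix; the embedding coordinates are the projections onto the
#' top right-singular directions. The sign of each component is fixed so
#' that its largest-magnitude loading is positive, making coordinates
#' reproducible across runs and platforms.
#'
#' @param fm A [assemble_features()] result.
#' @param n_components Number of embedding axes to report (default 2,
#'   the "X"/"Y" plane).
#' @return An object of class `activity_pca`: list with `coordinates`
#'   (recordings x components), `explained` (variance fractions for all
#'   components, non-increasing, summing to 1), `loadings` (features x
#'   components), `n_components`.
#' @export
pca_embed <- function(fm, n_components = 2L) {
  stopifnot(inherits(fm, "feature_matrix"))
  X <- fm$scaled
  if (nrow(X) < 2L) stop("PCA requires at least two recordings")
  if (ncol(X) < 2L) stop("PCA requires at least two non-constant features")
  if (all(abs(X) < 1e-12)) stop("zero total variance: recordings identical")
  X <- sweep(X, 2L, colMeans(X))   # already ~0 from z-scoring; exactness
  s <- svd(X)
  flip <- vapply(seq_along(s$d), function(k) {
    j <- which.max(abs(s$v[, k]))
    if (s$v[j, k] < 0) -1 else 1
  }, numeric(1))
  v <- sweep(s$v, 2L, flip, "*")
  u <- sweep(s$u, 2L, flip, "*")
  scores <- u %*% diag(s$d, nrow = length(s$d))
  n_components <- min(n_components, length(s$d))
  coords <- scores[, seq_len(n_components), drop = FALSE]
  dimnames(coords) <- list(rownames(X),
                           paste0("PC", seq_len(n_components)))
  loadings <- v
  dimnames(loadings) <- list(colnames(X), paste0("PC", seq_along(s$d)))
  structure(list(coordinates = coords,
                 explained = s$d^2 / sum(s$d^2),
                 loadings = loadings,
                 n_components = n_components),
            class = "activity_pca")
}

#' @export
print.activity_pca <- function(x, ...) {
  cat(sprintf("<activity_pca>: %d recordings embedded in %d-D\n",
              nrow(x$coordinates), x$n_components))
  cat(sprintf("  explained variance: %s\n",
              paste(sprintf("PC%d %.1f%%", seq_along(x$explained),
                            100 * x$explained), collapse = ", ")))
  invisible(x)
}

#' @export
plot.activity_pca <- function(x, labels = NULL, ...) {
  co <- x$coordinates
  col <- if (is.null(labels)) "steelblue" else as.integer(factor(labels)) + 1L
  graphics::plot(co[, 1], co[, 2], pch = 19, col = col,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$explained[2]), ...)
  graphics::text(co[, 1], co[, 2], rownames(co), pos = 3, cex = 0.7)
  if (!is.null(labels))
    graphics::legend("topright", legend = levels(factor(labels)),
                     col = seq_len(nlevels(factor(labels))) + 1L, pch = 19)
  invisible(x)
}

#' Rank features by their contribution to the embedding
#'
#' Ranks features by loading magnitude along a chosen direction in the
#' embedding plane and reports, for each feature, the cosine similarity
#' between its 2-D loading vector and that direction. The direction is
#' either a principal-component axis (`component`), the 2-D loading norm
#' (`component = "norm"`), or — when `labels` are supplied — the
#' difference of group centroids in the embedding plane ("state"
#' direction).
#'
#' @param emb An [pca_embed()] result with `n_components >= 2`.
#' @param top_k How many most / least significant features to list
#'   (truncated with a warning when larger than the feature count).
#' @param component `1`, `2`, or `"norm"`; ignored when `labels` given.
#' @param labels Optional grouping labels, one per recording, with exactly
#'   two distinct values; the ranking direction is then the difference of
#'   the two group centroids.
#' @return List with `most` and `least` (character vectors, length
#'   `top_k`) and `table` (all features with `score` and `cosine`,
#'   sorted by decreasing score).
#' @export
rank_features <- function(emb, top_k = 8L, component = 1L, labels = NULL) {
  stopifnot(inherits(emb, "activity_pca"))
  L2 <- emb$loadings[, 1:2, drop = FALSE]
  nf <- nrow(L2)
  top_k <- as.integer(top_k)
  if (top_k > nf) {
    warning(sprintf("top_k truncated from %d to %d features", top_k, nf),
            call. = FALSE)
    top_k <- nf
  }
  if (!is.null(labels)) {
    labels <- as.factor(labels)
    if (nlevels(labels) != 2L)
      stop("'labels' must define exactly two groups")
    co <- emb$coordinates[, 1:2, drop = FALSE]
    dir <- colMeans(co[labels == levels(labels)[2], , drop = FALSE]) -
           colMeans(co[labels == levels(labels)[1], , drop = FALSE])
    if (sqrt(sum(dir^2)) == 0) stop("group centroids coincide")
  } else if (identical(component, "norm")) {
    dir <- NULL
  } else {
    component <- as.integer(component)
    stopifnot(component %in% c(1L, 2L))
    dir <- c(0, 0); dir[component] <- 1
  }
  norms <- sqrt(rowSums(L2^2))
  if (is.null(dir)) {
    score <- norms
    cosine <- rep(1, nf)   # each feature compared with its own direction
  } else {
    dir <- dir / sqrt(sum(dir^2))
    proj <- as.numeric(L2 %*% dir)
    score <- abs(proj)
    cosine <- ifelse(norms > 0, proj / norms, 0)
  }
  ord <- order(score, decreasing = TRUE)
  tab <- data.frame(feature = rownames(L2)[ord], score = score[ord],
                    cosine = cosine[ord], row.names = NULL)
  list(most = tab$feature[seq_len(top_k)],
       least = rev(tab$feature)[seq_len(top_k)],
       table = tab)
}
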