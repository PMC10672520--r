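fake_features <- function(n_rec, n_feat, seed = 1) {
  set.seed(seed)
  stats::setNames(
    lapply(seq_len(n_rec), function(i)
      stats::setNames(rnorm(n_feat), paste0("m", seq_len(n_feat)))),
    paste0("rec", seq_len(n_rec)))
}

test_that("assemble_features validates, standardizes and drops constants", {
  fm <- assemble_features(fake_features(3, 12))
  expect_equal(dim(fm$raw), c(3L, 12L))
  expect_true(all(abs(colMeans(fm$scaled)) < 1e-12))
  expect_true(all(abs(apply(fm$scaled, 2, sd) - 1) < 1e-12))
  # missing metric errors with recording and metric name
  bad <- fake_features(3, 5)
  bad[[2]] <- bad[[2]][-3]
  expect_error(assemble_features(bad), "rec2.*m3")
  # constant column dropped with warning
  cst <- fake_features(4, 4)
  for (i in seq_along(cst)) cst[[i]]["m2"] <- 7
  expect_warning(fm2 <- assemble_features(cst), "constant.*m2")
  expect_false("m2" %in% colnames(fm2$scaled))
  expect_identical(fm2$dropped, "m2")
})

test_that("SVD embedding matches the covariance-eigendecomposition oracle", {
  set.seed(111)
  for (rep in 1:10) {
    feats <- fake_features(6, 8, seed = rep)
    fm <- assemble_features(feats)
    emb <- pca_embed(fm)
    X <- sweep(fm$scaled, 2, colMeans(fm$scaled))
    eig <- eigen(stats::cov(X))
    scores <- X %*% eig$vectors
    for (k in 1:2) {
      a <- emb$coordinates[, k]; b <- scores[, k]
      expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-8)
    }
    # explained-variance fractions from eigenvalues agree too
    ev <- eig$values / sum(eig$values)
    expect_equal(emb$explained[1:2], ev[1:2], tolerance = 1e-8)
  }
})

test_that("explained variance sums to 1 and collinear data load on PC1", {
  feats <- fake_features(5, 7, seed = 2)
  emb <- pca_embed(assemble_features(feats))
  expect_equal(sum(emb$explained), 1)
  expect_true(all(diff(emb$explained) <= 1e-12))
  # points on a line in feature space: PC1 carries everything
  t <- 1:6
  lin <- stats::setNames(
    lapply(t, function(ti) c(m1 = 2 * ti, m2 = -ti + 3, m3 = 0.5 * ti)),
    paste0("r", t))
  emb_lin <- pca_embed(assemble_features(lin))
  expect_equal(emb_lin$explained[1], 1, tolerance = 1e-12)
})

test_that("degenerate inputs are refused with clear errors", {
  feats <- fake_features(1, 5)
  expect_error(pca_embed(assemble_features(feats)), "two recordings")
  dup <- fake_features(3, 5, seed = 3)
  dup[[2]] <- dup[[1]]; dup[[3]] <- dup[[1]]
  expect_error(suppressWarnings(pca_embed(assemble_features(dup))))
})

test_that("embedding is reproducible and invariant where it should be", {
  feats <- fake_features(6, 9, seed = 4)
  fm <- assemble_features(feats)
  e1 <- pca_embed(fm); e2 <- pca_embed(fm)
  expect_identical(e1$coordinates, e2$coordinates)
  # sign convention: largest-magnitude loading of each component positive
  for (k in 1:2) {
    lk <- e1$loadings[, k]
    expect_gt(lk[which.max(abs(lk))], 0)
  }
  # row permutation permutes coordinates (up to nothing else)
  perm <- c(3, 1, 6, 2, 5, 4)
  fmp <- assemble_features(feats[perm])
  ep <- pca_embed(fmp)
  expect_equal(abs(ep$coordinates[order(perm), 1]),
               abs(e1$coordinates[, 1]), tolerance = 1e-8,
               ignore_attr = TRUE)
  # feature-column permutation leaves inter-point distances unchanged
  featc <- lapply(feats, function(v) v[c(5:9, 1:4)])
  ec <- pca_embed(assemble_features(featc))
  expect_equal(as.numeric(dist(ec$coordinates)),
               as.numeric(dist(e1$coordinates)), tolerance = 1e-8)
})

test_that("feature ranking finds dominant features and bounds cosines", {
  set.seed(112)
  n <- 8
  feats <- stats::setNames(
    lapply(1:n, function(i) {
      v <- rnorm(10, sd = 0.2)
      v[1] <- rnorm(1, sd = 10)   # m1 dominates the variance
      stats::setNames(v, paste0("m", 1:10))
    }), paste0("r", 1:n))
  fm0 <- assemble_features(feats)
  # rank on the raw (unstandardized) scale where m1 dominates
  fm0$scaled <- sweep(fm0$raw, 2, colMeans(fm0$raw))
  emb <- pca_embed(fm0)
  rk <- rank_features(emb, top_k = 3)
  expect_equal(rk$most[1], "m1")
  expect_true(all(abs(rk$table$cosine) <= 1 + 1e-12))
  expect_equal(nrow(rk$table), 10L)
  # truncation warning
  expect_warning(rank_features(emb, top_k = 50), "truncated")
  # state-direction ranking via group labels
  labs <- rep(c("ctrl", "x"), each = 4)
  rk2 <- rank_features(emb, top_k = 2, labels = labs)
  expect_equal(length(rk2$most), 2L)
  expect_error(rank_features(emb, labels = rep("a", n)), "two groups")
})

test_that("embed_recordings wires metrics through to an embedding", {
  recs <- lapply(1:3, function(s)
    generate_recording(synth_config(n_units = 6, n_frames = 600,
                                    seed = s))$recording)
  names(recs) <- paste0("run", 1:3)
  out <- suppressWarnings(embed_recordings(recs))
  expect_s3_class(out$embedding, "activity_pca")
  expect_equal(nrow(out$embedding$coordinates), 3L)
})
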