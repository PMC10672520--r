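make_rec <- function(X, fps = 20) recording(trace_matrix(X, fps))

test_that("pearson matrix matches the textbook formula and limit cases", {
  set.seed(61)
  X <- matrix(rnorm(50 * 200), 50)
  cm <- pearson_matrix(make_rec(X), method = "signal")
  for (pair in list(c(1, 2), c(3, 17), c(49, 50)))
    expect_equal(cm[pair[1], pair[2]],
                 oracle_pearson(X[pair[1], ], X[pair[2], ]),
                 tolerance = 1e-12)
  expect_true(isSymmetric(unclass(cm)))
  expect_equal(unname(diag(cm)), rep(1, 50))
  # identical and negated traces
  Y <- rbind(X[1, ], X[1, ], -X[1, ])
  cm2 <- pearson_matrix(make_rec(Y), method = "signal")
  expect_equal(cm2[1, 2], 1)
  expect_equal(cm2[1, 3], -1)
})

test_that("lagged correlation maximizes over shifts and reduces at lag 0", {
  set.seed(62)
  x <- rnorm(400)
  y <- c(rnorm(2), x[1:398])   # y is x delayed by 2 frames
  rec <- make_rec(rbind(x, y))
  expect_lt(pearson_matrix(rec, method = "signal", lag = 0)[1, 2], 0.5)
  expect_equal(pearson_matrix(rec, method = "signal", lag = 2)[1, 2], 1,
               tolerance = 1e-9)
  # lag 0 is exactly plain Pearson
  X <- matrix(rnorm(10 * 100), 10)
  expect_equal(unclass(pearson_matrix(make_rec(X), method = "signal",
                                      lag = 0)),
               unclass(pearson_matrix(make_rec(X), method = "signal")),
               ignore_attr = TRUE)
})

test_that("diff method correlates the derivative series", {
  set.seed(63)
  X <- matrix(rnorm(4 * 150), 4)
  cm <- pearson_matrix(make_rec(X), method = "diff")
  d1 <- trace_derivative(X[1, ]); d2 <- trace_derivative(X[2, ])
  expect_equal(cm[1, 2], oracle_pearson(d1, d2), tolerance = 1e-12)
})

test_that("zero-variance series give r = 0 with a warning", {
  X <- rbind(rep(1, 50), rnorm(50))
  expect_warning(cm <- pearson_matrix(make_rec(X), method = "signal"),
                 "zero-variance")
  expect_equal(cm[1, 2], 0)
})

test_that("active_acc implements the intersection-over-sum ratio", {
  a <- rep(c(1L, 0L), each = 40)
  expect_equal(active_acc(a, a), 0.5)             # identical masks
  expect_equal(active_acc(a, 1L - a), 0)          # disjoint masks
  expect_equal(active_acc(a, rep(0L, 80)), 0)     # one empty mask
  expect_equal(active_acc(rep(0L, 9), rep(0L, 9)), 0)
  set.seed(64)
  x <- rbinom(100, 1, 0.4); y <- rbinom(100, 1, 0.4)
  expect_equal(active_acc(x, y), sum(x & y) / (sum(x) + sum(y)))
  expect_equal(active_acc(x, y), active_acc(y, x))
})

test_that("active_acc matrix is symmetric with 0.5 diagonal for active units", {
  set.seed(65)
  mask <- random_mask(6, 200, 0.3)
  mask$active[6, ] <- 0L
  mask <- activity_mask(mask$active, fps = 20)
  cm <- pearson_matrix(mask = mask, method = "active_acc")
  expect_true(isSymmetric(unclass(cm)))
  expect_equal(unname(diag(cm)), c(rep(0.5, 5), 0))
  expect_true(all(cm >= 0 & cm <= 0.5))
})

test_that("network degree equals brute-force counting on the 0.05 grid", {
  set.seed(66)
  mask <- random_mask(12, 500, 0.2)
  cm <- pearson_matrix(mask = mask, method = "active")
  nd <- network_degree(cm)
  expect_equal(nd$threshold, seq(0, 1, 0.05))
  v <- cm[upper.tri(cm)]
  for (i in seq_len(nrow(nd)))   # exact counts; float order differs at 1 ulp
    expect_equal(nd$percent[i],
                 100 * sum(v > nd$threshold[i]) / length(v),
                 tolerance = 1e-12)
  expect_true(all(diff(nd$percent) <= 0))
  expect_equal(nd$percent[nd$threshold == 1], 0)   # strict inequality
})

test_that("degenerate correlation matrices give boundary degree curves", {
  ones <- matrix(1, 5, 5)
  attr(ones, "unit_ids") <- 0:4
  nd1 <- network_degree(ones)
  expect_true(all(nd1$percent[nd1$threshold < 1] == 100))
  zeros <- diag(5)
  nd0 <- network_degree(zeros)
  expect_true(all(nd0$percent == 0))
})

test_that("mean connectivity equals network degree at the same threshold", {
  set.seed(67)
  mask <- random_mask(10, 400, 0.25)
  cm <- pearson_matrix(mask = mask, method = "active")
  for (thr in c(0.0, 0.1, 0.3)) {
    conn <- connectivity(cm, thr)
    nd <- network_degree(cm)
    expect_equal(mean(conn$connectivity_pct),
                 nd$percent[abs(nd$threshold - thr) < 1e-9])
  }
  # hand example: 3 of 9 partners above threshold -> 33.33%
  m <- diag(10); m[1, 2:4] <- m[2:4, 1] <- 0.9
  expect_equal(connectivity(m, 0.5)$connectivity_pct[1], 100 / 3)
})

test_that("percentile clustering separates blocks and respects symmetry", {
  # two 3-unit blocks among 10 units: within-block pairs (6 of 45) sit
  # above the 80th percentile of the off-diagonal values, the rest at 0
  m <- matrix(0, 10, 10)
  m[1:3, 1:3] <- 0.9; m[4:6, 4:6] <- 0.9; diag(m) <- 1
  attr(m, "unit_ids") <- 0:9
  cl <- correlation_clusters(m)
  sizes <- table(cl$cluster)
  expect_equal(sum(sizes > 1), 2L)               # exactly 2 multi-unit clusters
  expect_equal(cl$cluster[1:3], rep(cl$cluster[1], 3))
  expect_equal(cl$cluster[4:6], rep(cl$cluster[4], 3))
  # all-equal off-diagonal: strict cut yields no edges -> all singletons
  flat <- matrix(0.4, 5, 5); diag(flat) <- 1
  attr(flat, "unit_ids") <- 0:4
  expect_equal(length(unique(correlation_clusters(flat)$cluster)), 5L)
  # permutation invariance up to relabeling
  set.seed(68)
  mask <- random_mask(8, 300, 0.3)
  cm <- pearson_matrix(mask = mask, method = "active")
  perm <- sample(8)
  cmp <- unclass(cm)[perm, perm]
  attr(cmp, "unit_ids") <- attr(cm, "unit_ids")[perm]
  cl1 <- correlation_clusters(cm)$cluster
  cl2 <- correlation_clusters(cmp)$cluster[order(perm)]
  expect_equal(outer(cl1, cl1, "=="), outer(cl2, cl2, "=="),
               ignore_attr = TRUE)
})

test_that("transfer entropy detects deterministic coupling", {
  set.seed(69)
  x <- rbinom(5000, 1, 0.5)
  y <- c(0L, x[-5000])
  expect_lt(abs(transfer_entropy(x, y, L = 1) - 1), 0.02)
  # reverse direction carries almost nothing
  expect_lt(transfer_entropy(y, x, L = 1), 0.05)
})

test_that("transfer entropy is ~0 for independent series and edge cases", {
  set.seed(70)
  te <- replicate(20, {
    x <- rbinom(5000, 1, 0.5); y <- rbinom(5000, 1, 0.5)
    transfer_entropy(x, y, L = 1)
  })
  expect_lte(mean(te), 0.01)
  expect_true(all(te >= 0))
  x <- rbinom(500, 1, 0.5)
  expect_equal(transfer_entropy(x, rep(1L, 500), L = 1), 0)  # constant receiver
  expect_equal(transfer_entropy(x, x, L = 1), 0)             # self TE
  expect_error(transfer_entropy(1:3, 1:3, L = 5), "too short")
})

test_that("correlation summary reports the off-diagonal statistics", {
  m <- matrix(0.5, 4, 4); diag(m) <- 1
  cs <- correlation_summary(m)
  expect_equal(cs$mean, 0.5)
  expect_equal(cs$range, 0)
  set.seed(71)
  mask <- random_mask(7, 300, 0.25)
  cm <- pearson_matrix(mask = mask, method = "active")
  v <- cm[upper.tri(cm)]
  cs2 <- correlation_summary(cm)
  expect_equal(cs2$mean, mean(v))
  expect_equal(cs2$range, max(v) - min(v))
})
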