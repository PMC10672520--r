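test_that("center of mass and rho match hand geometry", {
  pos <- neuron_positions(0:1, c(0, 2), c(0, 0))
  expect_equal(unname(center_of_mass(pos)), c(1, 0))
  one <- neuron_positions(0L, 5, 7)
  expect_equal(unname(center_of_mass(one)), c(5, 7))
  expect_equal(unname(polar_rho(one)), 0)
  # 3-4-5 triangle offset from the center
  p <- neuron_positions(0:1, c(0, 6), c(0, 8))   # center (3, 4)
  expect_equal(unname(polar_rho(p)), c(5, 5))
})

test_that("pair distances: euclidean, radial and their inequality", {
  p <- neuron_positions(0:1, c(0, 3), c(0, 4))
  expect_equal(pair_distances(p, "euclidean")$distance, 5)
  # equidistant units from the center have radial distance 0
  q <- neuron_positions(0:1, c(-1, 1), c(0, 0))
  expect_equal(pair_distances(q, "radial")$distance, 0)
  set.seed(81)
  for (rep in 1:20) {
    n <- sample(3:30, 1)
    layout <- neuron_positions(seq_len(n) - 1, runif(n, 0, 300),
                               runif(n, 0, 300))
    eu <- pair_distances(layout, "euclidean")$distance
    ra <- pair_distances(layout, "radial")$distance
    expect_true(all(ra <= eu + 1e-12))
    expect_true(all(eu >= 0))
  }
})

test_that("distances are invariant under translation and rotation", {
  set.seed(82)
  n <- 15
  x <- runif(n, 0, 100); y <- runif(n, 0, 100)
  p0 <- neuron_positions(seq_len(n) - 1, x, y)
  # translation
  p1 <- neuron_positions(seq_len(n) - 1, x + 12.5, y - 3.25)
  expect_equal(unname(center_of_mass(p1)),
               unname(center_of_mass(p0)) + c(12.5, -3.25))
  expect_equal(polar_rho(p1), polar_rho(p0), tolerance = 1e-9)
  # rotation about the center of mass
  cm <- center_of_mass(p0)
  th <- 0.7
  xr <- cm["x"] + cos(th) * (x - cm["x"]) - sin(th) * (y - cm["y"])
  yr <- cm["y"] + sin(th) * (x - cm["x"]) + cos(th) * (y - cm["y"])
  p2 <- neuron_positions(seq_len(n) - 1, xr, yr)
  expect_equal(polar_rho(p2), polar_rho(p0), tolerance = 1e-9)
  expect_equal(pair_distances(p2, "euclidean")$distance,
               pair_distances(p0, "euclidean")$distance, tolerance = 1e-9)
})

test_that("distance factor has the stated fixed points and monotonicity", {
  expect_equal(distance_factor(0, 100), 0)
  expect_equal(distance_factor(100, 100), 0.5)    # dist = d0
  d <- seq(0, 5000, by = 50)
  k <- distance_factor(d, 100)
  expect_true(all(diff(k) > 0))
  expect_true(all(k >= 0 & k < 1))
  expect_error(distance_factor(10, 0), "d0")
  # median of k at d0 = median distance is exactly 0.5 (odd pair count so
  # the median is an observed distance)
  set.seed(83)
  p <- neuron_positions(0:18, runif(19, 0, 300), runif(19, 0, 300))
  dd <- pair_distances(p, "euclidean")$distance   # 171 pairs
  expect_equal(stats::median(distance_factor(dd, stats::median(dd))), 0.5)
})

test_that("correlation-vs-distance produces the three dependence outputs", {
  set.seed(84)
  sim <- generate_recording(synth_config(n_units = 12, n_frames = 1200,
                                         seed = 15))
  rec <- sim$recording
  mask <- segment_recording(rec)
  corr <- pearson_matrix(rec, mask, method = "active")
  dep <- correlation_vs_distance(rec, mask, corr, kind = "euclidean",
                                 weighted = TRUE)
  expect_equal(nrow(dep$pairs), 12 * 11 / 2)       # scatter row count
  expect_true(all(dep$per_unit$active_ratio >= 0 &
                  dep$per_unit$active_ratio <= 1))
  expect_true(all(dep$pairs$k >= 0 & dep$pairs$k < 1))
  expect_equal(dep$pairs$weighted_r, dep$pairs$r * dep$pairs$k)
  # planted linear dependence: fluorescence proportional to rho -> r = 1
  rho <- polar_rho(rec$positions)
  X <- matrix(rep(2 + 0.05 * rho, 1200), nrow = 12)
  lin <- recording(trace_matrix(X + 0, fps = 20), rec$positions)
  mlin <- activity_mask(matrix(0L, 12, 1200), fps = 20)
  dep2 <- suppressWarnings(correlation_vs_distance(lin, mlin, corr))
  expect_equal(dep2$fluorescence_r, 1, tolerance = 1e-9)
  # all units at one point: zero-variance guard
  same <- neuron_positions(0:11, rep(5, 12), rep(5, 12))
  rec_same <- recording(trace_matrix(unclass(rec$traces), 20), same)
  w <- testthat::capture_warnings(
    dep3 <- correlation_vs_distance(rec_same, mask, corr))
  expect_match(w, "zero-variance", all = TRUE)
  expect_equal(dep3$fluorescence_r, 0)
})

test_that("distance analysis refuses recordings without positions", {
  sim <- generate_recording(synth_config(n_units = 5, n_frames = 600,
                                         seed = 16))
  rec <- recording(sim$recording$traces, positions = NULL)
  mask <- segment_recording(rec)
  corr <- pearson_matrix(rec, mask, method = "active")
  expect_error(correlation_vs_distance(rec, mask, corr),
               "requires positions")
})
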