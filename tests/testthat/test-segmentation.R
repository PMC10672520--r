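test_that("moving average matches hand-computed examples and edge rules", {
  expect_equal(smooth_trace(c(0, 0, 3, 0, 0), 3), c(0, 1, 1, 1, 0))
  v <- rnorm(50)
  expect_identical(smooth_trace(v, 1), v)           # identity window
  expect_equal(smooth_trace(rep(2.5, 30), 10), rep(2.5, 30))  # constant
  # edge renormalization: first sample of an increasing ramp
  expect_equal(smooth_trace(c(1, 2, 3, 4, 5), 3)[1], 1.5)
  expect_error(smooth_trace(v, 0), "wnd_size")
})

test_that("moving average equals the loop-based oracle", {
  set.seed(101)
  for (wnd in c(1, 2, 3, 7, 10)) {
    x <- rnorm(83)
    expect_equal(smooth_trace(x, wnd), oracle_smooth(x, wnd),
                 tolerance = 1e-12)
  }
})

test_that("derivative has the stated form and inverts cumsum", {
  expect_equal(trace_derivative(c(1, 3, 2)), c(0, 2, -1))
  expect_equal(trace_derivative(rep(4, 10)), rep(0, 10))
  set.seed(7)
  v <- rnorm(100)
  expect_equal(trace_derivative(cumsum(v))[-1], v[-1], tolerance = 1e-12)
  expect_error(trace_derivative(1), "length")
})

test_that("adaptive threshold is median plus mean absolute deviation", {
  expect_equal(adaptive_threshold(rep(0, 10)), 0)
  expect_equal(adaptive_threshold(c(0, 0, 10, 0, 0)), 2)  # median 0, mad 2
  set.seed(8)
  d <- rnorm(200)
  expect_equal(adaptive_threshold(d + 3.7), adaptive_threshold(d) + 3.7,
               tolerance = 1e-12)   # translation equivariance
})

test_that("warm merges short gaps and cold drops short intervals, in order", {
  iv <- data.frame(start = c(10L, 24L), end = c(20L, 30L))
  expect_equal(refine_intervals(iv, warm = 10, cold = 0),
               data.frame(start = 10L, end = 30L))
  expect_equal(nrow(refine_intervals(data.frame(start = 10L, end = 15L),
                                     warm = 0, cold = 8)), 0L)
  expect_equal(refine_intervals(iv, 0, 0), iv)   # defaults-off identity
  # warm-merge happens before cold-drop: two 3-frame bursts 2 frames apart
  # survive cold = 5 because the merge makes an 8-frame interval first
  iv2 <- data.frame(start = c(0L, 5L), end = c(3L, 8L))
  expect_equal(refine_intervals(iv2, warm = 3, cold = 5),
               data.frame(start = 0L, end = 8L))
})

test_that("a flat trace yields no active states", {
  res <- segment_trace(rep(1, 100), seg_params())
  expect_equal(nrow(res$intervals), 0L)
  expect_equal(sum(res$active), 0L)
})

test_that("segmentation equals the straight-line oracle frame-exactly", {
  set.seed(42)
  for (rep in 1:30) {
    x <- random_trace(n = sample(60:200, 1), n_events = sample(0:4, 1))
    wnd <- sample(c(1, 5, 10), 1)
    warm <- sample(c(0, 5, 15), 1)
    cold <- sample(c(0, 3), 1)
    mode <- sample(c("spike", "full"), 1)
    got <- segment_trace(x, seg_params(wnd, warm, cold, mode))
    want <- oracle_segment(x, wnd, warm, cold, mode)
    expect_identical(got$active, want$active)
    expect_equal(got$intervals, want$intervals)
  }
})

test_that("spike-mode active frames are a subset of full-mode frames", {
  set.seed(43)
  for (rep in 1:25) {
    x <- random_trace(200, n_events = sample(1:4, 1))
    sp <- segment_trace(x, seg_params(mode = "spike"))
    fu <- segment_trace(x, seg_params(mode = "full"))
    expect_true(all(fu$active[sp$active == 1L] == 1L))
  }
})

test_that("interval lists and binary matrix stay consistent", {
  set.seed(44)
  sim <- generate_recording(synth_config(n_units = 8, n_frames = 800,
                                         seed = 9))
  mask <- segment_recording(sim$recording)
  for (i in seq_len(n_units(mask)))
    expect_identical(miniact:::intervals_to_binary(mask$intervals[[i]],
                                                   n_frames(mask)),
                     mask$active[i, ])
})

test_that("segmentation is deterministic and refinement is monotone", {
  sim <- generate_recording(synth_config(n_units = 5, n_frames = 1000,
                                         seed = 10))
  m1 <- segment_recording(sim$recording)
  m2 <- segment_recording(sim$recording)
  expect_identical(m1$active, m2$active)
  # more warm merging never increases the interval count;
  # more cold dropping never increases total active time
  x <- sim$recording$traces[1, ]
  n_iv <- sapply(c(0, 5, 15, 40), function(w)
    nrow(segment_trace(x, seg_params(warm = w))$intervals))
  expect_true(all(diff(n_iv) <= 0))
  act <- sapply(c(0, 2, 5, 10), function(cd)
    sum(segment_trace(x, seg_params(cold = cd))$active))
  expect_true(all(diff(act) <= 0))
})

test_that("worked fixture segments into the hand-derived pattern", {
  fx <- generate_worked_fixture()
  mask <- segment_recording(fx$recording, seg_params())
  expect_equal(vapply(mask$intervals, nrow, integer(1)),
               fx$expected_n_intervals)
  # without warm merging the third unit shows its two separate transients
  mask0 <- segment_recording(fx$recording, seg_params(warm = 0))
  expect_equal(nrow(mask0$intervals[[3]]), 2L)
  # every planted rise intersects exactly one detected interval
  oracle <- oracle_segment(fx$recording$traces[1, ], 10, 15, 0)
  expect_equal(mask$intervals[[1]], oracle$intervals)
})

test_that("noiseless planted events are recovered perfectly", {
  sim <- generate_recording(synth_config(n_units = 20, n_frames = 3000,
                                         noise_sd = 0, seed = 12))
  mask <- segment_recording(sim$recording)
  rec <- event_recovery(mask, sim$ground_truth)
  expect_equal(rec$recall, 1.0)
  expect_equal(rec$precision, 1.0)
})
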