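# Straight-line reference implementations used as independent oracles.
# Deliberately loop-based and separate from the package internals.

oracle_smooth <- function(x, wnd) {
  n <- length(x)
  k <- wnd %/% 2
  s <- numeric(n)
  for (t in seq_len(n)) {
    tot <- 0; cnt <- 0
    for (i in (-k):k) {
      if (t - i >= 1 && t - i <= n) {
        tot <- tot + x[t - i]
        cnt <- cnt + 1
      }
    }
    s[t] <- tot / cnt
  }
  s
}

oracle_segment <- function(x, wnd, warm, cold, mode = "spike") {
  n <- length(x)
  s <- oracle_smooth(x, wnd)
  d <- numeric(n)
  for (t in 2:n) d[t] <- s[t] - s[t - 1]
  med <- stats::median(d)
  thr <- med + mean(abs(d - med))
  act <- d > thr
  # runs of TRUE -> half-open 0-based intervals
  starts <- c(); ends <- c()
  t <- 1
  while (t <= n) {
    if (act[t]) {
      s0 <- t
      while (t <= n && act[t]) t <- t + 1
      starts <- c(starts, s0 - 1); ends <- c(ends, t - 1)
    } else t <- t + 1
  }
  if (mode == "full" && length(starts) > 0) {
    for (i in seq_along(starts)) {
      base <- s[starts[i] + 1]
      cap <- if (i < length(starts)) starts[i + 1] else n
      e <- ends[i]
      while (e < cap && s[e + 1] > base) e <- e + 1
      ends[i] <- e
    }
  }
  # warm merge
  if (length(starts) > 1 && warm > 0) {
    ms <- starts[1]; me <- ends[1]
    out_s <- c(); out_e <- c()
    for (i in 2:length(starts)) {
      if (starts[i] - me < warm) me <- ends[i]
      else { out_s <- c(out_s, ms); out_e <- c(out_e, me)
             ms <- starts[i]; me <- ends[i] }
    }
    starts <- c(out_s, ms); ends <- c(out_e, me)
  }
  # cold drop
  if (cold > 0 && length(starts) > 0) {
    keep <- (ends - starts) >= cold
    starts <- starts[keep]; ends <- ends[keep]
  }
  bin <- integer(n)
  if (length(starts) > 0)
    for (i in seq_along(starts)) bin[(starts[i] + 1):ends[i]] <- 1L
  list(intervals = data.frame(start = as.integer(starts),
                              end = as.integer(ends)),
       active = bin)
}

# textbook Pearson coefficient, elementwise loops
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  num / sqrt(dx * dy)
}

# random piecewise calcium-like trace for property tests
random_trace <- function(n = 200, n_events = 3, noise = 0.05) {
  tr <- numeric(n)
  if (n_events > 0) {
    onsets <- sort(sample.int(n - 20, n_events))
    for (o in onsets) {
      rise <- sample(2:6, 1); amp <- runif(1, 0.5, 2)
      idx <- o:min(o + rise, n - 1)
      tr[idx + 1] <- tr[idx + 1] + amp * (idx - o) / rise
      dec <- (o + rise + 1):min(o + rise + 60, n - 1)
      if (length(dec) > 0 && dec[1] <= n - 1)
        tr[dec + 1] <- tr[dec + 1] + amp * exp(-(dec - o - rise) / 15)
    }
  }
  tr + rnorm(n, 0, noise)
}

random_mask <- function(n_units = 10, n_frames = 600, p = 0.2) {
  activity_mask(matrix(rbinom(n_units * n_frames, 1, p), n_units), fps = 20)
}
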