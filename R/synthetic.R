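#' Configuration for the synthetic recording generator
#'
#' Describes a calcium-imaging-like recording with known ground truth.
#' Each unit fires homogeneous-Poisson events; every event contributes a
#' GCaMP-like kernel (linear rise to the event amplitude over
#' `rise_frames`, then exponential decay with time constant
#' `decay_tau_frames`), and white Gaussian noise is added on top. Units
#' can be organized into correlated groups that share event onsets up to a
#' uniform jitter; unit centroids are placed uniformly in a square pixel
#' arena. Defaults mirror a typical 20-fps miniscope recording of a slow
#' indicator: 5-frame rise, 40-frame decay, amplitude 1 with noise sd 0.1
#' (signal-to-noise 10), 2 events per minute per unit.
#'
#' @param n_units Number of units.
#' @param n_frames Recording length in frames.
#' @param fps Frames per second.
#' @param event_rate Events per minute per unit.
#' @param rise_frames Rise duration of the event kernel, frames.
#' @param decay_tau_frames Decay time constant, frames.
#' @param amp_mean,amp_sd Event amplitude distribution (Normal truncated
#'   at 0).
#' @param noise_sd White-noise standard deviation.
#' @param n_correlated_groups Number of groups sharing onsets (0 =
#'   independent units; otherwise all units are assigned round-robin).
#' @param jitter_frames Uniform within-group onset jitter, +/- frames.
#' @param arena_size_px Side of the square arena, pixels.
#' @param seed RNG seed (`NULL` = current RNG state).
#'
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_units = 100L, n_frames = 6000L, fps = 20,
                         event_rate = 2, rise_frames = 5L,
                         decay_tau_frames = 40, amp_mean = 1, amp_sd = 0.2,
                         noise_sd = 0.1, n_correlated_groups = 0L,
                         jitter_frames = 2L, arena_size_px = 300,
                         seed = NULL) {
  stopifnot(n_units >= 1, n_frames >= 2, fps > 0, event_rate >= 0,
            rise_frames >= 1, decay_tau_frames >= 0, amp_mean >= 0,
            amp_sd >= 0, noise_sd >= 0, n_correlated_groups >= 0,
            jitter_frames >= 0, arena_size_px > 0)
  structure(list(n_units = as.integer(n_units),
                 n_frames = as.integer(n_frames), fps = fps,
                 event_rate = event_rate,
                 rise_frames = as.integer(rise_frames),
                 decay_tau_frames = decay_tau_frames, amp_mean = amp_mean,
                 amp_sd = amp_sd, noise_sd = noise_sd,
                 n_correlated_groups = as.integer(n_correlated_groups),
                 jitter_frames = as.integer(jitter_frames),
                 arena_size_px = arena_size_px,
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "synth_config")
}

# add one event kernel (linear rise + exponential decay) into a trace
add_kernel <- function(trace, onset, amp, rise, tau) {
  n <- length(trace)
  ri <- onset:min(onset + rise, n - 1L)               # 0-based frames
  trace[ri + 1L] <- trace[ri + 1L] + amp * (ri - onset) / rise
  dstart <- onset + rise + 1L
  if (tau > 0 && dstart <= n - 1L) {
    di <- dstart:min(dstart + ceiling(8 * tau), n - 1L)
    trace[di + 1L] <- trace[di + 1L] + amp * exp(-(di - onset - rise) / tau)
  }
  trace
}

#' Generate a synthetic recording with ground truth
#'
#' See [synth_config()] for the generative model. Fully reproducible from
#' the config seed.
#'
#' @param cfg A [synth_config()].
#' @return List with `recording` (a [recording()] with positions) and
#'   `ground_truth`: list with `events` (one data frame per unit: `onset`,
#'   `rise_end`, `extent_end` — half-open 0-based frames of the rise and
#'   of the whole kernel), `group` (integer group per unit, NA when
#'   ungrouped) and `positions` (the true layout).
#' @export
#'
#' @examples
#' sim <- generate_recording(synth_config(n_units = 4, n_frames = 1200,
#'                                        seed = 7))
#' sim$recording
#' head(sim$ground_truth$events[[1]])
generate_recording <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  nu <- cfg$n_units; nf <- cfg$n_frames
  minutes <- nf / cfg$fps / 60
  max_events <- max(1L, nf %/% (cfg$rise_frames + 2L))
  group <- rep(NA_integer_, nu)
  if (cfg$n_correlated_groups > 0L)
    group <- rep(seq_len(cfg$n_correlated_groups), length.out = nu)
  # group-shared onset trains (drawn once per group)
  group_onsets <- NULL
  if (cfg$n_correlated_groups > 0L)
    group_onsets <- lapply(seq_len(cfg$n_correlated_groups), function(g)
      draw_onsets(cfg, minutes, max_events))
  traces <- matrix(0, nu, nf)
  events <- vector("list", nu)
  for (i in seq_len(nu)) {
    onsets <- if (!is.na(group[i])) {
      jit <- if (cfg$jitter_frames > 0L)
        sample.int(2L * cfg$jitter_frames + 1L,
                   length(group_onsets[[group[i]]]),
                   replace = TRUE) - cfg$jitter_frames - 1L
      else 0L
      pmin(pmax(group_onsets[[group[i]]] + jit, 0L),
           nf - cfg$rise_frames - 1L)
    } else draw_onsets(cfg, minutes, max_events)
    onsets <- sort(unique(onsets))
    amp <- pmax(stats::rnorm(length(onsets), cfg$amp_mean, cfg$amp_sd), 0)
    tr <- numeric(nf)
    for (e in seq_along(onsets))
      tr <- add_kernel(tr, onsets[e], amp[e], cfg$rise_frames,
                       cfg$decay_tau_frames)
    traces[i, ] <- tr
    extent <- pmin(onsets + cfg$rise_frames +
                     ceiling(8 * cfg$decay_tau_frames), nf)
    events[[i]] <- data.frame(onset = onsets,
                              rise_end = onsets + cfg$rise_frames,
                              extent_end = as.integer(extent))
  }
  if (cfg$noise_sd > 0)
    traces <- traces + matrix(stats::rnorm(nu * nf, 0, cfg$noise_sd), nu, nf)
  pos <- neuron_positions(seq_len(nu) - 1L,
                          stats::runif(nu, 0, cfg$arena_size_px),
                          stats::runif(nu, 0, cfg$arena_size_px))
  rec <- recording(trace_matrix(traces, cfg$fps, seq_len(nu) - 1L),
                   positions = pos, name = "synthetic")
  list(recording = rec,
       ground_truth = list(events = events, group = group, positions = pos))
}

draw_onsets <- function(cfg, minutes, max_events) {
  k <- stats::rpois(1L, cfg$event_rate * minutes)
  if (k > max_events) {
    warning(sprintf("event rate too high: thinning %d events to %d",
                    k, max_events), call. = FALSE)
    k <- max_events
  }
  if (k == 0L) return(integer(0))
  latest <- cfg$n_frames - cfg$rise_frames - 1L
  sort(sample.int(latest + 1L, min(k, latest + 1L)) - 1L)
}

#' Tiny hand-checkable fixture recording
#'
#' Deterministic, noiseless 3-unit, 200-frame recording at 20 fps whose
#' default-parameter segmentation is known by construction:
#' \itemize{
#'   \item unit 0: a single calcium transient (onset frame 50, 10-frame
#'     rise, exponential decay) — exactly one detected interval;
#'   \item unit 1: flat baseline — no intervals;
#'   \item unit 2: two transients whose detected rises fall closer than
#'     the default `warm = 15` gap — merged into one interval.
#' }
#'
#' @return List with `recording` and `expected_n_intervals` (`c(1, 0, 1)`).
#' @export
generate_worked_fixture <- function() {
  nf <- 200L
  tr <- matrix(0, 3L, nf)
  # short decays keep the derivative median at 0 (mostly-flat baseline),
  # so the adaptive threshold stays positive on these noiseless traces
  tr[1L, ] <- add_kernel(numeric(nf), 50L, 5, 10L, 8)
  # two transients whose detected rises sit ~13 frames apart (< warm 15)
  tr[3L, ] <- add_kernel(add_kernel(numeric(nf), 60L, 5, 8L, 5),
                         80L, 5, 8L, 5)
  rec <- recording(trace_matrix(tr, fps = 20, unit_ids = 0:2),
                   name = "worked_fixture")
  list(recording = rec, expected_n_intervals = c(1L, 0L, 1L))
}

#' Score detected intervals against planted ground truth
#'
#' Matches detected active intervals to planted event rises. An event
#' counts as recovered (recall) when some detected interval intersects its
#' rise window widened by `slack` frames on both sides; a detected
#' interval counts as a true positive (precision) when it intersects some
#' widened rise window. `slack` absorbs the shift introduced by the
#' smoothing window.
#'
#' @param mask An `activity_mask` from [segment_recording()].
#' @param ground_truth The `ground_truth` element of
#'   [generate_recording()].
#' @param slack Widening of each rise window, frames.
#' @return List with `recall`, `precision`, `n_events`, `n_intervals`.
#' @export
event_recovery <- function(mask, ground_truth, slack = 10L) {
  stopifnot(inherits(mask, "activity_mask"))
  ev_list <- ground_truth$events
  stopifnot(length(ev_list) == n_units(mask))
  tp_ev <- tot_ev <- tp_iv <- tot_iv <- 0L
  for (i in seq_along(ev_list)) {
    iv <- mask$intervals[[i]]; ev <- ev_list[[i]]
    tot_ev <- tot_ev + nrow(ev); tot_iv <- tot_iv + nrow(iv)
    if (nrow(ev) == 0L || nrow(iv) == 0L) next
    lo <- ev$onset - slack; hi <- ev$rise_end + slack
    for (e in seq_len(nrow(ev)))
      if (any(iv$start < hi[e] & iv$end > lo[e])) tp_ev <- tp_ev + 1L
    for (k in seq_len(nrow(iv)))
      if (any(iv$start[k] < hi & iv$end[k] > lo)) tp_iv <- tp_iv + 1L
  }
  list(recall = if (tot_ev > 0L) tp_ev / tot_ev else NA_real_,
       precision = if (tot_iv > 0L) tp_iv / tot_iv else NA_real_,
       n_events = tot_ev, n_intervals = tot_iv)
}
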