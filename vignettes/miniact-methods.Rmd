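---
title: "miniact: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{miniact: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miniact)
```

`miniact` analyzes per-neuron calcium fluorescence traces as produced by
CNMF-style extraction from miniscope video. This vignette is the package's
account of the science inside it: the detection model and its assumptions,
what every tunable parameter does, what the synthetic generator does and
does not emulate, the numerical conventions, and the places where the
design was genuinely open and a choice had to be made.

## Conventions

Frames and unit ids are 0-based, active intervals are half-open
`[start, end)` in frames — the conventions of the Python tooling that
produces the input stores, kept so interval tables can be compared across
toolchains without off-by-one bookkeeping. Every metric quoted in seconds
or minutes converts through the recording's frame rate (`fps`, default 20).

## Active-state detection

A neuron's "active state" is the phase of rapid fluorescence growth that
follows action-potential firing. Detection is per unit:

1. **Smoothing**: centered moving average spanning `floor(wnd_size/2)`
   frames on each side. At the trace edges the window is truncated and
   renormalized by the number of samples actually inside it, so a constant
   trace maps to itself for every window width. `wnd_size = 1` disables
   smoothing.
2. **Differencing**: `x'_t = x_t − x_{t−1}`, with `x'_0 = 0` so the
   derivative stays frame-aligned with the trace.
3. **Adaptive threshold**: `median(x') + mad(x')`, where `mad` is the
   *mean* absolute deviation about the *median* — the median captures the
   unit's baseline drift, the deviation term its typical variability. The
   threshold is computed per unit per recording, never globally, and the
   crossing test is strict (`>`), so a perfectly flat trace produces no
   activity.
4. **Modes**: `spike` keeps exactly the supra-threshold (rising) frames;
   `full` extends each rise forward while the smoothed intensity stays
   above its value at the rise's first frame, capped at the next rise's
   onset. The termination rule for the decay is not uniquely determined by
   the method's description in the field; "return to onset level" was
   chosen because it is parameter-free, guarantees spike ⊆ full, and ends
   decays at a physiologically interpretable point.
5. **Refinement**: passive gaps shorter than `warm` frames are merged
   first, then active intervals shorter than `cold` frames are dropped.
   Merging first lets genuine bursts that were briefly interrupted survive
   a subsequent duration filter.

Parameter defaults (`wnd_size = 10`, `warm = 15`, `cold = 0`, all in
frames at 20 fps) are the values that work well for sparsely active
neurons with a slow indicator such as GCaMP6s; for traces with long
activity plateaus `wnd_size` should drop to 1–5.

### Assumptions, and a limitation worth knowing about

The detector assumes the traces are *denoised* — which CNMF outputs
largely are. The threshold sits `mad(x')` above the median, and for a
Gaussian derivative that is ≈ 0.8 standard deviations: about 21% of
noise-only frames cross a threshold that *scales with the noise itself*.
On traces contaminated with white noise the detector therefore fires
constantly regardless of the signal-to-noise ratio, and the `warm` merge
amplifies the problem by fusing nearby false crossings. The package's
validation reflects this honestly: on noise-free synthetic recordings
detection is exact (recall = precision = 1.0, asserted in the tests); at
SNR 10 white noise, recall stays 1.0 but interval-level precision falls to
≈ 0.16. Users with noisy traces should raise `cold` (drops the short noise
crossings) or pre-denoise; the defaults are tuned for CNMF output, not raw
fluorescence.

## Network metrics

With `A` the set of units and `active(x, i)` the binary mask:

- **burst rate** — per unit, number of distinct active intervals divided
  by the recording length in minutes (activations/min);
- **network spike rate (NSR)** — per window, percent of units active in at
  least one frame of the window (union semantics);
- **network spike peak (NSP)** — per window, the maximal instantaneous
  percent of simultaneously active units; NSR ≥ NSP window-wise because
  every unit counted by the peak is also counted by the union;
- **network spike duration (NSD)** — percent of frames on which the
  simultaneously active fraction strictly exceeds `nsd_threshold`.

Windows are consecutive and non-overlapping, `interval_s` seconds long
(default 3 s, sensible range 1 s – 1 min); a trailing partial window is
kept when it covers at least half a window, dropped otherwise — short
tails would otherwise produce noisy distribution entries. The NSD
threshold default (0.1) is a choice of this package: distributions of
simultaneous activity in sparse cortical/hippocampal recordings rarely
clear 10% by chance, which makes exceedances interpretable.

## Pairwise co-activity

Pearson's coefficient is computed over five input representations: raw
intensity (`signal`), the intensity derivative (`diff`, the most
drift-robust of the continuous modes), binarized activity (`active`,
`full`), and the coactivity ratio `active_acc` = |X∩Y| / (|X| + |Y|) —
time both active over summed individual activity, 0.5 for identical
activity, 0 for disjoint. The denominator is deliberately the *sum*, not
the union: the statistic then penalizes asymmetric activity loads, which
is what makes it the strictest of the five modes. Zero-variance series
(silent units) yield a coefficient of 0 with a warning rather than NA, so
thresholding stays total.

`lag` relaxes simultaneity: the reported coefficient is the maximum plain
Pearson over integer shifts in `[-lag, +lag]` with truncated overlap. The
maximum (rather than a fixed one-sided shift) is direction-agnostic and
reduces exactly to the unlagged coefficient at `lag = 0`.

Derived statistics: the **network degree** curve (percent of pairs with
`r > t` for `t` on the 0–1 grid in 0.05 steps, strictly non-increasing),
per-unit **connectivity** shares (whose mean equals the degree at the same
threshold — each pair enters both normalizations twice), percentile
**clustering** (edges where `r` strictly exceeds the 80th percentile of
off-diagonal values; clusters are connected components; strictness makes
the all-equal matrix produce singletons rather than one giant component),
and **transfer entropy**.

Transfer entropy is estimated with plug-in (maximum-likelihood) histogram
entropies: `TE(X→Y) = H(Y_t | Y_hist) − H(Y_t | Y_hist, X_hist)` with
history length `L` (default 1 frame), continuous inputs discretized into
`n_bins` quantile bins (default 3), binary activity used as-is, and the
estimate clamped at 0 (the plug-in difference can go marginally negative).
No bias correction is applied; at the series lengths the package targets
(≥ 5000 frames) the plug-in bias for the 2×2×2 binary case is far below
0.01 bits, which the tests verify on independent pairs.

## Spatial statistics

Unit positions are intensity-weighted footprint centroids, in pixels;
footprints are discarded after centroid computation since every downstream
quantity is a point statistic. Per recording: the unweighted center of
mass; per unit, `rho` — distance to that center; per pair, the Euclidean
distance and the radial distance `|rho_i − rho_j|` (≤ Euclidean, by the
reverse triangle inequality). The distance factor `k = d / (d + d0)` maps
distances into `[0, 1)`; `d0` defaults to the 25th percentile of the
recording's own Euclidean pair distances, making `k` adaptive to the field
of view (a fixed `d0 = 100` px can be passed to reproduce analyses that
used a hardware-specific constant). The "distance-weighted correlation"
exposed in the pair table is `r × k` — an optional extra column, never a
replacement for the raw coefficient, because no standard definition exists
for how the factor should enter.

## The shuffling null model

Surrogates conserve each unit's activation *count* exactly — the defining
constraint of the null — while randomizing everything else: each
interval's new duration is drawn uniformly from `{1, …, 2d − 1}` (mean
`d`, the original duration, so total active time is conserved in
expectation though not exactly), and the intervals are re-placed uniformly
at random with at least one passive frame between them (gap-sampling over
integer compositions). `ratio` selects the fraction of units shuffled
(drawn afresh each iteration); `ratio = 0` is the identity, and the whole
procedure is reproducible from the seed. Comparisons report mean ± SEM of
mean correlation, correlation range, mean NSR and mean NSP across
`num_of_shuffles` iterations; hypothesis testing is left to the user's
statistics software. Only mask-based correlation modes are allowed in the
comparison: the surrogates do not alter traces, so `signal`/`diff`
correlations would be unchanged by construction and reporting them would
be misleading.

## PCA state embedding

Per-recording metric profiles (burst-rate mean/median, mean NSR, mean NSP,
NSD, per-mode correlation means and ranges, degree at fixed thresholds,
median distances, optionally mean TE) are assembled into a
recording × metric matrix, z-scored per column (the metrics mix percent,
pixels, bits and per-minute rates; unscaled PCA would be dominated by the
pixel-valued columns — standardization can be disabled where raw loadings
are wanted), and decomposed by SVD. Coordinates are the projections on the
top-two right singular directions; explained-variance fractions are
`d_k² / Σ d²`. Each component's sign is fixed so its largest-magnitude
loading is positive — SVD signs are otherwise arbitrary and would make
exports irreproducible across BLAS implementations. Constant columns are
dropped with a warning; identical recordings (zero total variance) are an
error rather than a degenerate embedding. Feature ranking orders loadings
by magnitude along a chosen direction — a component axis or, when group
labels are supplied, the difference of group centroids in the embedding
plane — and reports each feature's cosine similarity to that direction.

## The synthetic generator

`generate_recording()` emulates the *output* of CNMF extraction, not raw
video: per unit, homogeneous-Poisson event onsets (`event_rate`/min);
per event, a linear rise over `rise_frames` to a Normal-truncated
amplitude followed by exponential decay with time constant
`decay_tau_frames`; white Gaussian noise of `noise_sd` on top; optional
co-active groups sharing onsets up to ±`jitter_frames`; centroids uniform
in a square arena. Defaults (20 fps, 5-frame rise, 40-frame decay,
amplitude 1 ± 0.2, noise 0.1, 300 px arena) describe a typical slow
indicator recording; they are fixture conventions, not measurements. What
the generator does *not* emulate: bleaching and slow drift, movement
artifacts, correlated (pink) noise, amplitude adaptation within bursts,
and spatial footprint overlap. Tests passing on this generator therefore
validate the *arithmetic* of the pipeline and its behavior under the
stated noise model — they do not certify detection performance on raw,
un-denoised fluorescence.

Validation problem sizes, chosen to keep the full suite fast while leaving
no estimator undersampled: segmentation oracle equivalence on 100 random
traces up to 500 frames; event recovery on 100 units × 5 min; transfer
entropy at 5000 samples × 20 replicates; shuffle-count conservation over
1000 draws; geometry properties over 1000 random layouts.

## Input/output

The store reader accepts zarr-v2 directory stores in the conventional
CNMF layout (`C` traces, optional `A` footprints, optional `unit_id`,
`position`), with raw or zlib-compressed chunks in C or Fortran order;
CSV tables are the dependency-free alternative. NaN frames are rejected by
default, naming the offending units; linear interpolation is available for
isolated interior gaps of at most 5 frames. Reports are written as one
workbook with one sheet per table plus byte-stable CSV mirrors; trace CSVs
are written with 17 significant digits so round trips are bit-exact.
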