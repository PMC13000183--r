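---
title: "Decoding topological transitions of tracked object configurations from ongoing EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding topological transitions of tracked object configurations from ongoing EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topotrack)
```

## The problem

In a multiple-object tracking (MOT) task, observers covertly track four
target items among eight identical moving items. One account of how
this is possible holds that the visual system maintains the targets not
as four independent locations but as a single object: the illusory
polygon formed by the shortest closed path through all four targets.
If that is so, qualitative changes of this polygon — changes that are
discrete even though the underlying motion is smooth — should have
measurable electrophysiological correlates. Three such *topological
transitions* exist for four points:

* **flip** — the cyclic order in which the shortest path visits the
  items changes (possible only while the configuration is concave);
* **concave** — the convex hull loses a corner (4 → 3): a previously
  convex polygon acquires a dent;
* **convex** — the hull regains its fourth corner (3 → 4).

`topotrack` implements the full analysis chain for testing whether
these transitions can be decoded from the ongoing EEG: trajectory
simulation, per-frame polygon topology and event detection, synthetic
multichannel EEG with event-locked responses as ground truth, ERP and
PCA spatial-filter machinery, a sliding normalized cross-correlation
decoder with a label-permutation baseline, time-lag maps, and
group-level permutation statistics.

## Trajectory simulation

`motion_config()` encodes the display constraints: a 14.4° × 14.4°
field, 8 items moving at a constant 4.1°/s for 4 s per trial, with no
two items ever closer than 0.8°, and 300 trials per session carrying
balanced probe-match labels (M0–M4, 60 each) that later serve as
cross-validation folds.

The motion law is a bounded random drift. Each item's heading moves
toward a target heading at up to `turn_rate_limit` (270°/s); new
target headings are drawn at Poisson instants (`turn_event_rate`,
1 Hz). This yields curved, continuous paths whose direction changes at
unpredictable times. Two details required care:

* **Boundary handling.** A look-ahead point is projected 1.5× the
  quarter-turn distance (≈2 °) ahead of the item. When it would leave
  the field, the item turns at full rate, committing to the rotation
  direction that keeps the simulated turning arc furthest inside the
  field (ties break toward the field centre). Committing to one
  direction matters: re-deciding every frame oscillates in corners,
  and turning by the shortest angle toward the centre can rotate
  *through* the wall-facing heading. Residual boundary grazes are rare
  (≈0.3 % of paths) and handled by redrawing the path — containment is
  enforced by rejection, never by clipping, which would break the
  constant-speed invariant.
* **Combination.** Items are simulated independently, so a pool of
  `pool_factor × n_items` candidate paths is generated per trial, the
  pool's pairwise minimum distances are computed once, and a
  combination of 8 mutually compatible paths is sought by randomized
  greedy selection within a 10,000-attempt budget. A fresh pool per
  trial guarantees that no trajectory occurs twice in a session.

At these defaults a 300-trial session produces on the order of 370–400
filtered target-set events of each type, comparable to the event rates
the task geometry implies (the hull of four points moving at 4.1°/s in
a ~14° field changes topology every few seconds, and the 500 ms repeat
filter caps the rate).

## Topology and event detection

For four points, only three distinct cyclic tours exist;
`shortest_path_polygon()` evaluates all three perimeters and returns
the minimizer, reduced to a canonical form (lexicographically minimal
rotation, reversal-invariant) by `canonical_cycle()`. The hull corner
count is 4 exactly when no point lies inside (or on an edge of) the
triangle of the other three. Frames where all four points are
collinear or coincide are degenerate: the last valid state is carried
forward and no event may be emitted into or out of such a frame.

`detect_transitions()` emits raw events at the later frame of each
qualifying frame pair, then applies two filters in order:

1. **Repeat filter (debounce).** An event is dropped when a kept event
   of the same type occurred less than 500 ms earlier. The repeat rule
   could equally be read as spanning all types; per-type is the
   default because it is the weaker, information-preserving reading,
   and `debounce_mode = "global"` provides the strict variant.
2. **Boundary exclusion.** Events within 500 ms of motion onset or
   offset are removed, so every retained event has a full ±500 ms of
   within-trial signal around it.

A flip is a change of the canonical cycle between consecutive valid
frames. When a flip and a hull-count change fall on the same frame
pair, both events are recorded — the definitions are independent.
Unfiltered concave/convex events alternate strictly (the hull count is
a two-state process), and flips occur only while the configuration is
concave; both properties are exercised in the test suite.

## Synthetic EEG

`simulate_dataset()` generates, for each subject, continuous
32-channel EEG (standard 10-20 labels, including O9/O1/Oz/O2/O10 and
the mastoid surrogates TP9/TP10) in which every *target-set* event
adds a spatially mixed, event-locked waveform; distractor-set events
add nothing and are therefore a built-in attention-specific null.
Every subject sees the same trial set — as in a study with
precomputed trajectories — with independent noise.

* **Noise.** Gaussian 1/f^α noise (α = 1 by default), synthesized in
  the frequency domain (the real part of a circularly symmetric
  complex Gaussian spectrum), unit variance per channel, with a
  uniform pairwise channel correlation (0.2) from a shared component.
* **Topography.** A single unit-norm bilateral ventral-occipital
  pattern (strongest at O9/O10, O1/O2) mixes all three kernels — the
  decoder must separate the types by waveform, not by scalp pattern.
* **Kernels.** The three waveforms must be mutually discriminable
  *and* recoverable by the windowed-correlation analysis. Waveform
  families were chosen under three explicit identifiability
  constraints: pairwise correlation below 0.5; a positive mean of the
  autocorrelation over ±50 ms, so that performance assessed at event
  occurrence does not self-cancel (a high-frequency carrier fails
  this: its locked correlation oscillates and integrates to zero);
  and compact support, so a 400 ms template window centred off the
  response captures distinctly less of its energy (a broad monophasic
  Gaussian fails this: after normalization, a half-captured and a
  fully-captured Gaussian correlate almost equally, flattening the
  lag profile). The defaults — a Gaussian-derivative for flips, a
  4.5 Hz cosine Gabor for concave, an 8 Hz sine Gabor for convex
  (pairwise |r| ≤ 0.31) — satisfy all three.
* **Latency shifts.** The flip kernel is centred 150 ms *before* its
  event, the concave kernel 150 ms *after*, the convex kernel at 0.
  These shifts are the recoverable ground truth for the time-lag
  analysis.
* **Amplitude.** `snr` is the kernel peak in units of noise SD
  (default 1). Trials are separated by 1 s of pure noise so that
  epoching and trace-edge handling are exercised.

## ERP core

Preprocessing applies a zero-phase order-2 Butterworth high-pass at
0.5 Hz and re-references to the mastoid mean. Epochs are cut at
±400 ms around each event (times snapped to the nearest sample; the
grid is 2 ms at 500 Hz). Grand averages pool over *all* events of a
type — every event counts once regardless of its subject or trial, so
unbalanced event counts are weighted as they occur, not equalized.

The spatial filter is a PCA of the grand-average ERP with the three
types' time courses concatenated as observations (3 × 401 rows) and
channels as variables: covariance PCA with channel-wise centering and
no rescaling, because the resulting weights are applied directly to
µV signals. Eigenvector sign is fixed by making each component's
largest-magnitude loading positive, so the decomposition is
deterministic across runs. Because re-referenced data always lie in a
31-dimensional subspace, one null component is expected and not
warned about. Component choice is exposed (`component = n`) along
with an automatic mode that scores candidates by training-set
self-similarity at events; in the synthetic data the embedded
topography dominates the evoked covariance, so the informative
component is C1 by construction.

## The event-similarity decoder

For subject *s*, split *m*, and training type *e*, the *signature* is
the pooled mean of the component-projected epochs of all training
events of type *e*. The event-similarity measure (ESM) at trial time
*t* is the Pearson-type correlation between the signature and the
signal slice `p(t + τ)`, both demeaned over the window
`[t + τ_min, t + τ_max]` and normalized by their windowed SDs — a
value in [−1, 1] per time point. Numerically the sliding dot products
are computed by FFT cross-correlation with per-trial contexts (signal
FFT and cumulative sums) cached and reused across signatures,
permutations and lag windows; the implementation is held to a naive
per-`t` Pearson oracle at 1e−10.

Policies for ill-defined points: windows that would leave the trial
are *missing* (event-locked averages then pool over defined samples
only, with effective counts logged); windows with zero variance yield
0 and are counted in a flag rather than propagating NaN.

The five training/test splits reuse the probe-match labels: condition
*m* trials are the test set, the rest train. Locked ESM curves are
pooled over test events. The *permutation baseline* shuffles the
three type labels among the training events (a permutation, so
per-type counts are preserved), recomputes signatures and locked
curves, and averages 50 such shuffles; event times and PCA weights
are never touched. The corrected ESM subtracts this baseline, then
averages over the five splits and then over subjects with unweighted
means; per-subject curves are kept for inference. Cells with no test
events are dropped from the means and logged via the count arrays.

The time-lag map repeats the whole computation with the signature
cropped to a 400 ms window whose centre (the *lag*) moves between
−300 and +300 ms: negative lags decode from signal preceding the
event. Each lag gets its own permutation baseline, with the random
streams restarted from the same seed at every lag so baseline noise is
coupled across columns. The lag-0 column reproduces the standard
analysis restricted to ±200 ms exactly, which the tests assert.

## Group statistics

* `cluster_permutation_t()` — pointwise one-sample *t* against zero,
  one-sided; contiguous supra-threshold points (runs in 1-D,
  4-connected components in 2-D) form clusters scored by mass (sum of
  *t*). The null is random whole-subject sign flips; `exact = TRUE`
  enumerates all 2^n flips and the Monte Carlo p uses the standard
  (1 + k)/(B + 1) correction. Mass is used because it is the common
  default where the method itself does not fix the statistic.
* `pointwise_repeated_F()` — one-factor repeated-measures F per grid
  point, from sums of squares, reported uncorrected (no sphericity
  correction); this is the time-pointwise reading of a "tANOVA",
  which is the reading implemented and labelled here.
* `event_histogram()` / `esm_histogram_correlation()` — the
  distribution of events of one type around events of another, binned
  at 20 ms, linearly interpolated onto the ESM grid, and Pearson-
  correlated with the locked ESM curve. In this simulation these
  correlations are driven by real co-occurrence structure: flips
  happen only between a concave and the following convex transition,
  so the types cluster in time and each type's kernels contaminate
  the others' surroundings.
* `performance_split()` — median split by error rate; ties go by
  subject-id parity, making the split deterministic.

## Problem sizes used by the tests

The packaged test-suite runs the full pipeline at desk scale, chosen
so the complete suite runs in well under half an hour on one core:
parameter-recovery replicates use 6 subjects × 60 trials at 200 Hz
with 20 baseline permutations (5 per lag column, lag grid ±{50, 150,
250} ms); false-positive calibration uses 200 replicates of 5
subjects × 10 trials at 100 Hz; the event-count check uses one full
300-trial session at the complete display parameters. Analysis
parameters are expressed in seconds throughout, so reduced sampling
rates change resolution, not definitions. The study-scale defaults
(500 Hz, 38 subjects, 300 trials, 50 permutations, 31 lag columns)
remain the package defaults.

## What the synthetic data do and do not show

The generator emulates the *structure* of the recordings — trial
layout, 1/f spatially correlated noise, a fixed evoked topography,
event-locked responses with type-specific waveforms and latencies,
and the attention contrast (target events drive responses, distractor
events do not). Passing tests therefore show that the pipeline
recovers planted effects of the stated size and rejects absent ones
at the stated rates. They do not show that real EEG contains such
responses: real data add non-stationary artifacts (ocular, muscular —
ICA cleaning is out of scope here), inter-subject topography
variability (the synthetic topography is shared, which is why C1
rather than a later component carries the signal), overlapping
cognitive processes, and unknown true latencies. Conclusions about
real recordings require the real-data path: `preprocess()`,
`epoch_recording()` and everything downstream operate on any
`eeg_recording` built from imported data.

## Known limitations

* Polygons are defined for exactly four tracked items; other set
  sizes are out of scope.
* The behavioral arm of the task (reaction times, error rates per
  match condition) is not modelled; `performance_split()` exists for
  real behavioral data.
* `run_pipeline()` regenerates recordings from their stage seeds
  instead of caching them, trading CPU for memory; at the full
  38-subject scale a run is correspondingly slow.
* The trajectory generator's motion law is a specific, documented
  choice (bounded random heading drift); event *rates* depend on it,
  so absolute counts are comparable only under this law, though their
  order of magnitude is set by the display geometry.
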