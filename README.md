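# topotrack

Decoding topological transitions of tracked object configurations from
ongoing EEG.

## What this package is for

In multiple-object tracking (MOT), observers track four target items
among eight identical moving items. Under an object-based account of
tracking, the four targets are maintained as one illusory polygon — the
shortest closed path through all four items. As the items move, this
polygon undergoes discrete **topological transitions**:

* **flip** — the cyclic item order of the shortest path changes
  (possible only in concave configurations);
* **concave** — the convex hull drops from 4 to 3 corners;
* **convex** — the hull regains its 4th corner.

`topotrack` is a simulation and decoding pipeline for testing whether
such transitions can be read out from the ongoing EEG. It provides:

1. a constrained MOT **trajectory generator** (constant 4.1°/s speed,
   14.4° × 14.4° field, 0.8° minimum inter-item distance, curved
   unpredictable motion);
2. per-frame **shortest-path polygon** computation and **transition
   detection** with a 500 ms repeat filter and 500 ms boundary
   exclusions;
3. a **synthetic 32-channel EEG generator** embedding event-locked
   waveforms (with known latency shifts: flip −150 ms, concave
   +150 ms, convex 0) on spatially correlated 1/f noise — the ground
   truth for validating every downstream stage;
4. **ERP machinery**: zero-phase high-pass, mastoid re-referencing,
   ±400 ms epoching, pooled grand averages, and a covariance **PCA
   spatial filter** `w` applied as `p_c(t) = Σ_n w_cn p_n(t)`;
5. the **event-similarity measure (ESM)**: a sliding, windowed,
   demeaned, SD-normalized cross-correlation between an event
   signature (the mean training-set ERP of one event type in component
   space) and the ongoing projected signal — a Pearson-type value in
   [−1, 1] at every time point — evaluated with five probe-condition
   cross-validation splits, corrected by a 50-shuffle label-permutation
   baseline, and extended to **time-lag maps** (400 ms signature crops
   sliding from −300 to +300 ms);
6. **group statistics**: one-sided cluster-based permutation *t* tests
   (sign-flip null, mass statistic, exact enumeration available),
   pointwise repeated-measures F across the three ESM traces,
   ESM-versus-event-histogram correlations, and a median performance
   split.

## Worked example

```r
library(topotrack)

# 2 subjects, 20 trials, 250 Hz, kernels at 1.5x noise SD
ds <- simulate_dataset(motion_config(),
                       synth_config(n_subjects = 2, sampling_rate = 250,
                                    snr = 1.5),
                       n_trials = 20, seed = 5)
table(ds$events_target$event_type)
#>    flip concave  convex
#>      27      29      25

recs <- lapply(ds$recordings, preprocess)
eps  <- combine_epochs(lapply(recs, epoch_recording,
                              events = ds$events_target))
w <- pca_weights(grand_average(eps))
w
#> <pca_weights> 32 components x 32 channels; variance explained: 46.7%, 16.6%, 3.9%, 2.5%...

res <- esm_analysis(recs, ds$events_target, session_trial_info(ds$session),
                    w, component = 1, n_perm = 20, seed = 9)
mid <- which.min(abs(res$tau))
m <- res$corrected[, , mid]
dimnames(m) <- list(train = event_types(), test = event_types())
round(m, 3)
#>          test
#> train       flip concave convex
#>   flip     0.089  -0.042 -0.059
#>   concave -0.068   0.077 -0.078
#>   convex  -0.089  -0.073  0.106
```

The matrix shows the baseline-corrected event similarity at the moment
of event occurrence: rows are the event type whose signature was used
for decoding (training), columns the type of the test event the trace
was locked on. The positive diagonal — each type's signature is most
similar to the ongoing EEG at its own events — is the decoding effect;
at this desk scale it is visible directly, and `cluster_permutation_t()`
on `res$corrected_subject[, e, f, ]` provides the group-level test.
With one embedded scalp pattern the first principal component carries
the signal; on real data the informative component must be found (the
`component` argument, or `select_component()`).

`lag_esm_map()` repeats the analysis with cropped, time-shifted
signatures and recovers *when* the informative signal occurs: with the
synthetic ground truth, the flip map peaks at negative lags
(anticipatory) and the concave map at positive lags.

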