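---
title: "Breath segmentation and waveform clustering: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breath segmentation and waveform clustering: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plethyclust)
```

This vignette explains what each stage of the pipeline computes, why the
defaults are what they are, which choices were genuinely open and how we
resolved them, and what the synthetic tests do and do not establish about
real recordings.

## Signal model and preprocessing

The input is a single-channel airflow-like trace from a whole body
plethysmograph: flow in ml/s, inspiration positive, sampled uniformly
(typically 500 samples/s). The pipeline assumes the chamber signal has
already been converted to flow and calibrated; temperature/humidity
corrections of derived volumes are out of scope, so reported V_T is the
integral of the recorded flow, in the units of that recording.

Preprocessing is a 2nd-order Butterworth lowpass at 15 Hz followed by
resampling to 90 samples/s. Respiratory content in rodents lives well
below 15 Hz even during sniffing (~6-10 Hz cycle rates), so the filter
removes sensor noise without touching breath morphology, and 90 samples/s
keeps ~45 Hz of bandwidth — ample for the filtered signal — while making
the waveform matrices an order of magnitude smaller.

Two choices here were open:

* **Causal vs zero-phase filtering.** The default is single-pass causal
  filtering, so the magnitude response at the cutoff is the textbook
  -3 dB point and the (small, ~15 ms at low frequency) group delay is
  shared by every breath; onset *intervals*, which drive all downstream
  duration logic, are unaffected. `run_config(zero_phase = TRUE)`
  switches to forward-backward filtering when absolute onset latency
  against an external event matters more than the documented prototype
  response.
* **Resampling algorithm.** 500 → 90 is a non-integer ratio, so naive
  decimation is not available and aliasing of content between 45 Hz and
  the original Nyquist must be prevented explicitly. `resample_trace()`
  applies a zero-phase 8th-order anti-alias Butterworth at 45% of the
  target rate and then evaluates the band-limited signal on the new grid
  by cubic spline. On a band-limited probe this is accurate to ~1e-8
  RMS, comfortably inside the 1% contract the tests enforce. Traces are
  reflect-padded before every filter so the first and last breaths of a
  record are usable.

## Breath detection and segmentation

Breaths are found by upward crossings of a 0.3 ml/s threshold; each
crossing is moved back to the preceding zero-crossing (the last sample
≤ 0) to mark the true start of inspiration. The threshold exists solely
to ignore noise excursions around zero, and is configurable
(`detect_threshold_mls`); crossings that are not separated by a return
to ≤ 0 collapse into one onset, so flutter around the threshold cannot
double-count. If no non-positive sample precedes the first crossing the
onset clips to the trace start.

A breath spans onset-to-onset; T_TOT is the raw onset interval, and the
final onset of a record (no successor) yields no breath, as does the
partial activity before the first onset. The analysis window of each
breath is additionally shifted back by `min(0.2 * T_TOT, 100 ms)` so that
pre-inspiratory negative deflections — a real feature of some breath
types — are inside the window; the shift is capped so slow breaths do not
swallow their predecessor's expiration.

T_E is not uniquely defined for arbitrary waveforms; the package uses an
operational rule: inspiration ends at the last positive-flow sample
before the first sustained (≥ 50 ms) run of non-positive flow, and
T_E = T_TOT minus that inspiratory time. V_T is the maximum of the
running trapezoidal integral of flow over the window — the inspired
volume before net expiration dominates — and is therefore non-negative
by construction.

Duration domains are half-open, lower-closed bins over
`c(0, 0.2, 0.5, 1.2, 4)` s. Half-open was chosen because the sniffing
domain is defined by cycles *below* 0.2 s, which forces that bin's upper
edge to be exclusive; the convention is applied uniformly. Breaths of
≥ 4 s are flagged out-of-range rather than merged or dropped: they stay
in every count and prevalence table (reserved `unassigned` column) but
are not clustered, since a single domain spanning them would be
shape-heterogeneous by construction.

## Clustering

Within each domain, waveforms are zero-padded to the longest member (the
padding is exactly zero, so un-padding is lossless whenever the last true
sample is nonzero) and reduced by PCA. Centering is by column means with
no scaling: all columns are flow samples in the same units, and scaling
would inflate the padded tail columns whose variance is mostly
bookkeeping. Components are retained in order until the cumulative
explained variance strictly exceeds `variance_target` (default 0.90),
with `n_retained` minimal; eigenvector signs are fixed by making each
vector's largest-magnitude loading positive, so centroids are
reproducible across platforms. A degenerate domain of identical rows is
defined to have one component explaining all (trivial) variance.

The Ward tree is built on the retained PC scores, not on the raw padded
samples — the scores are where each waveform has coordinates, and the
retained subspace already carries > 90% of the shape variance at ~10x
fewer dimensions. Merge heights are the standard `sqrt(2 ΔESS)` Ward
distances; the test suite verifies the tree merge-for-merge against an
O(n³) re-computation of Ward's criterion.

**Choosing k.** The merge-height curve d(k) (height of the merge that
produces k clusters) is large while genuinely distinct groups are being
joined and collapses to noise level once k reaches the true group count.
We operationalize the "elbow" as the k with maximal vertical deviation
*below* the chord joining (1, d(1)) and (k_max, d(k_max)), scanning
k_max = 30; ties resolve to the smaller k, and a numerically degenerate
tree (all heights at rounding scale, ≤ 1e-8) returns k = 1. On labeled
benchmarks with between-class separation ≥ 5 within-class SDs this
recovers the true count in ≥ 95% of runs with adjusted Rand index 1.
Its known failure mode is *unstructured* data: a single Gaussian cloud
still produces a bowed merge-height curve, and the rule will report some
small k > 1 rather than 1. The elbow certifies where structure stops
explaining distance, not whether structure exists; users should treat
k on visually structureless domains with suspicion (or override it via
`k_override`).

Global cluster numbers concatenate domains in duration order (domain 1
starts at 1), so a cluster id is meaningful across the whole model.
Centroids are per-sample means in the padded space; the display length
reported for plotting is mean + 1 sample SD (n − 1 denominator,
singletons report SD 0) of the members' true lengths.

Amplitude is deliberately part of the representation: two shapes that
differ only by scale can land in different clusters. Within one
calibrated dataset that is informative (depressed breathing *is* smaller
breathing); across datasets it requires consistent chamber calibration,
or classification of new data against a saved model
(`classify_new()`: pad/truncate to the model's row length, project onto
its eigenvectors, nearest centroid in PC space).

Domains with fewer than two breaths cannot be fitted and are skipped;
their breaths remain unassigned. Above `linkage_cap` (default 200,000)
waveforms per domain, the tree is fitted on a seeded uniform subsample
and the remainder assigned by nearest centroid — exact linkage is
quadratic in memory and this keeps desk-scale machines viable.

## Annotation and ventilation metrics

Windows are breath-indexed: 20 consecutive breaths, non-overlapping, the
trailing partial window left unannotated. A window takes a category
label only when that category's clusters hold *strictly more* than 51%
of its breaths (≥ 11 of 20 at the defaults); mixed windows stay
unannotated, which is itself informative — baseline breathing hops
between behaviors, depressed breathing does not. Category sets must be
disjoint; a strict majority is then automatically unique.

"Common" tidal clusters are recomputed per dataset: among
baseline-period breaths in the tidal clusters, a cluster is common when
its prevalence strictly exceeds the mean prevalence (equivalently
1/n over the tidal set). Strict inequality means a perfectly uniform
profile has no common clusters — the boundary case is reported honestly
rather than split arbitrarily.

RR is counted over the final `metric_window_s` (default 300 s) of each
period divided by the window in minutes; V_T is the mean integrated
volume of those breaths; V_E = RR × V_T identically (this is an
invariant, not an approximation). Periods shorter than the window are
used whole, with a message. An empty window reports RR = 0 and missing
V_T/V_E.

## The synthetic generator

`generate_trace()` emulates the *statistical* structure the pipeline
must resolve, not chamber physics. Each breath is a template
realization: half-sine inspiration (two stacked half-sines for the
augmented-breath class), exponential-decay expiratory flow, optional
zero-flow apnea tail; durations and tidal volumes are truncated
normals per class, clamped inside each class's nominal duration domain.
Defaults are rat-plausible: tidal V_T 1.6-2.2 ml, sniff cycles
0.11-0.19 s, sighs ~4.5 ml with post-sigh apnea, additive Gaussian
sensor noise of 0.05 ml/s. Amplitudes follow from volumes
(a = V_T·π/2T_i), so every ground-truth V_T is analytic.

State schedules apply two multipliers. The *rate* multiplier stretches
the expiratory/apneic portion of each cycle, leaving inspiratory timing
untouched; the *amplitude* multiplier scales flow. Consequently RR
tracks the rate multiplier and V_T the amplitude multiplier exactly in
expectation — which is what makes the end-to-end 50%-depression test a
sharp test of the *pipeline* rather than of the generator. The two-state
demo schedule uses the same tidal mixture in both states, with a 1%
sigh weight at baseline (about one sigh per minute, physiologically
reasonable) and none when depressed; periods are 600 s each so sampling
noise in the RR ratio is ~1%. These values were fixed as generator
design, before any measurement against them.

What the generator does **not** emulate: chamber pressure physics
(thermal/humidity components), temperature drift, movement artifacts,
postural effects, state-dependent autocorrelation of breath types
(classes are drawn i.i.d. within a state, whereas real sniffing comes in
bouts). Passing the synthetic suite therefore shows the algorithmic
contracts hold — detection equals its specification, clusters separate
what is separable, metrics conserve what they must — not that any
particular biological recording will yield this many clusters or this
clean a depression signature.

`generate_cluster_benchmark()` controls clustering difficulty directly:
class means displaced along a smooth base shape, within-class
variability Gaussian along a few smooth modes (waveform variability is
smooth, not white), with `separation` defined as adjacent-mean distance
in units of total within-class SD. Separation 0 collapses all classes
onto one distribution — which, per the elbow limitation above, the
cluster-count rule will *not* report as k = 1.

## Numerical conventions, in one place

* Bins half-open `[lo, hi)`; out-of-range ≥ last edge flagged, kept in
  counts.
* Majority rule strictly greater than `majority_pct`/100; common-tidal
  rule strictly greater than the mean prevalence.
* Elbow ties toward smaller k; flat/degenerate curve (d(1) ≤ 1e-8)
  gives k = 1.
* PCA sign: largest-|loading| positive; SDs use n − 1 (singletons 0).
* Model JSON round-trips numerics at ≤ 1e-12 error (full-precision
  serialization).
* Zero-crossing search walks back to the last sample ≤ 0, clipping at
  the trace start; detection threshold fires at ≥ threshold.
* Generators save and restore the caller's RNG state; identical seeds
  give bit-identical output.

## Problem sizes in the shipped tests

The test and acceptance runs use sizes chosen to exercise every code
path while completing in seconds on one core: 1000 random traces of
200-500 samples for the detector-oracle comparison, 100 instances of
n ≤ 10 for the Ward oracle, 100 benchmarks of 2-6 classes × 30
waveforms for recovery, and 2 × 600 s simulated records (~1500 breaths)
for the end-to-end depression study. The method itself has been designed
for full-study scale (hundreds of thousands of breaths across dozens of
animals); `linkage_cap` is the only concession required there.

## Known limitations

* The elbow rule reports spurious structure on structureless domains
  (see above).
* Amplitude sensitivity ties cross-dataset comparability to chamber
  calibration.
* T_E relies on an operational inspiratory-end rule; waveforms with
  fragmented inspiration will bias it long.
* No artifact rejection: movement artifacts that cross threshold become
  breaths, and typically surface as their own (short, odd-shaped)
  clusters — the cluster structure makes them visible but the package
  does not label them automatically.
* Volumes are uncorrected integrals of recorded flow; body-temperature
  corrections are the user's responsibility upstream.
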