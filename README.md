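# plethyclust

Breath detection and waveform cluster analysis for whole body
plethysmography (WBP).

## The problem

WBP records an airflow-like signal from an unrestrained animal, and awake
animals do not breathe metronomically: a single recording mixes quiet
tidal breathing, sniffing bursts, augmented breaths (sighs) and apneas.
Conventional analysis reduces all of this to respiratory rate and tidal
volume over hand-picked "stable" segments, discarding most of the record
and all of the waveform-shape information. `plethyclust` instead analyses
the *entire* record breath by breath: it segments every breath, clusters
the waveform shapes, and uses cluster membership to annotate behavior and
track how breathing patterns change across experimental periods (e.g.
baseline → respiratory depressant → rescue drug). It is aimed at
respiratory physiologists running preclinical WBP studies.

## The method

1. **Preprocess** — 2nd-order Butterworth 15 Hz lowpass, then resample to
   90 samples/s.
2. **Detect breaths** — upward crossings of a 0.3 ml/s flow threshold
   (above the noise floor around zero), each moved back to the preceding
   zero-crossing to mark the true start of inspiration. Breaths run
   onset-to-onset (duration T_TOT); each analysis window is additionally
   shifted back by 20% of T_TOT (max 100 ms) so the whole inspiratory
   effort, including any pre-inspiratory negative deflection, is captured.
3. **Duration domains** — breaths are binned by T_TOT into
   [0, 0.2) s (sniffing), [0.2, 0.5) s (short tidal), [0.5, 1.2) s (long
   tidal) and [1.2, 4) s (very long: sighs, post-sigh and spontaneous
   apneas); ≥ 4 s is flagged out-of-range.
4. **Cluster shapes** — per domain, waveforms are zero-padded to equal
   length, reduced by PCA (components retained until > 90% of variance is
   explained), and clustered by Ward agglomerative linkage (inner squared
   Euclidean distance) on the retained PC scores. The cluster count k is
   the elbow of the merge-height curve d(k): the k with maximal vertical
   deviation below the chord joining (1, d(1)) and (k_max, d(k_max)),
   k_max = 30. Cluster numbers are global and consecutive across domains.
5. **Annotate and quantify** — 20-breath windows are labeled with the
   behavior (sniffing / common tidal / uncommon tidal / augmented) whose
   clusters hold a strict > 51% majority; "common" tidal clusters are
   those whose baseline prevalence exceeds the across-cluster mean.
   Per-period outputs: cluster-prevalence tables (rows sum to 1),
   peri-event rasters, and the classical metrics RR (breaths/min over the
   final 5 min of each period), V_T (ml, mean integrated inspiratory
   flow) and minute ventilation V_E = RR × V_T.
6. **Reuse** — a fitted model (eigenvectors + centroids) can be saved and
   new recordings classified against the established clusters by nearest
   centroid in PC space.

A seeded synthetic generator (`generate_trace()`,
`generate_cluster_benchmark()`) produces WBP-like traces and labeled
waveform sets with ground truth, so the whole pipeline is testable
without recorded data.

## Worked example

Simulate ten minutes of breathing — five baseline, five with rate and
amplitude depressed to 50% (an opioid-like pattern) — then run the full
pipeline:

```r
library(plethyclust)

sim     <- generate_trace(two_state_schedule(300, 300), seed = 42)
cfg     <- run_config()
pre     <- preprocess_trace(sim$trace, cfg)
breaths <- segment_breaths(pre, detect_onsets(pre, cfg$detect_threshold_mls), cfg)
model   <- fit_waveform_clusters(breaths, cfg)
breaths$cluster_id <- model$assignments
model
#> cluster_model: 3 fitted domain(s), analysis rate 90 S/s
#>   domain 2: n = 276, 3 PCs (>90% var), k = 9, clusters 1-9
#>   domain 3: n = 372, 1 PCs (>90% var), k = 3, clusters 10-12
#>   domain 4: n = 131, 1 PCs (>90% var), k = 3, clusters 13-15

ventilation_summary(breaths, pre$periods, metric_window_s = 300,
                    normalize_to = "baseline")
#>   period_label n_breaths rr_bpm v_t_ml v_e_ml_min rr_pct v_t_pct v_e_pct
#> 1     baseline       525  105.0 1.7774     186.63 100.00  100.00  100.00
#> 2    depressed       254   50.8 0.9268      47.08  48.38   52.15   25.23
```

Reading: 525 breaths fell in the final 5 min of baseline (105/min, mean
V_T 1.78 ml); in the depressed period the rate fell to 48% and V_T to 52%
of baseline, so minute ventilation dropped to 25% — the pipeline recovers
the simulated 50%/50% depression. The prevalence table shows the same
shift as a redistribution of cluster mass: baseline breaths spread over
many tidal clusters, while depressed-period breaths concentrate in the
few slow, low-amplitude clusters (12 and 15 here, 49% and 51%).

A thin command-line wrapper is installed with the package
(`system.file("cli", "plethyclust.R", package = "plethyclust")`) with
`simulate`, `detect` and `run` subcommands over the same functions, e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","plethyclust.R",package="plethyclust"))')" \
    run --config config.json --out runs/exp1 --seed 1
```

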