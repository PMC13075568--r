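# capnet

Transient co-activation patterns (CAPs) and time-averaged resting-state
networks (RSNs) from band-limited EEG source envelopes, with a fully seeded
synthetic-cohort generator so every stage is testable without access to raw
recordings.

**Who it is for.** Researchers studying fast (<100 ms) brain-wide dynamics
in resting EEG/MEG who want a reproducible, scriptable version of the
frame-clustering CAP analysis and its comparison against classical
ICA-derived RSNs — and method developers who need a planted-ground-truth
benchmark for this family of pipelines.

## The core models

* **Source imaging.** Minimum-norm estimate
  `S(t) = Lᵀ (L Lᵀ + λ(t) I)⁻¹ Φ(t)`, where `L` is the lead field, `Φ(t)`
  the sensor frame, and `λ(t)` is selected per timeframe by generalized
  cross-validation; λ outliers beyond 3 SD are repaired by interpolation.
* **CAPs.** Alpha-band (8–12 Hz) Hilbert envelopes, averaged into ROIs,
  z-scored per ROI across time, concatenated across participants, and
  clustered by k-means with correlation distance `d(x, c) = 1 − r(x, c)`.
  Cluster-average frames are CAP maps; maximal runs of one label define
  occurrence rates (Hz) and lifetimes (ms).
* **RSNs.** Channel-wise z-scored EEG → 1-s STFT windows (1 Hz bins) →
  complex average over 8–12 Hz → group temporal ICA (complex FastICA) →
  component envelopes regressed per dipole (OLS) → beta maps, averaged into
  group maps.
* **Correspondence.** Fisher-z spatial correlations and dice scores (maps
  binarized at 20 % of their maxima), permutation tests over RSN
  relabelings, hemispheric symmetry (correlation between a map and its
  mirrored copy), leave-one-out consistency, a mixed model
  `z ~ pattern + group + (1 | participant)`, and a timeframe-overlap graph
  across k.

## Worked example

Plant four templates (one left/right-dominant pair, two bilateral), simulate
four participants of 120 s at 250 Hz at snr 2, and recover the CAPs:

```r
library(capnet)

tpl <- make_templates(n_roi = 60, k_true = 4, seed = 42)
st  <- simulate_state_sequence(120, 250, occ_rates = rep(0.7, 4),
                               mean_dwell_ms = 80, seed = 42)
co  <- simulate_roi_envelopes(tpl, st, snr = 2, n_participants = 4, seed = 42)

frames <- lapply(seq_along(co$env), function(p)
  zscore_rois(co$env[[p]], fs = 250, participant = p))
X   <- t(do.call(cbind, lapply(frames, `[[`, "Z")))
pid <- rep(seq_along(frames), each = 120 * 250)

km   <- kmeans_correlation(X, k = 4, n_init = 10, seed = 42)
caps <- build_cap_maps(km$labels, X, pid, k = 4)

cm  <- abs(cor(t(caps$group_maps), t(tpl$templates)))
sol <- as.integer(clue::solve_LSAP(cm, maximum = TRUE))
data.frame(cap = 1:4, template = sol, template_kind = tpl$mirror_spec[sol],
           map_corr = round(cm[cbind(1:4, sol)], 3),
           symmetry = round(sapply(1:4, function(j)
             symmetry_index(caps$group_maps[j, ], tpl$mirror_pairs)), 2))
```

prints

```
  cap template  template_kind map_corr symmetry
1   1        3      bilateral    0.869     0.99
2   2        4      bilateral    0.761     0.99
3   3        1  left-dominant    0.832    -0.14
4   4        2 right-dominant    0.815    -0.23
```

Each recovered CAP map correlates 0.76–0.87 with its planted template after
optimal assignment; the bilateral CAPs have hemispheric symmetry ≈ 1 while
the unilateral pair's self-mirror symmetry is low, as constructed. Temporal
metrics (dropping single-frame runs, which label noise fragments):

```r
met <- cohort_run_metrics(split(km$labels, pid), fs = 250, min_run = 2)
round(aggregate(cbind(occurrence_rate_hz, mean_lifetime_ms) ~ cap_id,
                met, mean), 2)
```

```
  cap_id occurrence_rate_hz mean_lifetime_ms
1      1               3.42            61.57
2      2               5.81            44.88
3      3               5.10            42.01
4      4               5.31            41.91
```

against planted expectations of 3.12 Hz and 80 ms per state
(`expected_state_stats(rep(0.7, 4), 80, 250)`); recovered lifetimes are
shortened by run fragmentation at imperfect frame labels — see the methods
vignette (`vignettes/capnet-methods.Rmd`) for the quantitative story.

The whole chain (including the oscillation mode that exercises GCV inverse
imaging, filtering, Hilbert envelopes and the RSN branch) can also be driven
from one config:

```r
res <- run_pipeline(list(seed = 1, simulate = list(n_roi = 60, k_true = 4,
                                                   duration_s = 60)))
```

or from the command line:
`Rscript inst/cli/capnet run --config config.yaml --out runs/demo`.

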