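---
title: "capnet: models, assumptions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{capnet: models, assumptions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## What the package computes

`capnet` implements a two-branch analysis of resting-state EEG source
envelopes and a synthetic-data generator that makes the whole chain testable
without access to raw recordings.

The **transient branch** clusters individual timeframes of band-limited
(8–12 Hz) source-envelope data into co-activation patterns (CAPs):
each frame is a spatial vector of z-scored instantaneous amplitudes over
ROIs; frames from all participants are concatenated and clustered by k-means
with correlation distance `1 - r`; the per-cluster frame averages are the CAP
maps. Temporal structure is summarized by run-length statistics: an
*occurrence* is a maximal run of identically labeled frames, its *lifetime*
the run duration in ms, and the *occurrence rate* the run count per second.

The **time-averaged branch** estimates resting-state networks (RSNs) the
classical way: non-overlapping 1-s STFT windows (1 Hz bins, 0–100 Hz) of
channel-wise z-scored EEG, complex-averaged over the alpha bins, concatenated
across participants, and unmixed by temporal ICA. Component envelopes are
regressed (OLS with intercept) against every dipole/ROI envelope, giving
per-participant beta maps whose unweighted mean is the group RSN map.

The two branches are compared with Fisher-z spatial correlations, dice
overlap of maps binarized at 20 % of each map's maximum, permutation tests
that relabel RSN columns, a hemispheric symmetry index (correlation between a
map and its left–right mirrored copy), leave-one-out inter-participant
consistency, a mixed-effects model of consistency by pattern and functional
group, and a timeframe-overlap graph tracking how clusters split as k grows.

Upstream of both branches, sensor data can be mapped to source space with
the minimum-norm estimate
`S(t) = L' (L L' + lambda(t) I)^-1 Phi(t)`, with `lambda(t)` chosen per
timeframe by generalized cross-validation (GCV) and a 3-SD outlier repair of
the `lambda` series.

## The synthetic world

No public generative model exists for this kind of data, so the generator's
distributional choices are explicit stand-ins, fixed once:

* **Templates.** `k_true` spatial templates over `R` ROIs, built from
  mutually orthogonal smooth half-hemisphere "cores". Bilateral templates
  copy the core symmetrically; unilateral pairs weight the hemispheres by
  `1 ± 0.7`, so mirroring one member reproduces the other exactly. In
  hierarchy mode, sibling pairs share a core and each parent is the
  normalized child sum (child–parent correlation `1/sqrt(1 + d^2) ≈ 0.82`,
  sibling correlation `(1 - d^2)/(1 + d^2) ≈ 0.34` at `d = 0.7`).
* **State sequence.** A semi-Markov chain: the successor state is drawn with
  probability proportional to the configured occurrence rates *excluding the
  current state*, and the dwell is geometric with the configured mean
  (config hook for fixed-length dwells). Drawing successors i.i.d. and
  merging repeats — a literal alternative — inflates the realized mean dwell
  by `1/(1 - sum p_i^2)` (about +20 % at six equal-weight states), which is
  why the no-repeat chain is used. Because states are exclusive and cover
  every frame, configured rates act as *selection weights*: with mean dwell
  `m` seconds the total rate is necessarily `1/m`, and
  `expected_state_stats()` returns the implied ground-truth expectations
  (run share proportional to `p_i (1 - p_i)` under the no-repeat chain).
* **Frames.** `frame(t) = baseline + a(t) * template_p[state(t)] + noise`,
  with `a(t)` a half-cosine bump over each run (no hard onsets), `template_p`
  the participant's perturbed template (perturbation sd per functional group,
  defaults SM 0.05 < HO 0.15 < Other 0.30 of the template sd — the
  inter-participant variability gradient), and spatially smoothed Gaussian
  noise (Gaussian kernel over the ROI index, width 3) scaled so that
  template-signal variance over noise variance equals `snr` (default 0.5).
* **Oscillation mode.** Each source carries a 10 Hz cosine with a random
  fixed phase, amplitude-modulated by `max(1 + 4 a(t) T, 0.05)`; sensors see
  `L S(t)` plus white noise; the true sources and modulators ride along for
  oracle tests. Lead fields are smoothed Gaussian matrices, full row rank by
  construction.

What a green test does **not** establish: realism of head geometry, EEG
artifacts, 1/f background, volume-conduction leakage patterns, or any claim
about real-data effect sizes. The generator's defaults (dwell 80 ms, rates
0.5–0.9 Hz, 100–200 ROIs, 250 Hz, minutes-scale recordings, 8 participants)
mirror the orders of magnitude of the phenomenon being emulated, nothing
more.

## Numerical choices

* **Filtering.** Zero-phase 4th-order Butterworth bandpass, designed by
  bilinear transform with prewarping and applied forward–backward with
  odd-reflection padding. The environment ships no IIR filter package, so
  the design is implemented here; coefficients were cross-checked against an
  independent reference implementation during development, and the test
  suite verifies passband gain, stopband rejection, and spectral confinement
  directly.
* **Hilbert envelope.** FFT-based analytic signal; no edge trimming by
  default, `edge_trim_s` (≥ 1 s recommended) available in the pipeline
  config.
* **Z-scoring.** Default per ROI across time with sample sd (`n - 1`),
  matching the "equal ROI weighting" rationale; the per-frame-across-ROIs
  reading is selectable (`axis = "frame"`) and never silently mixed.
* **GCV.** Standard Golub–Heath–Wahba statistic
  `n ||(I - A)phi||^2 / trace(I - A)^2`, `A = L L'(L L' + lambda I)^-1`,
  evaluated in the eigenbasis of `L L'` on a 30-point log grid spanning
  `[1e-6, 1e2]` times the mean eigenvalue; ties break toward smaller lambda.
  A subtlety worth knowing: for *noiseless* data the lambda factors cancel
  and the GCV curve is flat as `lambda -> 0` with a known degenerate second
  minimum at large lambda, so the minimizer sits at one *end* of the grid
  rather than always at the smallest point. With noisy data the selected
  lambda grows monotonically with the noise level, which is the regime the
  method is for. Outlier repair computes mean/SD on raw lambda by default
  (`on_log = TRUE` available since lambda spans decades); a constant series
  defines no outliers. Note that a spike can only exceed `k` SDs of the
  whole series if the series is long enough (`max |z| = (n-1)/sqrt(n)`), a
  masking property inherent to the rule.
* **k-means.** Frames are centred and scaled to unit norm, making
  correlation k-means a spherical k-means whose normalized-mean centroid
  update exactly maximizes within-cluster similarity; k-means++-style
  seeding in correlation distance, `n_init = 10` restarts, stop when
  assignments are stable or at 300 iterations; emptied clusters are
  re-seeded from the worst-fitting frame. CAP maps are averages of the raw
  z-frames (not the standardized rows).
* **ICA.** The complex fixed-point FastICA (kurtosis contrast, symmetric
  decorrelation) is the default; the documented fallback stacks real and
  imaginary parts as separate real channels under a tanh-contrast real
  FastICA. A kurtosis contrast is used because spectral envelope sources are
  strongly super-Gaussian; a log-type contrast was observed to stall at
  mixed fixed points on exactly these sources. For time-domain projection a
  complex demixing matrix is applied to the analytic signal (components'
  moduli are the envelopes); stacked weights `(u, v)` are interpreted as the
  complex weight `u - iv` for the same purpose.
* **Permutation tests.** Uniform column relabelings with the identity
  permitted and the add-one p-value convention
  `p = (1 + #{null >= obs})/(1 + n_perm)`. Because the identity is
  permitted, an observed statistic can be tied (never strictly beaten) by
  null draws when the number of RSNs is small; the exact lower bound
  `1/(n_perm + 1)` is attained only when no drawn relabeling fixes the whole
  matched mask. Per-pair p-values are Bonferroni-corrected over matched
  pairs (the correction behind reported corrected values being otherwise
  unspecified).
* **Dice.** Maps are signed; the default binarizes positive values at 20 %
  of the positive maximum (`use_abs` switch for magnitude maps).
* **Matching.** Visual matching is replaced by optimal one-to-one assignment
  (Hungarian, via `clue`) maximizing total Fisher-z, overridable by a user
  match table that may contain one-to-two hemisphere-tagged rows; such rows
  count as two hemisphere-restricted pairs in the matched-mean statistic.
* **Mixed model.** `z ~ pattern + group + (1 | participant)` fitted by REML
  (`lme4`), Wald normal p-values on the t statistics; singular or degenerate
  fits fall back to a fixed-effects-only model, flagged in the result.

## Known limitations

* The exclusive-state generator makes template activations mutually
  dependent (their sum is nearly constant), so temporal ICA recovers a
  rotated basis of the activation subspace rather than one component per
  template: the dominant template is recovered almost perfectly, the others
  cap near spatial correlation 0.6–0.7 even on ground-truth sources. This is
  a property of the stated world, not of the estimator, and is asserted at
  its measured level in the test suite.
* Per-ROI z-scoring divides each ROI by its own temporal standard deviation,
  which is larger for ROIs with large template loadings; cluster-average CAP
  maps are therefore a nonlinearly shrunk copy of the planted template. At
  snr 0.5 this caps the map–template correlation near 0.9 *even with perfect
  labels*, which is why the planted-recovery acceptance check hovers at
  0.895–0.898 against a 0.9 bound.
* In hierarchy mode the same shrinkage plus finite-sample residue of the
  opposing sibling asymmetries attenuates *parent*-level cluster maps
  (|corr| ≈ 0.75–0.82 at snr 0.5) even when the k = 3 clusters align with
  the families at > 80 % frame purity; child-level recovery meets 0.85.
* A single-pair permutation test against few RSNs cannot be significant
  (the null fixes the matched column with probability `1/n_rsn`); meaningful
  tests need several matched pairs.
* Occurrence statistics derived from *cluster labels* fragment at label
  errors: at ~80 % frame accuracy, spurious single-frame runs roughly double
  occurrence counts. Ground-truth fidelity of the generator and encoder
  correctness are therefore tested on the true state sequences, and
  `min_run = 2` is available for label-derived statistics.
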