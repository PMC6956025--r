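---
title: "Selective wavelet-enhanced ICA removal of ocular artifacts"
author: "eogica package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective wavelet-enhanced ICA removal of ocular artifacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eogica)
```

## The problem

Eye blinks and eye movements generate electro-oculographic (EOG)
potentials one to two orders of magnitude larger than cortical EEG.
They propagate across the scalp with a frontally dominant topography
and contaminate every channel to some degree. Classical remedies
operate on an independent component analysis (ICA) of the recording:
either the ocular component is discarded entirely before inverse ICA
("rejection ICA"), which also discards all the cortical activity that
component carried, or the whole component is wavelet-thresholded
("wICA"), which still touches every sample of the component.

The method implemented here corrects the ocular components *only where
ocular activity actually occurs*: EOG peaks are detected inside each
flagged component, one-second windows are placed around the peaks, and
within those windows the component is rebuilt from only the
high-frequency detail bands of a multilevel Symlet wavelet
decomposition. Outside the windows the component -- and therefore the
reconstructed recording -- is untouched. The whole pipeline is
automatic; no visual inspection is involved.

## The pipeline

1. **Preprocess** -- zero-phase Butterworth band-pass (1--47 Hz,
   4th-order design run forward--backward) and average re-referencing.
2. **Decompose** -- Infomax ICA, `x = A S + mean`, `S = W (x - mean)`.
3. **Identify** -- a component is ocular iff its mean absolute mixing
   weight over the frontal channels exceeds the Tukey fence
   `Q3 + 1.5 IQR` of all components' weights *and* its best absolute
   Pearson correlation with a frontal channel reaches `min_abs_corr`.
4. **Detect peaks** -- local maxima of `|y|` with `|y| > 3 E{|y|}`,
   greedily thinned to a 0.5 s minimum spacing.
5. **Windows** -- 1 s windows centred on the peaks, merged; if the
   windows cover more than 60% of the component, the whole component
   is rejected instead (heavy-contamination fallback).
6. **Correct** -- inside each window, 5-level `sym4` decomposition and
   reconstruction from the D1:D3 detail bands only. At 200 Hz these
   span roughly 12.5--100 Hz; the discarded D4, D5 and A5 bands span
   0--12.5 Hz, where EOG energy (concentrated below about 7 Hz) lives.
7. **Reconstruct** -- inverse ICA with the corrected sources.

Methods `"wica"` (threshold the whole flagged component's coefficients
at the universal threshold `K sqrt(2 log N) sigma`,
`sigma = median(|D1|)/0.6745`) and `"icarej"` (zero the flagged
columns of `A`) are provided as baselines behind the same interface.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `filter.low_hz`, `filter.high_hz` | 1, 47 | band edges (Hz) |
| `filter.order` | 4 | one-way Butterworth order |
| `identify.frontal_channels` | Fp1, Fp2, F7, F8 | forehead montage |
| `identify.min_abs_corr` | 0.75 | correlation gate |
| `peaks.amp_factor` | 3 | peak threshold over `E{|y|}` |
| `peaks.min_separation_s` | 0.5 | minimum peak spacing (s) |
| `windows.width_s` | 1.0 | correction window (s) |
| `windows.reject_fraction` | 0.60 | full-rejection coverage, strict |
| `wavelet.basis`, `wavelet.levels` | sym4, 5 | decomposition |
| `wavelet.keep` | D1, D2, D3 | retained bands |
| `wavelet.crossfade_s` | 0.01 | splice crossfade (s) |
| `wica.threshold_scale` | 1 | baseline threshold factor K |

Notes on choices the literature leaves open:

* "Zero-phase 4th order" is interpreted as a 4th-order *design* applied
  forward--backward (effective 8th-order magnitude). `filter.order` is
  the one-way order. Edge transients are suppressed by odd-symmetric
  extension with steady-state initial conditions.
* The correlation gate `min_abs_corr` has no published value; 0.75 is
  the package default, exposed in the configuration. The rationale: an
  ocular component does not merely correlate with the forehead, it
  *dominates* it -- on semi-simulated data the blink-carrying
  component's best frontal correlation is about 0.85-0.95 while the
  strongest cortical component stays at or below about 0.7, so 0.75
  sits in the empty margin between the two populations (a gate of 0.5
  falls inside the cortical range and misflags artifact-free data).
  The weight fence is the quantitative rule; the correlation is
  confirmatory, computed on the *filtered* channel data (preprocessing
  precedes identification).
* Quantiles use linear interpolation between order statistics
  (`type = 7`), in both the implementation and the test oracles.
* Peak detection works on `|y|` because ICA component sign is
  arbitrary. `E{|y|}` is the mean over the entire component, not per
  window. A local maximum must dominate a 25 ms neighbourhood, not
  just its immediate samples: one-sample neighbourhoods let noise on a
  blink's rising flank register as the "peak" and systematically shift
  detections early. Spacing conflicts within the 0.5 s rule keep the
  larger contender (an EOG-peak detector must prefer the EOG peak over
  a coincident background fluctuation); an earliest-kept mode is
  available via `peaks.tie_break`.
* Five decomposition levels are the faithful default regardless of
  sampling rate. Because the band split tracks `fs`, `wavelet.levels =
  "auto"` sets `ceiling(log2(fs / 6.25))` so the removed band stays at
  about 0--6.25 Hz at any rate (e.g. 9 levels at 2048 Hz).
* Windows are spliced back with a 10 ms linear crossfade (inside the
  window) to avoid step discontinuities that would ring through the
  inverse ICA; outside the windows the output is bit-identical to the
  input component.

## Numerical design

* **Wavelet transform.** The decimated quadrature-mirror cascade is
  computed on a circular (periodized) signal after zero-padding to the
  next multiple of `2^levels`. Zero padding adds no energy, so perfect
  reconstruction, linearity and exact coefficient-energy conservation
  hold for arbitrary segment lengths; all three are asserted in the
  tests. This differs from symmetric-extension conventions elsewhere;
  with all coefficients retained the inverse reproduces the segment to
  machine precision either way.
* **ICA.** Natural-gradient logistic Infomax on centred, whitened
  data; blocked updates over a seeded random permutation each pass;
  learning-rate times 0.9 whenever successive updates differ by more
  than 60 degrees (the standard oscillation heuristic) or, after a
  100-pass burn-in, whenever the per-pass weight change stops
  decreasing (the stochastic-plateau signature); convergence
  when the relative Frobenius change of `W` drops below `tol` (default
  `1e-7`; if not reached within `max_iter` passes the last iterate is
  returned with a warning, never an error). Average-referenced data
  are rank-deficient by exactly one, so the fit runs in the
  `n - 1`-dimensional principal subspace; `A` is then the
  Moore--Penrose right inverse of `W` (`W A = I`; `A W` is the
  projector onto the retained subspace, in which the data lie). Any
  *other* rank deficiency (duplicate channels) is an error advising
  explicit PCA reduction. Sources are unit-variance with the dominant
  mixing weight positive, which makes peak detection and tests
  reproducible. Runs are bit-reproducible given the seed.
* **Degenerate inputs.** Constant channels, band edges at or above
  Nyquist, segments shorter than `2^levels`, and empty `keep` sets are
  explicit errors; empty peak sets, empty windows and an empty flagged
  set are legal results that propagate to "output equals preprocessed
  input".

## The synthetic data generator

No external recordings ship with the package; every claim is exercised
on semi-simulated data built from the same additive contamination
model the evaluation assumes:

```
contaminated[i, ] = pure[i, ] + a[i] * veog + b[i] * heog
```

* **Pure EEG** emulates eyes-closed resting recordings: 60 bursty
  band-limited (1--47 Hz) `1/f` sources with smooth, equal-norm
  dipolar topographies on a 2-D 10--20 scalp layout (more sources than
  channels, so every component is a mixture and no cortical source
  dominates a single electrode), a posterior-dominant
  waxing-and-waning alpha oscillation (8--12 Hz), and a 4 uV
  per-electrode noise floor. Channel RMS follows the eyes-closed
  front-to-back gradient, about 12 uV frontally to 26 uV occipitally.
  The slow amplitude envelopes make the sources super-Gaussian (excess
  kurtosis of several), which is what lets Infomax actually separate
  them -- and is true of real cortical activity.
* **VEOG** blinks are squared-cosine bumps, 200--400 ms wide,
  100--400 uV, at renewal-process times with a 1.2 s refractory gap.
* **HEOG** models spontaneous gaze shifts (20 per minute by default)
  as a piecewise-constant eye position jumping within +-150 uV at
  saccade times (0.6 s refractory gap), with 30 ms raised-cosine
  edges.
* **Propagation.** `a = aMax * exp(-d / tau)` with `d` the normalized
  front-to-back scalp coordinate and `tau = 0.28`, so a blink reaches
  Fp1 at full strength, the F row at about 60%, and the occiput at
  about 3%. The HEOG profile carries the same decay weighted toward
  lateral channels (F7/F8), both because eye movements project
  laterally and because proportional VEOG/HEOG profiles would collapse
  the two sources onto a single direction in channel space, making
  separation impossible for any method. Published per-channel
  coefficients for this model do not exist; the defaults reproduce the
  frontal-dominant topography the identification step assumes.

What the generator deliberately does *not* emulate: true
volume-conduction forward models, focal bursty sources at the frontal
pole itself (in an artifact-free reference such activity would be
indistinguishable from EOG by any frontal-topography criterion --
real "pure" reference data are selected for its absence), muscle or
cardiac artifacts, and non-stationary channel noise. Passing tests on
these data therefore demonstrate the pipeline's mechanics and its
ordering relative to the baselines, not clinical performance on
arbitrary real recordings.

All randomness flows from one seed through named sub-streams, so the
pure EEG, the EOG sources and the ICA toy problem are individually
reproducible.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely from the
generator: identification checks use 19-channel, 60--90 s datasets at
200 Hz with 12 blinks/min; the three-method benchmark uses twenty
120 s datasets under the same montage (one ICA fit per dataset, shared
by the three methods, since they diverge only after the
decomposition); the ICA recovery check uses three Laplacian sources at
20000 samples. These sizes keep every advertised property measurable
on a laptop-class machine.

## Evaluation metrics

Against a known pure reference (preprocessed identically, so filter
response is not counted as removal error):

* **lambda** `= 100 (1 - (Rref - Rcleaned) / (Rref - Rcontam))`, with
  `Rref` the lag-1 autocorrelation of the pure signal and the other
  two the correlations of pure with cleaned/contaminated. The
  reference mixes an autocorrelation with cross-correlations; it is
  implemented literally as defined. 0 means no improvement, 100 means
  the cleaned signal correlates with the truth as strongly as the
  truth's own lag-1 autocorrelation (values outside [0, 100] are
  possible and meaningful). On a channel the artifact barely reaches,
  `Rref - Rcontam` is near zero (or negative, since an uncontaminated
  channel correlates with its own truth better than the lag-1
  reference) and the ratio is numerically meaningless; lambda is
  therefore reported only where `Rref - Rcontam >= 0.05`, and channel
  means skip undefined channels.
* **delta-SNR** in dB, capped at +-120 for exact recovery.
* **RMSE** in uV.
* **Magnitude-squared coherence** via Welch averaging (Hann windows,
  2 s segments, 50% overlap by default -- the magnitudes depend on
  these, so they are configurable), averaged over the 1--47 Hz band.
* **Peak-detection sensitivity** `Se = 100 TP / (TP + FN)` with greedy
  one-to-one matching within +-100 ms (tolerance configurable; no
  published value).

All metrics are computed per channel and averaged.

## Known limitations

* Identification assumes ocular artifacts are the dominant
  frontal-weight outliers; recordings whose largest frontal source is
  cortical will produce false flags (the correlation gate mitigates
  but cannot eliminate this).
* With several strong simultaneous ocular sources, each component's
  share of any single frontal channel shrinks, and the confirmatory
  gate may reject genuine ocular components at its single-artifact
  default; lower `identify.min_abs_corr` for heavily contaminated
  recordings.
* The 60% coverage fallback means continuous-artifact components are
  rejected whole, with the same information loss as rejection ICA.
* With the `sym4`/5-level default the removed band is tied to the
  sampling rate; use `wavelet.levels = "auto"` away from 200 Hz.
* Infomax here is the logistic (super-Gaussian) variant; sub-Gaussian
  artifact types (e.g. line noise) are out of scope.
* Streaming operation is not supported; the pipeline is batch.
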