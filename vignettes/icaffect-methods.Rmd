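---
title: "Locating emotion-correlated EEG sources: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating emotion-correlated EEG sources: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis this package implements

`icaffect` implements a source-space analysis chain for the question:
*which neural sources carry frequency-band power that tracks an
observer's emotional state during affective picture viewing?*  Emotional
state is parameterized by the circumplex model — a valence axis
(unpleasant to pleasant) and an arousal axis (calm to excited), each
rated 1–9 with 5 neutral — and every picture stimulus carries a
normative rating on both axes.

The chain is:

1. **Preprocessing** — earlobe or average re-reference, zero-lag
   windowed-sinc FIR band-pass (0.5–45 Hz), decimation to the analysis
   rate, extraction of the 6-s stimulus epochs, automated channel and
   epoch cleaning, common-average reference, PCA rank reduction.
2. **ICA** — linear decomposition of the concatenated epochs into
   independent components (ICs), each a source time course with a fixed
   scalp topography.
3. **Dipole localization** — a single equivalent current dipole fitted
   to each topography in a spherical head model; ICs are kept as *brain
   ICs* when the dipole explains the topography well (residual variance
   at most 15%), sits inside the brain, and the component is not
   muscle- or ocular-like.
4. **Cross-participant clustering** — k-means on an 18-dimensional
   description of each brain IC (3 dipole coordinates, 10 topography
   principal components, 5 ERP principal components), 3-SD outlier
   pruning, retention of clusters spanning a strict majority of
   participants.
5. **Band-power features** — Welch PSDs (1-s Hann segments, 0.25-s
   overlap) averaged across a participant's member ICs *before* the
   logarithm, then natural-log band power in theta (4–7), alpha (8–13),
   beta (14–30) and gamma (31–45 Hz).  Band edges are inclusive; with
   1-Hz bins, 7 Hz belongs to theta and 8 Hz to alpha.
6. **State-specific regression** — for each rating axis, epochs are
   split into the high (> 5) and low (< 5) state; within each of the
   four (axis, state) subsets, ordinary least squares predicts the
   standardized normative rating from the four standardized band powers,
   evaluated by leave-one-participant-out (LOPO) cross-validation.
   Standardization is within participant, with the population (1/n)
   variance so "variance 1" holds exactly; the convention does not
   affect correlations but is fixed for reproducibility.
7. **Group inference** — per cluster, the fold-wise Pearson correlations
   between predictions and ratings are Fisher-z transformed, tested
   against zero with a one-tailed one-sample t-test (sample SD, n−1
   degrees of freedom), and Holm–Bonferroni corrected across the
   retained clusters within each (axis, state) family at α = 0.025
   (0.05 halved over the two states per axis).  The back-transformed
   mean z is reported as the cluster's mean r.

`run_pipeline(pipeline_config(...))` executes all stages from one
serializable configuration; every random stage draws its seed
deterministically from the single configured seed, so a results table is
reproducible from the archived `config.yaml` alone.  The `analysis/`
scripts present the same chain as a stepwise narrative.

## The spherical forward model

Anatomy is deliberately out of scope: the forward model is a single
homogeneous conducting sphere (default radius 90 mm, conductivity
0.33 S/m) with electrodes on rings of the upper hemisphere.  The surface
potential of an interior dipole has a closed form obtained by summing
the interior Neumann-problem Legendre expansion with the
generating-function identities; the test suite checks it against an
independent term-by-term series evaluation to below 1e-6 relative error.
Localization claims are therefore *model-consistent* statements
(recovering a dipole that generated data in the same sphere), not
anatomical ones.  "Outside the brain" becomes radius > 0.9 of the sphere
radius, since a sphere has no anatomical boundary.

Dipole fitting is a coarse-to-fine search: residual variance (RV) is
evaluated on a 10-mm interior grid — at each candidate the optimal
moment is a 3-column linear least-squares solve, so RV is exact per
location and invariant to topography scale — and the best candidate is
refined by Nelder–Mead simplex until the location moves less than
0.5 mm.  The refinement is derivative-free on purpose: the RV surface is
smooth but the implementation does not assume the lead field is
differentiable.  Topographies whose best grid RV exceeds 0.35 receive a
single abbreviated refinement round; from a 10-mm grid, refinement
cannot bridge the gap to the 15% acceptance threshold, so these
components cannot become dipolar and only their (large) RV is needed.

With sparse montages the depth of an eccentric dipole is weakly
determined: nearly identical topographies arise from slightly deeper and
shallower dipoles, so a fitted location can drift outward at essentially
zero RV.  This is an identifiability limit of single-dipole fitting, not
an optimizer failure; it motivates the generator's choice to seat
cortical sources at moderate depths (below 0.8 of the sphere radius).

## The synthetic cohort generator

No public recording exists for this design, so the generator *is* the
data source, and its defaults define the study conditions: 25
participants, 160 stimuli (40 per quadrant, uniform within each
quadrant's rectangle with a ±0.1 guard band around the neutral value 5,
so state membership is never ambiguous), 8 sessions × 20 trials with 5
stimuli per quadrant per session, 64 channels, 6-s epochs at 512 Hz
(the post-downsampling rate; simulating at 2048 Hz and decimating is
exercised separately in the filter tests).  The scaled demonstration
cohort (`demo_cohort_config()`) keeps the 160-epoch design but uses 6
participants, 16 channels and 96 Hz — the lowest rate whose Nyquist
clears the 45-Hz gamma edge — so that a full pipeline run takes seconds
rather than hours.

Each source is a fixed dipole whose activation is synthesized per epoch
from four band-limited oscillations plus a 1/f background:

* Oscillations are built in the frequency domain (fixed amplitude
  spectrum on the band's bins, random phases), burst-modulated by a
  slow (0.5-Hz) random envelope, and normalized to exact target RMS.
  Bursting matters twice: real EEG rhythms wax and wane, and the
  resulting super-Gaussian marginals are what make the mixture
  identifiable by ICA at all — without it the sources are
  near-Gaussian and no ICA algorithm can separate them.
* The planted effect is on the log power of band b in epoch e:
  `log P_b(e) = log(baseline_b) + slope(b, axis, state(e)) * z(e) +
  participant offset + noise`, with z(e) the stimulus rating
  standardized over the stimulus set.  Slopes act only in their
  configured state, which is exactly the state-specificity the
  regression stage is meant to exploit.  Background energy is placed
  only on bins *outside* the four bands, so planted band powers are
  exact up to the burst envelope's small leakage (≈ 9% of band energy,
  nearly constant, absorbed by standardization).
* Baseline band powers (theta 1, alpha 2, beta 0.6, gamma 0.15) sketch
  a realistic falling spectrum with an alpha peak; the beta-to-gamma
  ratio matters because the muscle-IC heuristic tests the 20–45-Hz
  spectral slope, and a flat baseline there would let ordinary
  participant-level power variation flip the slope positive.
* Per-participant variability: dipole-location jitter (SD 5 mm, clipped
  to depth 0.8 R for cortical and 0.88 R for artifact sources),
  multiplicative effect-size perturbation (SD 20% of the slope), and
  per-band log-power offsets (SD 0.3).
* One ocular artifact dipole sits shallow at the sphere's front with
  only slow (0.5–3.5 Hz) power and no rating dependence; sensor noise
  is half white, half 1/f, at SNR 10 (mixed-signal variance over
  noise variance per channel).
* Amplitudes are calibrated to the conventional EEG scale: each
  source's moment magnitude is set so its strongest electrode sees 5 µV
  per unit source RMS, which lands cortical channels near 10 µV RMS —
  the scale the 200-µV peak-to-peak epoch-rejection default assumes.

Planted slope magnitude 0.5 (on standardized ratings) is a calibration
choice: the field reports no effect sizes in physical units, and 0.5
produces fold correlations around 0.3–0.5 in the scaled cohort — large
enough that recovery measures pipeline correctness rather than luck,
small enough that the regression problem stays non-trivial.

What the generator does **not** emulate: volume-conduction anatomy,
session-level nonstationarity, non-dipolar or moving sources,
correlated source activity, muscle and line-noise artifacts (off by
default), or behavioral reports.  Passing tests therefore demonstrate
that the chain recovers effects of the planted kind under the stated
noise model — not that real EEG satisfies that model.

## Numerical and design choices

* **Cleaning thresholds** replace visual inspection with stated rules:
  robust |z| of channel log-variance > 5 flags a channel (catching dead
  as well as noisy channels); epoch peak-to-peak > 200 µV or robust
  log-variance z > 4 removes an epoch.  All are configuration keys.
* **Channel interpolation** uses spherical-spline weights (order-7
  Legendre kernel, m = 4, light ridge).  Distance-weighted averaging was
  tried first and rejected: on average-referenced dipolar fields the
  distant channels carry opposite-polarity values, and both global and
  nearest-neighbour inverse-distance kernels reconstructed held-out
  channels poorly (correlations as low as 0.3 in adversarial
  geometries, versus > 0.9 for the spline on interior channels).
* **Rank rule**: after average referencing, rank = channels − 1 −
  interpolated channels; ICA runs in that principal subspace.
* **ICA**: two algorithms behind one contract — extended-Infomax
  natural-gradient (default) and fixed-point negentropy with symmetric
  decorrelation.  The Infomax stochastic phase anneals its step only
  when successive update directions oscillate, then a full-batch
  natural-gradient polish removes the stochastic noise floor so
  identical data reach the same optimum from any seed (up to
  permutation and sign).  Components are returned in descending order
  of projected variance with unit-norm topographies, sign-fixed so the
  largest-magnitude weight is positive; every later stage relies on
  that deterministic polarity.  The demonstration configuration selects
  the fixed-point algorithm, which converges in ~25 sweeps on the
  scaled cohorts; the unmixing matrix may be estimated on an evenly
  spaced subsample of the concatenated data (50,000 samples by
  default), with activations always computed on the full data.
* **Outlier pruning** in clustering interprets "3 SD" with the k-means
  convention: a cluster's SD is the root-mean-square member distance to
  its centroid.  Taking instead the standard deviation *of the
  distances* prunes entire clusters in 18 dimensions, where distances
  concentrate (large mean, small spread).  Pruning runs once, then
  memberships are recomputed once against the re-estimated centroids.
* **k is not auto-selected**: the default (7 at full scale, 4 in the
  demonstration cohort, matching its 4 cortical sources) is a
  configuration key, and a mean silhouette width is emitted as a
  diagnostic for choosing it.
* **Band power** is the mean over in-band PSD bins (not the integral);
  with fixed bins the two differ by a constant per band that
  standardization removes.  Logs are natural; any base differs by a
  constant factor that standardization also removes.
* **ERP block**: the 0–500-ms across-epoch mean activation, resampled
  to a fixed 128 points so cohorts at different sampling rates produce
  comparable features.
* **Neutral ratings** (exactly 5) cannot occur in simulation; on
  imported data they are excluded from both states with a warning.

## Validation studies

Three studies, run by `scripts/acceptance.R` and (lighter) by
`analysis/06_validation_studies.R`:

* **End-to-end recovery** (`recovery_validation()`): on independently
  simulated scaled cohorts (6 participants, 160 epochs, 4 cortical
  sources), find the retained cluster nearest the occipital plant and
  ask whether it is Holm-significant for (valence, high) and whether
  its mean theta coefficient is negative.  Across development runs the
  significance rate was ≈ 0.9 and the sign rate 1.0.
* **Null familywise error** (`null_fwer_validation()`): cohorts with no
  planted effect, simulated at the regression-input level (independent
  band-power features for 3 clusters, 6 participants, 40 epochs per
  state), full regression and Holm inference per family.  Simulating
  at the feature level is what makes 200 replicates feasible; the
  regression and inference stages under test are exercised in full.
* **Separation quality** (`amari_snr_validation()`): the Amari index
  between estimated unmixing and true mixing decreases monotonically
  along an SNR ladder.

## Known limitations

* **The fold t-test is anti-conservative.**  LOPO folds are not
  independent samples: every fold predicts the *same* normative
  ratings, and any two training sets share all but two participants, so
  fold-wise Fisher-z values are positively correlated (≈ 0.24 pairwise
  under the null at the scaled conditions, while their marginal
  variance matches the independent-sampling value).  The one-sample
  t-test across folds — faithfully implemented as the procedure
  prescribes — then rejects a true null more often than its nominal
  level: measured per-cluster P(p < 0.025) ≈ 0.08 and familywise rates
  around 0.05–0.07 instead of 0.025 at 6 folds.  The package reports
  the measured rate rather than forcing it to the nominal level; users
  drawing confirmatory conclusions should calibrate significance by
  permutation (shuffling ratings within participants) instead of
  relying on the t reference distribution.
* Localization accuracy is montage-limited; with 16 channels the depth
  of eccentric dipoles is weakly identified (errors of ~10 mm at
  near-zero RV are possible), which occasionally costs a participant's
  IC at the brain-margin check.
* The homogeneous sphere ignores skull conductivity layering; RV
  thresholds tuned for real BEM models are applied unchanged within the
  self-consistent sphere world.
* Problem sizes in the shipped studies are scaled (6 participants,
  16 channels, 96 Hz; 50 recovery seeds; 200 null replicates) so the
  whole validation suite completes on a laptop; the full-design
  defaults (25 participants, 64 channels, 512 Hz) are exposed by
  `cohort_config()` and run unchanged, only longer.
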