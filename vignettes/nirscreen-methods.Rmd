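---
title: "Resting-state prefrontal fNIRS connectivity and cognitive screening: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state prefrontal fNIRS connectivity and cognitive screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nirscreen` implements a complete resting-state prefrontal fNIRS analysis:
raw two-wavelength intensities are converted to oxy-/deoxy-hemoglobin
concentration changes, channel series are aggregated into 10 prefrontal
regions of interest (ROIs), ROI-pair functional connectivity (FC) is
estimated by band-averaged coherence (COH) and the phase-locking value
(PLV), group differences across normal controls (NC), subjective cognitive
decline (SCD) and mild cognitive impairment (MCI) are tested with one-way
ANOVA + Benjamini-Hochberg FDR + LSD-t post hocs, and a nine-classifier
cross-validated screen discriminates the groups, benchmarked against a
permutation-derived empirical chance accuracy (EACC). Because no subject
recordings ship with the package, a synthetic-cohort generator with known
ground truth stands at the front of the pipeline; every stage is validated
against it.

## The measurement model

A continuous-wave device records intensity at two wavelengths (780 and
850 nm) for 48 prefrontal channels at 8.138 Hz with a 3.0 cm
source-detector separation. Light attenuation follows the modified
Beer-Lambert law: writing optical density as
$\Delta OD_\lambda(t) = -\ln I_\lambda(t)/\bar I_\lambda$, the chromophore
concentration changes solve, per channel and sample,

$$\Delta OD_\lambda = \left(\varepsilon_{HbO,\lambda}\,\Delta HbO +
  \varepsilon_{HbR,\lambda}\,\Delta HbR\right) d \cdot ppf,$$

with $d = 3$ cm, partial pathlength factor $ppf = 6$, and
$\Delta HbT = \Delta HbO + \Delta HbR$ by definition. The extinction
coefficients at the two wavelengths are not universal constants across
compilations, so the package ships a fixed, named table
(`hb_extinction_table()`, mM^-1 cm^-1) and uses it for both the forward
map of the simulator and the inverse of the preprocessing chain; results
are therefore bit-reproducible against a declared coefficient set, and the
forward-inverse round trip is exact to numerical precision.

## Preprocessing chain

Stages run in a fixed order (`preprocess_recording()`), each with the
conventional default for a resting-state protocol:

1. **SNR pruning.** A channel is excluded when
   $20\log_{10}(\mathrm{mean}(I)/\mathrm{sd}(I)) < 25$ dB at either
   wavelength. The dB formula is the standard raw-intensity quality metric
   for continuous-wave fNIRS; a constant channel has infinite SNR and is
   kept. A subject with all 48 channels pruned is marked excluded rather
   than raising an error, mirroring quality exclusions in real cohorts.
2. **Intensity to OD**, invariant to any positive rescaling of intensity
   (gain-independence of the whole chain follows).
3. **Motion detection** (`detect_motion_artifacts_by_channel()`): a 2-s
   sliding window flags excursions exceeding 50 x the channel's baseline
   SD or 5 OD units; flags are dilated by 4 s each side and pooled across
   wavelengths. The baseline SD is estimated in two passes -- first a
   MAD-based robust estimate (a large artifact must not inflate its own
   threshold), then the classical SD of the samples left unflagged.
4. **Spline correction** (`spline_correct()`): within each flagged
   segment a smoothing spline (p = 0.99 in the csaps convention; we map
   p to `smooth.spline`'s penalty as $\lambda = (1-p)/p/(n-1)^3$ to undo
   its x-rescaling) is fitted and subtracted, removing the artifact
   waveform. Segments are then re-anchored in sequence by matching mean
   levels over a 30-s window. The window length matters: it must be long
   relative to in-band oscillations so genuine signal averages out and
   only baseline discontinuities are removed. With a 2-s window a spike
   correction propagates a spurious level shift to the rest of the
   record; with 30 s both spike- and shift-type artifacts are repaired
   (shift baselines reduced by >99% in the test suite, spike records
   restored to r > 0.95 against the clean signal). Segments too short
   for a spline fall back to linear detrending.
5. **Band-pass 0.01-0.1 Hz**: third-order Butterworth applied
   forward-backward (zero phase), with odd-reflection padding and exact
   DC removal so slow-pole startup transients do not contaminate the
   passband. Mid-band loss is below 5% and cardiac-band (1 Hz)
   attenuation exceeds 20 dB.
6. **Global PCA** (`pca_filter()`): the single largest-variance principal
   component of the channel ensemble is projected out per wavelength
   (count configurable), the standard spatial filter for superficial and
   systemic physiology that survives the temporal filter (Mayer waves sit
   at the passband edge). The removed variance equals the corresponding
   covariance eigenvalues exactly.
7. **Beer-Lambert inversion** to HbO/HbR/HbT in micromolar.

The stage count and order are fixed; each stage's intermediate output can
be retained (`keep_intermediates = TRUE`) for audit. Because the global
PCA removes shared variance by design, the forward/inverse recovery
checks in the test suite run with `pca_remove = 0` -- with nuisance
disabled, the largest shared component *is* the injected signal.

## ROI connectivity

The 48 channels map onto 10 ROIs (right/left DLPFC, DLPFC/RPFC border,
MPFC, OFC, VLPFC) with per-ROI channel counts (6,6,6,6,3,3,5,5,4,4);
`roi_channel_map()` returns the fixed montage. ROI series are unweighted
means over unpruned member channels; an ROI with no surviving channel is
invalid and its pairs propagate as missing.

Two FC estimators operate on the 0.01-0.1 Hz band:

- **COH** (`coherence_fc()`): Welch magnitude-squared coherence
  $|S_{xy}|^2/(S_{xx}S_{yy})$ with 120-s Hann segments at 50% overlap
  (four segments for a 5-min recording), averaged over the in-band
  frequencies. The exact flavor of "amplitude-frequency coherence" is a
  genuinely open design point; Welch with band averaging was chosen as
  the standard reproducible estimator on the same band as the temporal
  filter, with segment length and overlap config-exposed. Note the
  estimator floor: with four 50%-overlapping segments, independent noise
  yields band-averaged COH around 0.27, not 0.
- **PLV** (`plv_fc()`): both series are band-limited, instantaneous
  phases are taken from the FFT analytic signal, and
  $PLV = |\mathrm{mean}_t\, e^{i(\varphi_x - \varphi_y)}|$ after
  discarding 5% of samples at each end (analytic-signal edge effects).
  The PLV band equals the preprocessing passband; no second, narrower
  band is introduced.

Both estimators are bounded in [0, 1], equal 1 for a self-pair, and error
on constant (degenerate) input; degenerate or invalid pairs are stored as
`NA`. Per subject, 2 estimators x 3 chromophores x 45 ROI pairs give the
270 FC features of `fc_features()` / `build_feature_table()`.

## Group statistics

Per connection (across subjects, pairwise-complete): a Shapiro-Wilk gate
at alpha = 0.05 decides whether the feature is z-score transformed (the
procedure is a faithful implementation of the z-transform-if-non-normal
convention; note a z-transform cannot actually normalize a distribution,
and the ANOVA F is invariant to it -- it matters only for the descriptive
scale of the post hocs). The omnibus test is the classical one-way
fixed-effects ANOVA; p-values are BH-adjusted within each (estimator,
chromophore) family of 45 connections, because results are reported per
family (pooling across all 270 is available via `fdr_family = "pooled"`).
Where the corrected p falls below 0.05, Fisher LSD-t post hocs compare
the three group pairs using the omnibus within-group mean square,
$t = (\bar x_a - \bar x_b)/\sqrt{MSW(1/n_a + 1/n_b)}$ with $df = N - k$.
The suite checks these against brute-force sum-of-squares oracles,
`stats::aov`/`oneway.test`, manual BH step-up, null (type-I) and
power simulations.

## Classifier screen

Three binary tasks (SCD vs NC, MCI vs NC, MCI vs SCD; the impaired group
is the positive class) x two feature sets (270 FC features, or 270 + 6
neuropsychological scores) x nine classifiers (LDA, logistic regression,
Gaussian naive Bayes, RBF SVM, 5-NN, random forest, XGBoost, a classic
gradient-boosting configuration, and RUSBoost -- AdaBoost-style boosting
with per-round random undersampling of the majority class, implemented
in-package over depth-limited CART learners) x stratified 5- and 10-fold
cross-validation.

Within every training fold, in order: a variance filter on the raw
training features, z-scoring by training means/SDs, PCA retaining 95% of
the training variance, classifier fit. All statistics are frozen on the
training fold and reapplied verbatim to the test fold; the suite asserts
that perturbing test rows cannot change fitted transforms. Metrics (ACC,
sensitivity and specificity w.r.t. the declared positive class, rank-based
AUC with a DeLong 95% CI) are computed on the predictions pooled across
test folds, so each subject is predicted exactly once per scheme and one
CI is reported per model.

Two deliberate departures from a literal reading of the printed recipe:

- **Variance-filter placement and threshold.** Applied after z-scoring,
  a "remove variance <= 1" rule deletes every feature (training variance
  is exactly 1 by construction), so the filter runs on *raw* training
  features, before normalization. Even so, a threshold of 1 removes all
  FC features, whose values -- hence variances -- are bounded well below
  1. `fit_fold()` keeps `var_threshold = 1` as its documented default
  and errors informatively when the filter empties the feature set;
  the pipeline-level entry points (`full_screen()`, `run_pipeline()`)
  disable the filter (`var_threshold = 0`, i.e. drop only constant
  features), which is the only self-consistent reading for bounded
  connectivity features. The threshold is config-exposed throughout.
- **Fold schemes side by side.** 5- and 10-fold results are both
  computed and reported in separate rows rather than pooled, since either
  could be the headline scheme.

**EACC.** For each task x model x scheme, the identical CV pipeline is
rerun `n_perm` times (default 200) with labels randomly permuted; EACC is
the mean pooled accuracy. ACC > EACC indicates performance above what the
same pipeline extracts from label-free structure (class imbalance
included: a majority-class-biased learner on a 90:48 task has EACC near
0.65, not 0.5). The suite verifies EACC ~ 0.5 on balanced uninformative
data and that informative data puts ACC well above EACC.

## The synthetic cohort

`generate_cohort()` emulates the study conditions: groups NC/SCD/MCI of
48/65/90 subjects, 5-min recordings at 8.138 Hz (2441 samples), and six
neuropsychological scores (MMSE, TMT-A, TMT-B, BNT, HVLT, CDT) drawn per
group from normal distributions with the published group means and SDs,
clipped to instrument bounds and rounded for integer-valued tests.

Recordings are built forward: latent ROI signals are 0.01-0.1 Hz
band-limited noise mixed through the Cholesky factor of a group-specific
coupling matrix, so a pair's correlation equals its configured coupling
and a shared source is weighted by the coupling value; member channels
inherit the ROI signal as Delta-HbO (0.5 uM SD), Delta-HbR is
-0.3 x Delta-HbO plus independent narrowband noise (the literature gives
no generative HbR model; anticorrelated scaling is the conventional
stylized fact, and the ratio is configurable); concentrations pass
through the forward Beer-Lambert map; cardiac (1 Hz), respiratory
(0.25 Hz) and Mayer (0.1 Hz) oscillations, a linear drift, motion
artifacts (half spikes of 5-20 x signal SD and 0.5-2 s, half persistent
baseline shifts; Poisson event times at 0.5 events/min) and white
measurement noise (0.002 OD) are added in OD; intensities are
$1000\,e^{-OD}$, hence strictly positive. Defaults were chosen once as
representative resting-state magnitudes. Note that at these conservative
defaults most injected artifacts sit *below* the 50 x SD / 5 OD
detection thresholds -- the detector targets gross artifacts, as its
parameters imply.

Ground truth (group, coupling matrix, clean ROI HbO, artifact table) is
returned per subject, enabling the recovery tests: with nuisance, noise
and artifacts disabled the chain recovers injected concentration series
to r >= 0.95, and the pipeline's FC estimate for a pair rises
monotonically with the injected coupling. The default group effect
raises three connections (ROI1-ROI3, ROI2-ROI7, ROI4-ROI7) with coupling
0.30/0.45/0.60 for NC/SCD/MCI over a 0.3 background -- the reported
effect sizes are not published, so these deltas are free parameters of
the generator, not calibrated values.

What the generator does *not* emulate: photon transport through layered
tissue, scalp hemodynamics, heteroscedastic channel gains, non-Poisson
artifact clustering, or realistic score-FC correlations beyond the group
structure. Passing tests therefore demonstrate correctness of the
algorithms under a controlled generative model, not performance on real
cohorts -- reproducing the published clinical classification metrics is
explicitly out of scope because the subject data are not deposited.

## Numerical choices and problem sizes

- Filtering uses odd-reflection padding (length ~ one high-pass period)
  and exact mean removal; zero phase is asserted by cross-correlation.
- Welch segments: 120 s, 50% overlap, Hann; changing the segment length
  changes the estimator floor, so comparisons should keep it fixed.
- The coupling matrix is nudged to the nearest positive-definite
  correlation matrix (eigenvalue clipping) before Cholesky mixing.
- Tie handling: rank AUC uses mid-ranks (ties count 1/2), verified
  exactly against an exhaustive pairwise oracle.
- Test-suite problem sizes are desk-scale by design: e.g. 20 seeded
  replicates for pipeline coupling monotonicity, 60 replicates for
  estimator floors, n = 10,000 for score-distribution recovery, 25-rep
  null and 20-rep power simulations for the statistics gate, and a
  12-subject end-to-end pipeline run. All randomness flows from explicit
  seeds; identical config + seed reproduces cohorts bitwise.

## Known limitations

- Recordings are serialized in a plain-text container (header + TSV)
  rather than a binary neuroimaging format; the format is lossless for
  the data the pipeline consumes and keeps the package dependency-light.
- The spline correction's level-chaining assumes baselines should match
  across artifacts; a genuine slow level change coinciding with a flagged
  segment would be flattened.
- LSD post hocs are unadjusted beyond the FDR-corrected omnibus gate, by
  construction of the procedure.
- EACC at `n_perm = 200` has a Monte-Carlo SE of roughly 0.2/sqrt(200)
  ~ 0.014 on a balanced task; differences smaller than that are noise.
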