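---
title: "Classifying thyroid smears from MALDI-MSI data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying thyroid smears from MALDI-MSI data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Matrix-assisted laser desorption/ionisation mass spectrometry imaging
(MALDI-MSI) acquires one profile-mode mass spectrum per pixel of a scanned
specimen, so a single cytological smear becomes a data cube: two spatial
axes and an m/z axis (here m/z 3000-25000, the protein region accessible to
linear-TOF instruments). For thyroid nodules the clinically painful cases
are the cytologically undetermined reports (SIAPEC category THY3): most turn
out benign on post-surgical histology, yet current guidelines send them to
thyroidectomy. `msiclass` implements a complete, reusable pipeline that
turns raw MSI data cubes into a binary benign-versus-malignant (Ben/PTC)
classifier and applies it both to per-patient average proteomic profiles and
pixel by pixel across a smear.

The pipeline stages are:

1. **Preprocessing** (per spectrum): Savitzky-Golay smoothing, TopHat
   baseline subtraction, total-ion-current (TIC) normalisation.
2. **Feature extraction**: MAD-based signal-to-noise peak picking, greedy
   ppm-tolerance peak alignment across spectra, presence filtering, and the
   peak-list matrix (samples x aligned reference peaks).
3. **Feature selection**: recursive feature elimination (RFE), candidate
   subsets scored by a two-class partial least squares (PLS) model under
   repeated stratified 10-fold cross-validation.
4. **Classification**: a radial-kernel SVM, grid-tuned over (cost, gamma),
   assessed by repeated cross-validation and external validation with the
   full diagnostic panel (accuracy, sensitivity, specificity, PPV, NPV,
   ROC AUC; benign is the positive class, because the clinically useful act
   is *confirming benignity* of an undetermined report).
5. **Pixel maps**: the trained model applied to every pixel of an unknown
   smear, rendered green (benign) / red (malignant) / grey (unclassified).

## Preprocessing operators

All window parameters are counted in points (index space), not Th: the
spectra are near-uniformly sampled and the operators act on the sampled
sequence.

* **Savitzky-Golay smoothing** (`savgol_half_window = 10`, `polyorder = 3`):
  each point is replaced by the centre value of a local least-squares
  polynomial fit. Within `half_window` points of the edges the polynomial is
  fitted on the truncated window and evaluated in place, so no padded values
  ever enter a fit. The operator reproduces polynomials up to the fit order
  exactly, which the tests exploit as an oracle.
* **TopHat baseline** (`tophat_half_window = 75`): the baseline is the
  morphological opening (erosion then dilation with a flat structuring
  element of width `2*75+1` points) of the intensity trace; the residual is
  clipped at zero. Opening is anti-extensive and idempotent — both are
  asserted as invariants. The element must be wider than any real peak: at
  the 3 Th default axis step of the synthetic data, 151 points comfortably
  exceed the ~50-point width of the broadest peaks at m/z 25000.
* **TIC normalisation** (`tic_target = 1`): intensities are scaled so each
  spectrum integrates to the same area. A spectrum whose total ion current
  is not positive raises a typed degenerate-spectrum condition; the pixel
  classifier catches it and marks the pixel unclassified instead of
  aborting a whole map.

The fixed order is smooth, then baseline, then normalise. Smoothing before
the opening keeps noise spikes from carving the baseline; normalising last
makes the unit-area contract exact on the final signal. Smoothing may
produce small negative excursions; the baseline step clips the final result
at zero.

## Peak extraction

Noise is one global scalar per spectrum, `1.4826 * median(|I - median(I)|)`
(the Gaussian-consistent MAD). A peak is the unique maximum within +/-20
points whose intensity reaches 3 times the noise, *inclusive* — "a
threshold of 3" is read as >=. S/N picking is known to admit false positive
peaks from noise; that is exactly what the downstream presence filter is
for.

Alignment pools all peaks, sorts them, and starts a new reference group
whenever the gap to the previous peak exceeds 2000 ppm of the incoming m/z.
Groups that capture two peaks from one source are split recursively at
their largest internal gap, so no source contributes twice to a reference.
The reference m/z is the intensity-weighted mean of the group, favouring
well-measured peaks and breaking ties deterministically. The presence
filter keeps references detected in at least 25% of the sources (boundary
inclusive), the denominator being whichever collection is being processed —
patient profiles during training, pixels during pixel-map filtering.

The peak-list matrix has one row per source and one column per surviving
reference. Cells without a detected peak are backfilled with the source
spectrum's maximum intensity inside the tolerance window (the detection
mask remembers they were not picked); training matrices, validation feature
vectors and restored-model scoring all use the same backfill rule, because
mixing backfilled training features with zero-filled validation features
would shift the validation cohort systematically toward low intensities.

Patient profiles are the pointwise mean spectrum of the patient's pixels,
computed after preprocessing; peak picking then runs on the mean spectrum.
Averaging first and picking second keeps weak but consistent peaks that
per-pixel picking would lose, at the cost of hiding per-pixel peak
statistics — the pixel classifier compensates by re-picking per pixel.

## Feature selection

The PLS scorer is a NIPALS PLS1 fit on the class code (Ben = +1,
PTC = -1), three latent components, both blocks deflated, giving mutually
orthogonal scores. Predictors are mean-centred and autoscaled to unit
variance inside the fit. Autoscaling is a deliberate design choice: peak
intensities span orders of magnitude, and without it the absolute
regression coefficient — the importance statistic used to decide
elimination order — would rank features by their variance rather than
their class information. Ties in importance break toward the lower m/z, so
elimination is fully deterministic.

RFE runs 2 repeats of stratified 10-fold cross-validation. Within each
training fold, features are eliminated block-wise down through the
candidate sizes `{2, 5, 10, 15, 20, 25, 30, 40, 60, 80, 100, all}`
(re-fitting the PLS model at each step), and each size's held-out accuracy
is recorded. The chosen size maximises mean cross-validated accuracy, ties
going to the *smallest* size; the final feature set comes from re-running
the elimination on the whole training set at that size.

A consequence worth knowing: on strongly separable cohorts the accuracy
profile saturates, several sizes tie at the maximum, and the smallest-size
tie-break deliberately returns a compact panel rather than the full set of
truly informative features. Completeness of recovery and parsimony pull in
opposite directions here; the pipeline follows the parsimony rule, and the
synthetic-data tests measure recovery as the fraction of planted
discriminative peaks contained in whatever panel is selected.

## The SVM and its evaluation

The classifier is a soft-margin C-classification SVM with an RBF kernel;
the quadratic-programming core is delegated to libsvm via `e1071`, while
tuning, cross-validation, metrics and serialisation are implemented here.
Features are standardised inside the SVM by default. Tuning evaluates a
fixed grid (cost in {0.1, 1, 10, 100}, gamma in {0.01, 0.11, 1.11,
1/n_features}) with every point seeing identical fold draws; ties prefer
the smaller cost, then the smaller gamma. The tuning record also stores an
`epsilon` field for fidelity with the original toolchain's reports, but it
is inert: epsilon parametrises regression SVMs, not classification.

Cross-validation is stratified, repeated, and pooled: metrics are computed
over all held-out predictions of all repeats rather than averaged over
folds, which keeps small-fold ratios well-defined. With `k = n` it reduces
exactly to leave-one-out, which the tests verify by explicit enumeration.
Undefined diagnostic ratios (empty denominators) are reported as `NA`,
never silently as zero. AUC is the rank-based Mann-Whitney area over
decision values when they exist; from hard labels it equals
(sensitivity + specificity)/2.

Trained classifiers serialise to a single JSON artifact carrying the
selected m/z panel, the complete decision-function state (support vectors,
dual coefficients, offset, feature scaling, orientation), and the full
preprocessing/alignment provenance plus a configuration hash and seed, so
a restored model can score raw imzML data bit-compatibly with the original
fit.

## Pixel-by-pixel classification

For an unknown smear the pipeline preprocesses every pixel with the
training configuration, picks peaks per pixel, applies a *dataset-wide*
presence filter across the smear's own pixels at the training threshold
(discarding the false positives S/N picking produces on single spectra),
aligns each pixel's surviving peaks to the model's references
(nearest peak within the ppm window; ties to the higher intensity),
backfills undetected model features from the pixel's preprocessed spectrum
— the same rule the training matrix used, without which every pixel would
sit systematically below the training intensity scale — and scores the
resulting vectors. Pixels with degenerate TIC are rendered
unclassified; pixels whose feature vector is all zero are still classified,
because the decision function is defined at the origin and silently
dropping them would bias area fractions.

## The synthetic cohort generator

No MSI data are shipped or downloaded; the generator produces cohorts with
the statistical structure the analysis assumes, so every stage is testable
against known ground truth:

* Gaussian peaks whose width grows with m/z (sigma = 1000 ppm), on an
  exponentially decaying chemical baseline, with additive Gaussian noise,
  per-spectrum log-normal TIC variation (sigma 0.3), and per-spectrum peak
  position jitter (300 ppm) that exercises the 2000 ppm alignment.
* 30 shared peaks plus 10 discriminative peaks whose log-amplitudes differ
  between classes by `effect_size * amp_sdlog`; the planted directions
  alternate (half up, half down in PTC) so that total ion current carries
  as little trivial class signal as possible.
* Amplitude variation on two levels: pixel-to-pixel within a patient
  (sdlog 0.4) and patient-to-patient within a class (sdlog 0.6). The
  between-patient level is set above the within-patient level — smear
  cellularity and preparation vary more between patients than across one
  smear — and it is the level that limits patient-profile classification.
  `effect_size` is defined per spectrum: an effect of 3 means the class
  means of a discriminative peak differ by three within-patient standard
  deviations of log-amplitude.
* Malignant smears are pixel mixtures: by default 80% of a malignant
  patient's pixels carry the malignant signature in a contiguous raster
  block, the rest look benign, which both dilutes patient profiles
  realistically and gives pixel maps a planted region with known area.
* Cohort sizes default to the study design the package mirrors: 14 benign
  + 18 malignant training patients and an 11-patient (8 benign / 3
  malignant) undetermined validation batch; tests and the acceptance
  script use 10 + 10 patients at 50 pixels each so the full pipeline runs
  in a few minutes on one CPU.

What the generator does *not* emulate: isotope envelopes, detector
saturation, matrix crystallisation artefacts, spatially correlated noise,
and m/z-dependent resolution changes beyond the ppm width model. Passing
tests therefore demonstrate the pipeline's statistical and numerical
correctness on data with the assumed structure, not instrument-level
realism.

Because TIC normalisation couples peaks (a composition), planted
"discriminative" and "shared" labels are not perfectly clean after
preprocessing: raising some peaks in one class slightly depresses all
others. The alternating effect directions keep this leakage small, but on
cohorts of twenty patients the importance ranking of a genuinely
informative peak and a shared peak carrying leaked signal can overlap;
recovery of the planted panel is therefore a statistical outcome, not a
certainty, and the test suite treats it as such.

## Numerical and degenerate-input policy

* S/N threshold inclusive; presence threshold inclusive ("at least").
* Importance ties break by ascending m/z; size ties by smallest size;
  tuning ties by smaller cost then gamma; nearest-peak ties by higher
  intensity. Every stochastic stage threads one integer seed.
* Zero-TIC spectra: typed error, skippable per pixel. The baseline step
  snaps sub-machine-precision residuals to exact zero (64 eps relative to
  the local signal) so that a featureless spectrum reliably reaches the
  degenerate-TIC path instead of surviving on rounding crumbs. Empty peak lists are
  legal everywhere. Constant spectra smooth to themselves and open to zero.
* imzML I/O supports 32/64-bit uncompressed floats, continuous and
  processed dialects; writing is deterministic (the ibd UUID derives from
  an md5 of the payload) and always 64-bit so round-trips are exact.

## Limitations

The pipeline is binary by design (the undetermined-category triage
problem); multiclass staging, probability calibration and ensemble voting
are out of scope. Alignment is a single greedy pass with one global
tolerance; no per-spectrum recalibration is attempted. The SVM state is
portable but the stored model does not re-optimise the decision threshold
for new class priors.
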