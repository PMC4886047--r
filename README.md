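# msiclass

Diagnostic classification of MALDI mass spectrometry imaging (MSI) data.

Thyroid nodules are triaged by fine-needle aspiration cytology into SIAPEC
categories THY1-THY5. The undetermined category (THY3) is the clinical pain
point: most of these lesions prove benign at histology, yet they are
routinely resected. `msiclass` is for proteomics/bioinformatics groups who
want to build and validate machine-learning classifiers that read the
molecular profile of a smear directly from MALDI-MSI data cubes — one mass
spectrum per 100 µm pixel, m/z 3000-25000 — and predict benign (Ben) versus
papillary thyroid carcinoma (PTC), both per patient and per pixel.

## The method

For spectra $s_i$ with intensities $I_i(m)$ the pipeline computes:

1. **Preprocessing** — Savitzky-Golay smoothing (local least-squares
   polynomial, order 3, 21-point window); TopHat baseline subtraction
   (morphological opening with a flat 151-point structuring element,
   residual clipped at 0); TIC normalisation
   $I \leftarrow I \cdot T/\sum_m I(m)$ so every spectrum has the same
   integrated area.
2. **Peak extraction** — noise $\hat\sigma = 1.4826\,\mathrm{med}\,
   |I - \mathrm{med}\,I|$ (MAD); peaks are unique local maxima with
   $I \ge 3\hat\sigma$; peaks are aligned across spectra with a 2000 ppm
   tolerance (greedy gap clustering, intensity-weighted reference m/z) and
   references present in fewer than 25% of spectra are discarded; the
   result is the peak-list matrix $X \in \mathbb{R}^{n \times p}$.
3. **Feature selection** — recursive feature elimination scored by a
   two-class PLS model (NIPALS, Ben = +1, PTC = −1, importance =
   |regression coefficient| on autoscaled predictors) under 2× stratified
   10-fold cross-validation; the subset size maximising CV accuracy is
   selected (ties to the smallest).
4. **Classification** — an RBF-kernel SVM
   $f(x) = \sum_j \alpha_j K(x_j, x) - \rho$,
   $K(u,v) = e^{-\gamma\|u-v\|^2}$, grid-tuned over cost and gamma,
   assessed by repeated CV and on an external validation cohort with
   accuracy, sensitivity, specificity, PPV, NPV and ROC AUC (positive
   class: Ben).
5. **Pixel maps** — the trained model applied to every pixel of an unknown
   smear after identical preprocessing, per-smear presence filtering and
   alignment of each pixel's peaks to the model's reference m/z panel.

A synthetic-cohort generator with known ground truth (shared and
discriminative Gaussian peaks, decaying baseline, TIC variation, ppm
jitter, mixed-pixel malignant smears) stands in for protected clinical
data, so the whole pipeline is testable end to end. See
`vignettes/msi-classification.Rmd` for the full methodological account.

## Worked example

The package ships the 11-patient external-validation worked example (an
undetermined-cytology batch with post-surgical histological truth; two
benign patients are predicted malignant):

```r
library(msiclass)
we <- generate_worked_example()
compute_metrics(we$predicted, we$true, positive_class = "Ben")
```

```
<performance_report> n = 11, positive class = Ben
         truth
predicted Ben PTC
      Ben   6   0
      PTC   2   3
accuracy 0.818 | sensitivity 0.750 | specificity 1.000 | PPV 1.000 | NPV 0.600 | AUC 0.875
```

Read: of 8 truly benign patients 6 are recognised (sensitivity 0.750 for
detecting benignity), no malignant lesion is called benign (specificity
1.000, PPV 1.000), and the hard-label ROC area is 0.875.

A full synthetic run:

```r
spec  <- cohort_spec(n_benign = 10, n_malignant = 10,
                     pixels_per_patient = 50, effect_size = 3, seed = 1)
study <- generate_study(spec, 8, 3)          # train + THY3-style validation
fit   <- run_training(study$train$dataset, pipeline_config(seed = 1))
val   <- run_validation(fit$classifier, study$validation$dataset)
cm    <- classify_pixels(study$validation$dataset, fit$classifier)
render_map(cm, "map.png")
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/msiclass.R` (subcommands `simulate`, `train`, `validate`,
`classify-pixels`).

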