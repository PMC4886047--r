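# Shared fixtures, built in code at test time.

# A smooth synthetic spectrum: Gaussian peaks + decaying baseline (+ noise).
make_peak_spectrum <- function(centers = c(3500, 4200), amps = c(50, 30),
                               sigma = 15, baseline = 20, noise_sd = 0,
                               mz = seq(3000, 5000, by = 1),
                               x = 1L, y = 1L, patient_id = "P01") {
  int <- baseline * exp(-(mz - min(mz)) / 2000)
  for (i in seq_along(centers)) {
    int <- int + amps[i] * exp(-(mz - centers[i])^2 / (2 * sigma^2))
  }
  if (noise_sd > 0) int <- int + rnorm(length(mz), 0, noise_sd)
  mass_spectrum(mz, int, x = x, y = y, patient_id = patient_id)
}

# Two well-separated Gaussian point clouds in feature space.
make_separable_xy <- function(n_per_class = 10, p = 2, delta = 5,
                              sd = 0.5, seed = 42) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * p, delta, sd), n_per_class, p),
             matrix(rnorm(n_per_class * p, -delta, sd), n_per_class, p))
  colnames(X) <- sprintf("f%d", seq_len(p))
  list(X = X, y = rep(c("Ben", "PTC"), each = n_per_class))
}

# Brute-force morphological opening (max of min over explicit windows),
# the independent oracle for the TopHat baseline.
brute_opening <- function(x, hw) {
  n <- length(x)
  ero <- vapply(seq_len(n), function(i) {
    min(x[max(1, i - hw):min(n, i + hw)])
  }, numeric(1))
  vapply(seq_len(n), function(i) {
    max(ero[max(1, i - hw):min(n, i + hw)])
  }, numeric(1))
}

# A small trained pipeline shared across pixel-map and pipeline tests
# (built lazily once per test run).
.fixture_cache <- new.env(parent = emptyenv())
fixture_small_model <- function() {
  if (!is.null(.fixture_cache$model)) return(.fixture_cache$model)
  spec <- cohort_spec(n_benign = 6, n_malignant = 6, pixels_per_patient = 12,
                      seed = 11)
  study <- generate_study(spec, 4, 2)
  config <- pipeline_config(folds = 5, repeats = 2, seed = 11)
  training <- run_training(study$train$dataset, config)
  .fixture_cache$model <- list(study = study, config = config,
                               training = training)
  .fixture_cache$model
}
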