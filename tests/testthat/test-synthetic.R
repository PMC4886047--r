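# Synthetic cohort generator

test_that("cohort dimensions and determinism", {
  spec <- cohort_spec(n_benign = 2, n_malignant = 2, pixels_per_patient = 5,
                      seed = 31)
  co <- generate_cohort(spec)
  expect_length(co$dataset$spectra, 20L)
  expect_identical(nrow(co$dataset$metadata), 4L)
  expect_identical(sort(table(co$dataset$metadata$histological_class),
                        decreasing = TRUE),
                   sort(table(c("Ben", "Ben", "PTC", "PTC")),
                        decreasing = TRUE))
  expect_identical(nrow(co$truth$pixels), 20L)

  co2 <- generate_cohort(spec)
  expect_identical(co, co2)

  spec2 <- cohort_spec(n_benign = 2, n_malignant = 2, pixels_per_patient = 5,
                       seed = 32)
  expect_false(identical(generate_cohort(spec2)$dataset, co$dataset))
})

test_that("spec validation rejects nonsense", {
  expect_error(cohort_spec(mz_range = c(5000, 3000)), "increasing")
  expect_error(cohort_spec(pixels_per_patient = 0), "pixels_per_patient")
  expect_error(cohort_spec(malignant_pixel_fraction = 1.2), "fraction")
  expect_error(cohort_spec(mz_step = -1), "positive")
})

test_that("malignant smears contain the planted benign-pixel admixture", {
  spec <- cohort_spec(n_benign = 1, n_malignant = 1, pixels_per_patient = 20,
                      malignant_pixel_fraction = 0.3, seed = 33)
  co <- generate_cohort(spec)
  px <- co$truth$pixels
  mal <- px[grepl("^MAL", px$patient_id), ]
  expect_equal(mean(mal$latent_class == "PTC"), 0.3)
  ben <- px[grepl("^BEN", px$patient_id), ]
  expect_true(all(ben$latent_class == "Ben"))
})

test_that("planted peaks are recovered with sub-jitter error in the
           near-noiseless regime", {
  spec <- cohort_spec(n_benign = 2, n_malignant = 2, pixels_per_patient = 3,
                      noise_sd = 1e-4, tic_lognormal_sd = 0,
                      mz_jitter_ppm = 100, baseline_amplitude = 5,
                      seed = 34)
  co <- generate_cohort(spec)
  cfg <- preprocess_config()
  lists <- lapply(co$dataset$spectra, function(s) {
    pick_peaks(preprocess_spectrum(s, cfg))
  })
  ap <- filter_peaks(align_peaks(lists, 2000), 0.25)
  planted <- co$truth$peaks$mz
  err_ppm <- vapply(planted, function(m) {
    1e6 * min(abs(ap$reference_mz - m)) / m
  }, numeric(1))
  # every planted peak has an aligned reference within the jitter scale
  # (plus sampling-grid quantisation of about half a 3 Th step)
  expect_lt(max(err_ppm), 100 + 200)
})

test_that("TIC normalisation removes the planted multiplicative
           variation", {
  spec <- cohort_spec(n_benign = 4, n_malignant = 0, pixels_per_patient = 8,
                      patient_sdlog = 0, tic_lognormal_sd = 0.3, seed = 35)
  co <- generate_cohort(spec)
  cfg <- preprocess_config()
  pre <- lapply(co$dataset$spectra, smooth_savitzky_golay, cfg = cfg)
  pre <- lapply(pre, subtract_baseline_tophat, cfg = cfg)
  post <- lapply(pre, normalize_tic, cfg = cfg)
  peak_mz <- co$truth$peaks$mz
  cv <- function(spectra) {
    vals <- vapply(spectra, function(s) {
      vapply(peak_mz, function(m) {
        idx <- which(abs(s$mz - m) < 30)
        max(s$intensity[idx])
      }, numeric(1))
    }, numeric(length(peak_mz)))
    mean(apply(vals, 1, function(v) sd(v) / mean(v)))
  }
  expect_lt(cv(post), cv(pre))
})

test_that("training and validation cohorts of a study share the peak
           panel", {
  spec <- cohort_spec(n_benign = 2, n_malignant = 2, pixels_per_patient = 3,
                      seed = 36)
  study <- generate_study(spec, 2, 1)
  expect_identical(study$train$truth$peaks$mz,
                   study$validation$truth$peaks$mz)
  expect_true(all(study$validation$dataset$metadata$cytological_class ==
                    "THY3"))
  expect_identical(nrow(study$validation$dataset$metadata), 3L)
  # distinct patient draws
  expect_false(identical(study$train$dataset$spectra[[1]]$intensity,
                         study$validation$dataset$spectra[[1]]$intensity))
})

test_that("the worked-example fixture has the published composition", {
  we <- generate_worked_example()
  expect_identical(nrow(we), 11L)
  expect_identical(sum(we$predicted != we$true), 2L)
  disagreements <- we$sample_id[we$predicted != we$true]
  expect_setequal(disagreements, c("Patient #20", "Patient #41"))
  expect_identical(as.integer(table(we$true)[c("Ben", "PTC")]), c(8L, 3L))
})

test_that("feature selection tracks the planted effect size", {
  # with no planted effect the selected panel hits the discriminative-peak
  # ground truth only at chance level; with a planted effect it does
  # substantially better (averaged over a few generator seeds; everything
  # here is deterministic for the fixed seeds)
  recovery <- function(effect, sd) {
    spec <- cohort_spec(n_benign = 6, n_malignant = 6,
                        pixels_per_patient = 8, effect_size = effect,
                        seed = sd)
    co <- generate_cohort(spec)
    cfg <- pipeline_config()
    pp <- preprocess_dataset(co$dataset, cfg$preprocess)
    ids <- co$dataset$metadata$patient_id
    profiles <- lapply(ids, function(p) average_patient_profile(pp, p))
    names(profiles) <- ids
    lists <- lapply(ids, function(p) {
      pick_peaks(profiles[[p]], cfg$peaks, source_id = p)
    })
    ap <- filter_peaks(align_peaks(lists, cfg$tolerance_ppm),
                       cfg$min_presence)
    pm <- build_peak_matrix(ap, spectra = profiles, backfill = TRUE)
    y <- training_labels(co$dataset$metadata)[pm$sample_ids]
    res <- rfe(pm$values, y, sizes = c(10, 5, 2), k = 6, repeats = 2,
               seed = sd)
    planted <- co$truth$peaks$mz[co$truth$peaks$discriminative]
    mean(vapply(planted, function(m) {
      any(abs(res$selected_mz - m) / m < 2000e-6)
    }, logical(1)))
  }
  seeds <- 37:40
  null_recovery <- mean(vapply(seeds, recovery, numeric(1), effect = 0))
  alt_recovery <- mean(vapply(seeds, recovery, numeric(1), effect = 3))
  expect_lte(null_recovery, 0.4)
  expect_gt(alt_recovery, null_recovery)
})
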