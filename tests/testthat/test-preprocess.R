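# Savitzky-Golay smoothing, TopHat baseline, TIC normalisation

test_that("Savitzky-Golay leaves constants unchanged and reproduces
           polynomials up to the fit order", {
  mz <- seq_len(200) + 3000
  const <- mass_spectrum(mz, rep(7, 200))
  for (cfg in list(preprocess_config(savgol_half_window = 5,
                                     savgol_polyorder = 2),
                   preprocess_config(savgol_half_window = 12,
                                     savgol_polyorder = 0))) {
    expect_equal(smooth_savitzky_golay(const, cfg)$intensity,
                 rep(7, 200), tolerance = 1e-12)
  }
  # quadratic q(i) = 2 + 3 i + i^2 reproduced exactly with polyorder 2,
  # including the truncated-window edges
  i <- seq_len(120)
  quad <- mass_spectrum(i + 3000, 2 + 3 * i + i^2)
  cfg <- preprocess_config(savgol_half_window = 7, savgol_polyorder = 2)
  out <- smooth_savitzky_golay(quad, cfg)
  expect_lt(max(abs(out$intensity - (2 + 3 * i + i^2))), 1e-9)
  expect_identical(out$mz, quad$mz)
})

test_that("Savitzky-Golay matches a sliding-window least-squares oracle", {
  set.seed(7)
  n <- 101
  s <- mass_spectrum(seq_len(n) + 4000, rnorm(n, 50, 10))
  hw <- 5L
  p <- 3L
  out <- smooth_savitzky_golay(
    s, preprocess_config(savgol_half_window = hw, savgol_polyorder = p))
  # oracle: ordinary least squares cubic in every full window, evaluated at
  # the centre via lm()
  for (i in seq(hw + 1L, n - hw)) {
    idx <- (i - hw):(i + hw)
    fit <- lm(y ~ poly(t, p, raw = TRUE),
              data = data.frame(t = idx - i, y = s$intensity[idx]))
    expect_equal(out$intensity[i], unname(coef(fit)[1]), tolerance = 1e-8)
  }
  # edge oracle: same fit on the truncated window
  for (i in c(1L, 3L, n - 2L, n)) {
    idx <- max(1L, i - hw):min(n, i + hw)
    fit <- lm(y ~ poly(t, p, raw = TRUE),
              data = data.frame(t = idx - i, y = s$intensity[idx]))
    expect_equal(out$intensity[i], unname(coef(fit)[1]), tolerance = 1e-8)
  }
})

test_that("smoothing rejects windows longer than the spectrum", {
  s <- mass_spectrum(1:15 + 3000, rnorm(15))
  expect_error(
    smooth_savitzky_golay(s, preprocess_config(savgol_half_window = 8)),
    "not shorter")
})

test_that("TopHat flattens constants and recovers isolated narrow peaks
           exactly", {
  const <- mass_spectrum(1:50 + 3000, rep(4.2, 50))
  cfg <- preprocess_config(tophat_half_window = 5)
  expect_equal(subtract_baseline_tophat(const, cfg)$intensity, rep(0, 50))

  # flat baseline + one peak narrower than the structuring element: the
  # opening equals the baseline, so the residual is exactly the peak
  int <- rep(3, 21)
  int[10:12] <- 3 + c(5, 9, 5)
  s <- mass_spectrum(1:21 + 3000, int)
  out <- subtract_baseline_tophat(s, preprocess_config(tophat_half_window = 4))
  expected <- rep(0, 21)
  expected[10:12] <- c(5, 9, 5)
  expect_equal(out$intensity, expected)
})

test_that("TopHat equals the brute-force min/max opening oracle", {
  set.seed(8)
  x <- abs(rnorm(200, 10, 5)) + seq(20, 1, length.out = 200)
  s <- mass_spectrum(seq_len(200) + 3000, x)
  for (hw in c(3L, 11L, 40L)) {
    out <- subtract_baseline_tophat(
      s, preprocess_config(tophat_half_window = hw))
    expect_equal(out$intensity, pmax(x - brute_opening(x, hw), 0))
  }
})

test_that("opening is idempotent and anti-extensive", {
  set.seed(9)
  cfg <- preprocess_config(tophat_half_window = 10)
  for (rep in 1:5) {
    x <- abs(rnorm(150, 20, 8))
    s <- mass_spectrum(seq_len(150) + 3000, x)
    once <- subtract_baseline_tophat(s, cfg)
    twice <- subtract_baseline_tophat(once, cfg)
    expect_lt(max(abs(twice$intensity - once$intensity)), 1e-12)
    # baseline never exceeds the signal => residual within [0, x]
    expect_true(all(once$intensity >= 0))
    expect_true(all(once$intensity <= x + 1e-12))
  }
})

test_that("TIC normalisation scales to the target and is scale-invariant", {
  cfg <- preprocess_config(tic_target = 1)
  s <- mass_spectrum(1:4 + 3000, c(1, 2, 3, 4))
  expect_equal(normalize_tic(s, cfg)$intensity, c(0.1, 0.2, 0.3, 0.4))

  const <- mass_spectrum(1:25 + 3000, rep(3, 25))
  expect_equal(normalize_tic(const, cfg)$intensity, rep(1 / 25, 25))

  zero <- mass_spectrum(1:10 + 3000, rep(0, 10))
  expect_error(normalize_tic(zero, cfg), "degenerate",
               class = "msiclass_degenerate_spectrum")

  set.seed(10)
  r <- mass_spectrum(1:30 + 3000, runif(30, 0, 5))
  for (k in c(0.01, 3, 1e6)) {
    scaled <- mass_spectrum(r$mz, r$intensity * k)
    expect_equal(normalize_tic(scaled, cfg)$intensity,
                 normalize_tic(r, cfg)$intensity, tolerance = 1e-12)
  }
})

test_that("the pipeline is the composition smooth -> baseline -> TIC", {
  set.seed(11)
  s <- make_peak_spectrum(noise_sd = 1)
  cfg <- preprocess_config()
  manual <- normalize_tic(
    subtract_baseline_tophat(smooth_savitzky_golay(s, cfg), cfg), cfg)
  piped <- preprocess_spectrum(s, cfg)
  expect_identical(piped$intensity, manual$intensity)
  expect_equal(sum(piped$intensity), cfg$tic_target, tolerance = 1e-9)
  expect_identical(piped$patient_id, s$patient_id)
  expect_identical(c(piped$x, piped$y), c(s$x, s$y))

  # a constant spectrum loses everything to the baseline: degenerate
  const <- mass_spectrum(1:300 + 3000, rep(5, 300))
  expect_error(preprocess_spectrum(const, cfg),
               class = "msiclass_degenerate_spectrum")
})

test_that("preprocess_dataset can drop degenerate pixels on request", {
  good <- make_peak_spectrum(x = 1L)
  flat <- mass_spectrum(good$mz, rep(1, length(good$mz)), x = 2L)
  ds <- msi_dataset(list(good, flat))
  cfg <- preprocess_config()
  expect_error(preprocess_dataset(ds, cfg),
               class = "msiclass_degenerate_spectrum")
  expect_warning(out <- preprocess_dataset(ds, cfg, on_degenerate = "drop"),
                 "degenerate")
  expect_length(out$spectra, 1L)
})
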