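# MAD noise, peak picking, alignment, filtering, peak matrix, averaging

test_that("MAD noise matches direct evaluation of the formula", {
  cfg <- peak_pick_config()
  s <- mass_spectrum(1:5 + 3000, c(1, 2, 3, 4, 100))
  # median 3, |dev| = {2,1,0,1,97}, median 1 -> 1.4826
  expect_equal(estimate_noise_mad(s, cfg), 1.4826)

  expect_equal(estimate_noise_mad(mass_spectrum(1:9 + 3000, rep(2, 9)), cfg),
               0)
  expect_equal(estimate_noise_mad(mass_spectrum(1:5 + 3000, 0:4), cfg),
               1 * 1.4826)
  # alternative consistency constant is honoured
  expect_equal(estimate_noise_mad(mass_spectrum(1:5 + 3000, 0:4),
                                  peak_pick_config(mad_scale = 1)), 1)
})

test_that("peak picking finds exactly the planted apexes", {
  mz <- seq(3000, 4000, by = 1)
  int <- 10 * exp(-(mz - 3500)^2 / (2 * 10^2))
  s <- mass_spectrum(mz, int)
  pl <- pick_peaks(s, peak_pick_config())
  expect_identical(pl$mz, 3500)
  expect_equal(pl$intensity, 10)

  # everything below the S/N threshold: empty list is legal
  # (uniform intensities: max = 1 < 3 * MAD = 3 * 1.4826 * 0.25)
  set.seed(12)
  noise <- mass_spectrum(mz, runif(length(mz)))
  expect_lt(max(noise$intensity),
            3 * estimate_noise_mad(noise, peak_pick_config()))
  expect_length(pick_peaks(noise, peak_pick_config())$mz, 0L)
  flat <- mass_spectrum(1:100 + 3000, rep(c(1, 1.001), 50))
  expect_length(pick_peaks(flat, peak_pick_config())$mz, 0L)
})

test_that("the S/N threshold is inclusive", {
  # background with hand-computable MAD: values alternate 0 and 2 around
  # median 1, so every absolute deviation is 1 and MAD = 1.4826
  n <- 400
  int <- rep(c(0, 2), length.out = n)
  noise_oracle <- 1.4826 * 1
  # plant three isolated peaks at S/N {2, 3, 10} (heights relative to the
  # oracle noise); peaks are rare enough not to move the medians
  apex <- c(100, 200, 300)
  snr <- c(2, 3, 10)
  int[apex] <- snr * noise_oracle
  s <- mass_spectrum(seq_len(n) + 5000, int)
  cfg <- peak_pick_config(snr_threshold = 3, halfwindow_local_max = 10)
  expect_equal(estimate_noise_mad(s, cfg), noise_oracle)
  pl <- pick_peaks(s, cfg)
  # S/N 3 kept (inclusive), S/N 2 rejected
  expect_identical(pl$mz, apex[2:3] + 5000)
})

test_that("alignment groups peaks by the ppm gap rule", {
  # 10 Th apart at 10 kTh: inside a 2000 ppm (20 Th) window -> one reference
  a <- peak_list("s1", 10000.0, 5)
  b <- peak_list("s2", 10010.0, 15)
  ap <- align_peaks(list(a, b), 2000)
  expect_length(ap$reference_mz, 1L)
  expect_identical(ap$support, 2L)
  # intensity-weighted mean reference
  expect_equal(ap$reference_mz, (10000 * 5 + 10010 * 15) / 20)

  # 30 Th apart: beyond the window -> two references
  b2 <- peak_list("s2", 10030.0, 15)
  ap2 <- align_peaks(list(a, b2), 2000)
  expect_length(ap2$reference_mz, 2L)

  # single list: identity relabelling
  pl <- peak_list("only", c(4000, 5000, 6000), c(1, 2, 3))
  ap3 <- align_peaks(list(pl), 2000)
  expect_equal(ap3$reference_mz, pl$mz)
  expect_equal(ap3$peaks$ref, 1:3)
})

test_that("groups with two peaks from one source are split at the largest
           internal gap", {
  # both s1 peaks fall into one 2000 ppm chain together with s2's peak
  s1 <- peak_list("s1", c(10000, 10012), c(5, 5))
  s2 <- peak_list("s2", 10005, 8)
  ap <- align_peaks(list(s1, s2), 2000)
  expect_length(ap$reference_mz, 2L)
  by_ref <- split(ap$peaks$source, ap$peaks$ref)
  expect_true(all(vapply(by_ref, anyDuplicated, integer(1)) == 0L))
})

test_that("alignment respects tolerance bounds on random inputs", {
  set.seed(13)
  for (rep in 1:20) {
    n_src <- sample(2:5, 1)
    lists <- lapply(seq_len(n_src), function(i) {
      mz <- sort(runif(sample(3:12, 1), 4000, 20000))
      # enforce within-list strict increase with a margin
      mz <- mz[c(TRUE, diff(mz) > 1)]
      peak_list(sprintf("s%d", i), mz, runif(length(mz), 1, 10))
    })
    tol <- 2000
    ap <- align_peaks(lists, tol)
    # pooled peaks merged into one reference are chain-connected within
    # tolerance: exhaustive pairwise check over consecutive members
    for (g in split(ap$peaks, ap$peaks$ref)) {
      if (nrow(g) > 1L) {
        gap <- diff(sort(g$mz))
        lim <- tol * 1e-6 * sort(g$mz)[-1]
        expect_true(all(gap <= lim))
      }
      expect_identical(anyDuplicated(g$source), 0L)
    }
    # matrix shape contract
    pm <- build_peak_matrix(ap)
    expect_identical(nrow(pm$values), n_src)
    expect_identical(ncol(pm$values), length(ap$reference_mz))
    # references strictly increasing
    expect_true(all(diff(ap$reference_mz) > 0))
  }
})

test_that("presence filtering is inclusive at the boundary and monotone", {
  set.seed(14)
  # 100 sources; one reference present in exactly 25, another in 1
  lists <- lapply(1:100, function(i) {
    mz <- numeric(0)
    if (i <= 25) mz <- c(mz, 8000)
    if (i == 50) mz <- c(mz, 12000)
    peak_list(sprintf("s%03d", i), mz, rep(1, length(mz)))
  })
  ap <- align_peaks(lists, 2000)
  expect_length(ap$reference_mz, 2L)
  kept <- filter_peaks(ap, 0.25)
  expect_equal(kept$reference_mz, 8000)   # 25/100 kept: "at least" 25%
  expect_length(filter_peaks(ap, 0.26)$reference_mz, 0L)

  # min_presence = 1 keeps a universal reference
  all_lists <- lapply(1:10, function(i) {
    peak_list(sprintf("t%d", i), 9000, 2)
  })
  apu <- align_peaks(all_lists, 2000)
  expect_length(filter_peaks(apu, 1)$reference_mz, 1L)

  # monotone non-increasing retention in min_presence
  rand_lists <- lapply(1:20, function(i) {
    mz <- sort(sample(seq(4000, 20000, by = 400), sample(2:8, 1)))
    peak_list(sprintf("r%d", i), mz, runif(length(mz), 1, 5))
  })
  apr <- align_peaks(rand_lists, 2000)
  sizes <- vapply(c(0.05, 0.25, 0.5, 0.75, 1),
                  function(f) length(filter_peaks(apr, f)$reference_mz),
                  integer(1))
  expect_true(all(diff(sizes) <= 0))
  # near-zero threshold is the identity on references seen at least once
  expect_length(filter_peaks(apr, 1e-9)$reference_mz,
                length(apr$reference_mz))
})

test_that("the peak matrix records detections and backfills from spectra", {
  a <- peak_list("A", c(5000, 9000), c(2, 3))
  b <- peak_list("B", 5001, 4)
  ap <- align_peaks(list(a, b), 2000)
  expect_length(ap$reference_mz, 2L)

  pm0 <- build_peak_matrix(ap)
  expect_equal(unname(pm0$values["B", 2]), 0)      # missing, no backfill
  expect_true(pm0$presence["A", 2])
  expect_false(pm0$presence["B", 2])
  expect_equal(unname(pm0$values["A", 1]), 2)

  # backfill reads the maximum intensity inside the tolerance window
  mzb <- seq(4500, 9500, by = 1)
  intb <- rep(0.5, length(mzb))
  intb[mzb >= 8990 & mzb <= 9010] <- 1.25
  spectra <- list(A = make_peak_spectrum(),
                  B = mass_spectrum(mzb, intb, patient_id = "B"))
  pm1 <- build_peak_matrix(ap, spectra = spectra, backfill = TRUE)
  expect_equal(unname(pm1$values["B", 2]), 1.25)
  expect_false(pm1$presence["B", 2])

  expect_error(build_peak_matrix(ap, spectra = list(), backfill = TRUE),
               "no spectrum supplied for source B")
})

test_that("patient average profiles are pointwise means", {
  mz <- seq(3000, 3010, 1)
  p1 <- mass_spectrum(mz, c(0, 2, rep(1, 9)), 1, 1, "P")
  p2 <- mass_spectrum(mz, c(2, 0, rep(1, 9)), 2, 1, "P")
  ds <- msi_dataset(list(p1, p2))
  avg <- average_patient_profile(ds, "P")
  expect_equal(avg$intensity[1:2], c(1, 1))
  expect_identical(avg$patient_id, "P")

  same <- msi_dataset(list(p1, mass_spectrum(mz, p1$intensity, 2, 1, "P")))
  expect_equal(average_patient_profile(same, "P")$intensity, p1$intensity)

  # 50 random pixels against an independent summation oracle
  set.seed(15)
  mats <- matrix(runif(50 * 11), 50, 11)
  pix <- lapply(1:50, function(i) {
    mass_spectrum(mz, mats[i, ], x = i, y = 1L, patient_id = "Q")
  })
  avg50 <- average_patient_profile(msi_dataset(pix), "Q")
  oracle <- colSums(mats) / 50
  expect_lt(max(abs(avg50$intensity - oracle)), 1e-12)

  expect_error(average_patient_profile(ds, "nobody"), "no spectra")
})

test_that("noiseless multi-peak spectra are recovered apex-exact through
           pick + align", {
  mz <- seq(3000, 20000, by = 2)
  centers <- c(5000, 9000, 15000)
  int <- rowSums(vapply(centers, function(cc) {
    40 * exp(-(mz - cc)^2 / (2 * (0.001 * cc)^2))
  }, numeric(length(mz))))
  s <- mass_spectrum(mz, int)
  pl <- pick_peaks(s, peak_pick_config())
  expect_identical(pl$mz, centers)
})
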