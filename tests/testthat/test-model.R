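# SVM training, tuning, cross-validation, prediction, serialisation

test_that("separable clusters are fitted perfectly", {
  d <- make_separable_xy()
  clf <- train_svm(d$X, d$y, svm_config(cost = 10, gamma = 0.11))
  pred <- predict(clf, d$X)
  expect_identical(pred$label, d$y)
  # Ben points sit on the positive side of the oriented decision values
  expect_true(all(pred$decision[d$y == "Ben"] > 0))
  expect_true(all(pred$decision[d$y == "PTC"] < 0))
})

test_that("the radial kernel separates XOR", {
  X <- rbind(c(1, 1), c(-1, -1), c(1, -1), c(-1, 1))
  colnames(X) <- c("f1", "f2")
  y <- c("Ben", "Ben", "PTC", "PTC")
  clf <- train_svm(X, y, svm_config(cost = 10, gamma = 1))
  expect_identical(predict(clf, X)$label, y)

  # reference solver agrees on the training labels
  skip_if_not_installed("kernlab")
  ref <- kernlab::ksvm(X, factor(y), type = "C-svc", kernel = "rbfdot",
                       kpar = list(sigma = 1), C = 10, scaled = FALSE)
  expect_identical(as.character(kernlab::predict(ref, X)), y)
})

test_that("duplicating every training point leaves decision values
           unchanged", {
  d <- make_separable_xy(n_per_class = 6, delta = 3, seed = 21)
  cfg <- svm_config(cost = 5, gamma = 0.3, scale = FALSE)
  clf1 <- train_svm(d$X, d$y, cfg)
  clf2 <- train_svm(rbind(d$X, d$X), c(d$y, d$y), cfg)
  grid <- matrix(rnorm(20, 0, 3), 10, 2, dimnames = list(NULL, colnames(d$X)))
  expect_lt(max(abs(predict(clf1, grid)$decision -
                    predict(clf2, grid)$decision)), 1e-8)
})

test_that("prediction validates feature dimensions and names", {
  d <- make_separable_xy()
  clf <- train_svm(d$X, d$y)
  expect_error(predict(clf, d$X[, 1, drop = FALSE]), "dimension mismatch")
  bad <- d$X
  colnames(bad) <- c("f1", "zz")
  expect_error(predict(clf, bad), "missing model features")
  expect_error(train_svm(d$X, rep("Ben", nrow(d$X))), "two training samples")
})

test_that("a serialised classifier restores the identical decision
           function", {
  for (scale in c(TRUE, FALSE)) {
    d <- make_separable_xy(n_per_class = 8, delta = 2, sd = 1, seed = 22)
    clf <- train_svm(d$X, d$y, svm_config(cost = 10, gamma = 0.11,
                                          scale = scale))
    clf$provenance <- list(tolerance_ppm = 2000, min_presence = 0.25,
                           preprocess = unclass(preprocess_config()),
                           peaks = unclass(peak_pick_config()))
    path <- file.path(withr::local_tempdir(), "model.json")
    write_classifier(clf, path)
    back <- read_classifier(path)
    grid <- matrix(rnorm(30, 0, 2), 15, 2,
                   dimnames = list(NULL, colnames(d$X)))
    expect_lt(max(abs(predict(clf, grid)$decision -
                      predict(back, grid)$decision)), 1e-8)
    expect_identical(predict(clf, grid)$label, predict(back, grid)$label)
    expect_equal(back$provenance$tolerance_ppm, 2000)
  }
})

test_that("the portable decision state matches e1071 on the training fit", {
  d <- make_separable_xy(n_per_class = 7, delta = 1.5, sd = 1, seed = 23)
  clf <- train_svm(d$X, d$y, svm_config(cost = 2, gamma = 0.5))
  manual <- msiclass:::.svm_decision(clf$state, d$X)
  expect_lt(max(abs(manual - predict(clf, d$X)$decision)), 1e-8)
})

test_that("tuning picks deterministically, with ties towards smaller
           cost then gamma", {
  d <- make_separable_xy(seed = 24)
  one <- data.frame(cost = 7, gamma = 0.2)
  cfg <- tune_svm(d$X, d$y, grid = one, k = 5, repeats = 1, seed = 1)
  expect_equal(cfg$cost, 7)
  expect_equal(cfg$gamma, 0.2)

  # perfectly separable data: every grid point reaches accuracy 1, so the
  # tie-break must choose the smallest cost, then the smallest gamma
  grid <- expand.grid(cost = c(10, 1), gamma = c(0.11, 1.11))
  cfg2 <- tune_svm(d$X, d$y, grid = grid, k = 5, repeats = 2, seed = 2)
  expect_true(all(cfg2$tuning$accuracy == 1))
  expect_equal(cfg2$cost, 1)
  expect_equal(cfg2$gamma, 0.11)

  cfg3 <- tune_svm(d$X, d$y, grid = grid, k = 5, repeats = 2, seed = 2)
  expect_identical(cfg2$tuning, cfg3$tuning)
  expect_error(tune_svm(d$X, d$y, grid = data.frame()), "empty tuning grid")
})

test_that("cross-validation is reproducible and perfect on separable
           data", {
  d <- make_separable_xy(n_per_class = 10, seed = 25)
  rep1 <- cross_validate(d$X, d$y, svm_config(cost = 10, gamma = 0.11),
                         k = 5, repeats = 2, seed = 9)
  expect_equal(rep1$accuracy, 1)
  rep2 <- cross_validate(d$X, d$y, svm_config(cost = 10, gamma = 0.11),
                         k = 5, repeats = 2, seed = 9)
  expect_identical(metrics_vector(rep1), metrics_vector(rep2))
  expect_identical(rep1$n, 40L)  # pooled over both repeats
})

test_that("k = n cross-validation reduces to leave-one-out", {
  d <- make_separable_xy(n_per_class = 5, delta = 1, sd = 1.2, seed = 26)
  n <- nrow(d$X)
  cfg <- svm_config(cost = 1, gamma = 0.5)
  got <- cross_validate(d$X, d$y, cfg, k = n, repeats = 1, seed = 1)
  # explicit enumeration of all n leave-one-out fits
  pred <- character(n)
  dec <- numeric(n)
  for (i in seq_len(n)) {
    clf <- train_svm(d$X[-i, , drop = FALSE], d$y[-i], cfg)
    p <- predict(clf, d$X[i, , drop = FALSE])
    pred[i] <- p$label
    dec[i] <- p$decision
  }
  oracle <- compute_metrics(pred, d$y, decision_values = dec)
  expect_identical(metrics_vector(got), metrics_vector(oracle))
})

test_that("permuted labels score at chance in cross-validation", {
  set.seed(27)
  X <- matrix(rnorm(24 * 4), 24, 4, dimnames = list(NULL, letters[1:4]))
  y <- rep(c("Ben", "PTC"), 12)
  accs <- vapply(1:20, function(i) {
    yp <- sample(y)
    cross_validate(X, yp, svm_config(cost = 1, gamma = 0.25), k = 4,
                   repeats = 1, seed = i)$accuracy
  }, numeric(1))
  # majority rate 0.5; the mean of 20 permutation runs stays within a few
  # binomial standard errors of it
  se <- sqrt(0.25 / 24) / sqrt(20)
  expect_lt(abs(mean(accs) - 0.5), 6 * se)
})
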