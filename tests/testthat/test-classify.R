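# well-separated Gaussian clouds as a feature set
cloud_set <- function(n_per = 20, dim = 10, gap = 10, sd = 0.5, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * dim, 0, sd), n_per),
             matrix(rnorm(n_per * dim, 0, sd) + gap / sqrt(dim), n_per))
  feature_set(x, rep(c("awake", "anesthetized"), each = n_per),
              window_s = 1, source = "ds")
}

test_that("separable clouds train to zero error and unit AUC", {
  fs <- cloud_set()
  model <- train_svm(fs)
  expect_equal(as.character(predict(model, fs)), as.character(fs$labels))
  rep <- evaluate(fold_protocol(25, seed = 2), fs)
  expect_equal(median(rep$errors_pct), 0)
  expect_equal(rep$auc, 1)
})

test_that("training is deterministic and rejects single-class input", {
  fs <- cloud_set(seed = 5)
  m1 <- train_svm(fs)
  m2 <- train_svm(fs)
  expect_identical(m1$w, m2$w)
  expect_identical(m1$b, m2$b)
  idx <- fs$labels == "awake"
  expect_error(train_svm(fs$vectors[idx, ], fs$labels[idx]),
               "single class")
})

test_that("decision scores are oriented positive-for-anesthetized", {
  fs <- cloud_set(seed = 7)
  model <- train_svm(fs)
  sc <- predict(model, fs, type = "score")
  expect_gt(min(sc[fs$labels == "anesthetized"]), 0)
  expect_lt(max(sc[fs$labels == "awake"]), 0)
})

test_that("fold protocol arithmetic and scheme contracts hold", {
  fs <- cloud_set(n_per = 10)                 # 20 vectors
  p <- fold_protocol(1, train_fraction = 0.5, seed = 3)
  rep <- evaluate(p, fs)
  expect_equal(rep$config$n_train_pool, 20)
  # within_session validates on the held-out half: 10 vectors -> errors in
  # multiples of 10%
  expect_true(all(rep$errors_pct %% 10 == 0))
  expect_error(evaluate(fold_protocol(2, scheme = "cross_session"), fs),
               "requires a validation")
  expect_error(evaluate(fold_protocol(2), fs, cloud_set(seed = 9)),
               "within_session")
})

test_that("ROC curves are monotone, closed, and AUC flips with labels", {
  fs <- cloud_set(n_per = 15, gap = 2, sd = 1, seed = 11)   # overlapping
  rep <- evaluate(fold_protocol(20, seed = 4), fs)
  roc <- rep$roc
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  expect_true(rep$auc >= 0 && rep$auc <= 1)

  # label swap with a fixed score orientation maps AUC to 1 - AUC
  set.seed(12)
  scores <- rnorm(60)
  truth <- ifelse(scores + rnorm(60) > 0, "anesthetized", "awake")
  flipped <- ifelse(truth == "awake", "anesthetized", "awake")
  a1 <- dynstab:::trapezoid_auc(dynstab:::roc_points(scores, truth))
  a2 <- dynstab:::trapezoid_auc(dynstab:::roc_points(scores, flipped))
  expect_equal(a1 + a2, 1, tolerance = 1e-12)
})

test_that("label-permuted training performs at chance", {
  fs <- cloud_set(n_per = 30, seed = 13)
  set.seed(14)
  perm <- feature_set(fs$vectors, sample(as.character(fs$labels)),
                      window_s = 1, source = "ds")
  rep <- evaluate(fold_protocol(40, seed = 15), perm)
  n_valid <- 30                               # held-out half
  half_width <- 2.576 * 50 / sqrt(n_valid)
  expect_gt(median(rep$errors_pct), 50 - half_width)
  expect_lt(median(rep$errors_pct), 50 + half_width)
})

test_that("fold error variability shrinks with training-pool size", {
  mads <- vapply(c(16, 40, 100), function(n_per) {
    fs <- cloud_set(n_per = n_per, gap = 1.2, sd = 1, seed = 17)
    rep <- evaluate(fold_protocol(30, seed = 18), fs)
    mad(rep$errors_pct)
  }, numeric(1))
  expect_true(mads[3] <= mads[1])
})

test_that("performance_vs_window orders DS ahead of FFT on matched spectra", {
  sr <- make_two_state_recording(durations_s = c(20, 20), seed = 19,
                                 n_channels = 8, matched_spectra = TRUE)
  tab <- performance_vs_window(sr$recording, sr$intervals, windows = c(1, 2),
                               sources = c("ds", "fft"), n_per_interval = 8,
                               n_folds = 8, seed = 20)
  expect_equal(nrow(tab), 4L)
  for (w in c(1, 2)) {
    ds <- tab$median_error_pct[tab$window_s == w & tab$source == "ds"]
    ff <- tab$median_error_pct[tab$window_s == w & tab$source == "fft"]
    expect_lt(ds, ff)
  }
})
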