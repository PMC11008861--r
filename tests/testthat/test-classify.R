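test_that("restrict_range keeps the inclusive fingerprint window", {
  sp <- tibble::tibble(shift = seq(200, 2000, by = 2), intensity = rnorm(901))
  r <- restrict_range(sp, 550, 1800)
  expect_gte(min(r$shift), 550)
  expect_lte(max(r$shift), 1800)
  expect_equal(nrow(r), sum(sp$shift >= 550 & sp$shift <= 1800))

  one <- restrict_range(sp, 1004, 1004)
  expect_equal(nrow(one), 1)
  expect_error(restrict_range(sp, 2100, 2200), class = "serds_error_empty")
  expect_error(restrict_range(sp, 1800, 550), class = "serds_error_value")
})

test_that("fit_fold separates well-separated classes and keeps an orthonormal basis", {
  data <- make_gaussian_dataset(20, p = 10, sep = 30)
  X <- as_spectra_matrix(data)
  fm <- fit_fold(X, data$label)
  pr <- predict_fold(fm, X)
  expect_equal(mean(pr$class == data$label), 1)

  gram <- crossprod(fm$rotation)
  expect_lt(max(abs(gram - diag(ncol(gram)))), 1e-8)
  expect_true(all(fm$ev_fraction >= 0))
  expect_lte(sum(fm$ev_fraction), 1 + 1e-8)
  expect_lte(fm$n_components, nrow(X) - 2)

  # duplicating the training set leaves the fitted model unchanged
  fm2 <- fit_fold(rbind(X, X), c(data$label, data$label))
  expect_equal(fm2$mean, fm$mean)
  expect_equal(unname(abs(diag(crossprod(fm2$rotation, fm$rotation)))),
               rep(1, fm$n_components), tolerance = 1e-6)

  expect_error(fit_fold(X, rep("a", nrow(X))), class = "serds_error_class")
  expect_error(fit_fold(X[1:3, ], c("a", "a", "b")), class = "serds_error_class")
})

test_that("predict_fold centers with the training mean and is rowwise", {
  data <- make_gaussian_dataset(15, p = 12, sep = 10)
  X <- as_spectra_matrix(data)
  fm <- fit_fold(X, data$label)

  centroid <- colMeans(X[data$label == "neurofibroma", ])
  expect_equal(as.character(predict_fold(fm, rbind(centroid))$class), "neurofibroma")

  # predictions are independent of the other rows in the test batch:
  # a heavily shifted companion row must not re-center the projection
  junk <- matrix(100, nrow = 5, ncol = ncol(X))
  alone <- predict_fold(fm, rbind(centroid))$class
  crowded <- predict_fold(fm, rbind(centroid, junk))$class[1]
  expect_identical(as.character(alone), as.character(crowded))

  test_rows <- X[1:6, ]
  perm <- c(4, 2, 6, 1, 3, 5)
  expect_identical(predict_fold(fm, test_rows)$class[perm],
                   predict_fold(fm, test_rows[perm, ])$class)

  expect_error(predict_fold(fm, X[, 1:5]), class = "serds_error_shape")
})

test_that("stratified folds partition every class evenly", {
  labels <- rep(c("neurofibroma", "skin", "nerve"), times = c(9, 12, 6))
  for (seed in 1:5) {
    fold <- stratified_folds(labels, k = 5, seed = seed)
    expect_setequal(unique(fold), 1:5)
    sizes <- table(fold)
    expect_lte(diff(range(sizes)), 2)
    for (cl in unique(labels)) {
      per_class <- table(fold[labels == cl])
      expect_lte(diff(range(per_class)), 1)
    }
  }
  expect_error(stratified_folds(labels, k = 7), class = "serds_error_class")
  expect_error(stratified_folds(labels, k = 1), class = "serds_error_config")
})

test_that("cross-validation is leakage-safe, exhaustive and seed-stable", {
  data <- make_gaussian_dataset(12, p = 20, sep = 8,
                                classes = c("neurofibroma", "skin", "fat"))
  cv1 <- cross_validate(data, k = 4, seed = 11)
  cv2 <- cross_validate(data, k = 4, seed = 11)
  expect_identical(cv1$assignments, cv2$assignments)
  expect_identical(tidy(cv1), tidy(cv2))

  # every locus tested exactly once; fold sizes near n/k
  expect_setequal(cv1$assignments$locus, data$locus)
  expect_equal(nrow(cv1$assignments), nrow(data))
  sizes <- table(cv1$assignments$fold)
  expect_true(all(sizes %in% c(nrow(data) %/% 4, nrow(data) %/% 4 + 1)))

  # confusion conservation: counts sum to the rows involved per comparison
  rep_tbl <- tidy(cv1)
  all_row <- rep_tbl[rep_tbl$comparison == "neurofibroma vs all", ]
  expect_equal(all_row$tp + all_row$fp + all_row$fn + all_row$tn, nrow(data))
  skin_row <- rep_tbl[rep_tbl$comparison == "neurofibroma vs skin", ]
  expect_equal(skin_row$tp + skin_row$fp + skin_row$fn + skin_row$tn, 24)

  # leakage audit: dropping a test row leaves its fold's model untouched
  X <- as_spectra_matrix(data)
  fold <- stratified_folds(data$label, k = 4, seed = 11)
  test_idx <- which(fold == 1)
  train <- fold != 1
  fm_full <- fit_fold(X[train, ], data$label[train])
  keep <- setdiff(seq_len(nrow(X)), test_idx[1])
  fm_dropped <- fit_fold(X[keep, ][fold[keep] != 1, ], data$label[keep][fold[keep] != 1])
  expect_identical(fm_full$mean, fm_dropped$mean)
  expect_identical(fm_full$rotation, fm_dropped$rotation)
})

test_that("a separable two-class simulation cross-validates at 100%", {
  data <- make_gaussian_dataset(20, p = 10, sep = 30, seed = 4)
  cv <- cross_validate(data, k = 5, seed = 2)
  expect_equal(cv$overall_accuracy, 100)
  rep_tbl <- tidy(cv)
  expect_equal(rep_tbl$accuracy[rep_tbl$comparison == "neurofibroma vs all"], 100)
})

test_that("binary metrics reproduce the tumor-vs-tissue panel arithmetic", {
  # all-tissue comparison: 9/9 tumors correct, 71 of 73 physiological correct
  m <- binary_metrics(tp = 9, fp = 2, fn = 0, tn = 71)
  expect_equal(m$sensitivity, 100)
  expect_equal(round(m$specificity, 1), 97.3)
  expect_equal(round(m$accuracy, 1), 97.6)
  expect_equal(round(m$error, 1), 2.4)
  expect_equal(m$n, 82)

  # mucosa panel: 25 of 27 mucosa correct
  m2 <- binary_metrics(tp = 9, fp = 2, fn = 0, tn = 25)
  expect_equal(round(m2$specificity, 1), 92.6)
  expect_equal(round(m2$accuracy, 1), 94.4)

  # skin panel: 8 of 9 tumors, all 12 skin correct
  m3 <- binary_metrics(tp = 8, fp = 0, fn = 1, tn = 12)
  expect_equal(round(m3$sensitivity, 1), 88.9)
  expect_equal(round(m3$accuracy, 1), 95.2)
  expect_equal(round(m3$error, 1), 4.8)

  expect_error(binary_metrics(0, 0, 0, 10), class = "serds_error_degenerate")
  expect_error(binary_metrics(5, 0, 0, 0), class = "serds_error_degenerate")
  expect_error(binary_metrics(-1, 0, 1, 10), class = "serds_error_value")
})

test_that("rank-based AUC behaves as a Mann-Whitney statistic", {
  labels <- rep(c("neurofibroma", "other"), each = 10)
  perfect <- c(rnorm(10, 10), rnorm(10, -10))
  expect_equal(roc_auc(perfect, labels), 100)
  expect_equal(roc_auc(-perfect, labels), 0)

  some <- runif(20)
  expect_equal(roc_auc(some, labels) + roc_auc(-some, labels), 100)

  # ties get midranks
  expect_equal(roc_auc(rep(1, 20), labels), 50)
  expect_error(roc_auc(1:5, rep("neurofibroma", 5)), class = "serds_error_degenerate")

  # null calibration: independent scores hover near 50%
  aucs <- withr::with_seed(12, {
    replicate(200, roc_auc(rnorm(1000), sample(rep(c("neurofibroma", "other"), 500))))
  })
  expect_gte(mean(aucs > 45 & aucs < 55), 0.93)

  # agreement with an independent implementation
  skip_if_not_installed("pROC")
  sc <- withr::with_seed(5, rnorm(40))
  lb <- rep(c("neurofibroma", "other"), 20)
  ref <- 100 * as.numeric(pROC::auc(pROC::roc(
    response = lb, predictor = sc, levels = c("other", "neurofibroma"),
    direction = "<", quiet = TRUE
  )))
  expect_equal(roc_auc(sc, lb), ref, tolerance = 1e-10)
})

peak_tbl_for_test <- function(centers, fwhm, amps) {
  tibble::tibble(center = centers, fwhm = fwhm, mean_amplitude = amps,
                 inter_locus_cv = 0.15)
}

test_that("stronger between-class contrast never degrades median accuracy", {
  # two synthetic classes sharing line positions; the contrast knob scales
  # their amplitude-pattern difference
  run_once <- function(contrast, seed) {
    centers <- c(1004, 1270, 1450, 1658)
    fwhm <- c(12, 40, 22, 35)
    base <- c(600, 400, 700, 500)
    dir <- c(1, -1, 1, -1)
    lib <- list(
      neurofibroma = class_template("neurofibroma", peak_tbl_for_test(
        centers, fwhm, base * (1 + 0.25 * contrast * dir))),
      skin = class_template("skin", peak_tbl_for_test(
        centers, fwhm, base * (1 - 0.25 * contrast * dir)))
    )
    cfg <- cohort_config(counts = c(neurofibroma = 8, skin = 8), seed = seed,
                         grid = seq(800, 940, length.out = 512))
    cohort <- cohort_differences(generate_cohort(cfg, lib, collapse_repeats = TRUE))
    cohort$purified <- purrr::map(cohort$diff, classic_reconstruct)
    cv <- cross_validate(spectra_dataset(cohort), k = 4, seed = seed)
    cv$overall_accuracy
  }
  acc <- vapply(c(0, 0.5, 1), function(ct) {
    median(vapply(1:10, function(s) run_once(ct, s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(acc) >= 0))
  expect_gt(acc[3], acc[1])
})
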