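#' Restrict a purified spectrum to a shift window
#'
#' Keeps bins with `low <= shift <= high` (inclusive); the tissue-diagnostic
#' fingerprint region is 550-1800 cm^-1.
#'
#' @param spectrum A `purified_spectrum` (or any tibble with `shift`).
#' @param low,high Window bounds in cm^-1.
#' @return The restricted spectrum.
#' @export
restrict_range <- function(spectrum, low = 550, high = 1800) {
  if (low > high) abort("need low <= high.", class = "serds_error_value")
  keep <- spectrum$shift >= low & spectrum$shift <= high
  if (!any(keep)) abort("no bins in the requested range.", class = "serds_error_empty")
  out <- spectrum[keep, ]
  for (a in c("locus", "label", "purifier")) attr(out, a) <- attr(spectrum, a)
  out
}

#' Assemble the classifier dataset from a purified cohort
#'
#' One row per locus; the spectral matrix is restricted to the fingerprint
#' window.
#'
#' @param cohort A cohort tibble with a `purified` list-column.
#' @param low,high Shift window (cm^-1).
#' @return A `serds_dataset` tibble with columns `locus`, `label` and a
#'   `spectrum` list-column, plus the shift axis as an attribute.
#' @export
spectra_dataset <- function(cohort, low = 550, high = 1800) {
  stopifnot("purified" %in% names(cohort))
  restricted <- purrr::map(cohort$purified, restrict_range, low = low, high = high)
  axis <- restricted[[1]]$shift
  out <- tibble(
    locus = cohort$locus, label = cohort$label,
    spectrum = purrr::map(restricted, "intensity")
  )
  if (any(!purrr::map_lgl(out$spectrum, ~ all(is.finite(.x))))) {
    abort("dataset contains non-finite intensities.", class = "serds_error_value")
  }
  attr(out, "shift_axis") <- axis
  class(out) <- c("serds_dataset", class(out))
  out
}

#' Spectral matrix of a dataset
#' @param data A `serds_dataset`.
#' @return Numeric matrix, loci x shift bins.
#' @export
as_spectra_matrix <- function(data) {
  do.call(rbind, data$spectrum)
}

#' Fit one cross-validation fold (PCA + multiclass LDA)
#'
#' Centers the training rows on their mean, computes the PCA basis from the
#' training rows only, retains the smallest number of components explaining
#' at least `var_threshold` of the training variance (capped at
#' `n_train - n_classes`), and fits a multiclass linear discriminant on the
#' retained scores. Nothing from any test row enters the fit.
#'
#' @param X Training spectral matrix (rows = loci).
#' @param labels Factor or character labels, >= 2 classes, each with >= 2
#'   rows.
#' @param var_threshold Explained-variance retention threshold.
#' @param fold Fold index (bookkeeping).
#' @return A `fold_model`: training mean, orthonormal basis,
#'   explained-variance fractions, retained count, LDA fit.
#' @export
fit_fold <- function(X, labels, var_threshold = 0.95, fold = NA_integer_) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) abort("need >= 2 classes.", class = "serds_error_class")
  if (any(table(labels) < 2)) {
    abort("every class needs >= 2 training rows (stratification failure).",
          class = "serds_error_class")
  }
  mu <- colMeans(X)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  cap <- max(1L, nrow(X) - nlevels(labels))
  k <- min(which(cumsum(ev) >= var_threshold), cap)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  lda_fit <- MASS::lda(scores, grouping = labels)
  structure(
    list(
      mean = mu, rotation = pc$rotation[, seq_len(k), drop = FALSE],
      ev_fraction = ev, n_components = k, lda = lda_fit,
      classes = levels(labels), fold = fold
    ),
    class = "fold_model"
  )
}

#' Predict with a fold model
#'
#' Test rows are centered with the training mean (never the test mean),
#' projected on the training PCA basis, and classified by the trained LDA.
#'
#' @param model A `fold_model`.
#' @param X Test spectral matrix on the same bin axis as the training rows.
#' @return List with `class` (factor) and `posterior` (matrix of class
#'   posteriors, used as decision scores).
#' @export
predict_fold <- function(model, X) {
  if (ncol(X) != length(model$mean)) {
    abort("test rows are on a different bin axis.", class = "serds_error_shape")
  }
  scores <- sweep(X, 2, model$mean) %*% model$rotation
  pr <- predict(model$lda, newdata = scores)
  list(class = pr$class, posterior = pr$posterior)
}

#' Stratified k-fold partition
#'
#' Shuffles within class (seeded) and deals loci round-robin so each fold's
#' class composition mirrors the cohort (test sizes n %/% k or n %/% k + 1).
#'
#' @param labels Class label per row.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold assignments in 1..k.
#' @export
stratified_folds <- function(labels, k = 5, seed = 1) {
  if (k < 2) abort("need k >= 2 folds.", class = "serds_error_config")
  labels <- factor(labels)
  if (any(table(labels) < k)) {
    abort("every class needs >= k rows for stratified folding.",
          class = "serds_error_class")
  }
  fold <- integer(length(labels))
  with_preserved_seed(seed, {
    offset <- 0L
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- 1L + (offset + seq_along(idx) - 1L) %% k
      offset <- offset + length(idx)
    }
  })
  fold
}

#' Binary classification metrics
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy (TP+TN)/total and
#' classification error 100 - accuracy, as percentages.
#'
#' @param tp,fp,fn,tn Confusion counts with the stated positive class.
#' @param positive Name of the positive class.
#' @return One-row tibble with counts and percentage metrics.
#' @export
binary_metrics <- function(tp, fp, fn, tn, positive = "neurofibroma") {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) abort("confusion counts must be >= 0.", class = "serds_error_value")
  total <- sum(counts)
  if (total == 0) abort("empty confusion matrix.", class = "serds_error_value")
  if (tp + fn == 0) {
    abort("no positive observations: sensitivity undefined.", class = "serds_error_degenerate")
  }
  if (tn + fp == 0) {
    abort("no negative observations: specificity undefined.", class = "serds_error_degenerate")
  }
  tibble(
    positive = positive, tp = tp, fp = fp, fn = fn, tn = tn, n = total,
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    accuracy = 100 * (tp + tn) / total,
    error = 100 - 100 * (tp + tn) / total
  )
}

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney formulation with midranks for ties: the probability that a
#' random positive scores above a random negative.
#'
#' @param scores Numeric decision scores (higher = more positive-like).
#' @param labels Binary labels.
#' @param positive The positive class value.
#' @return AUC as a percentage.
#' @export
roc_auc <- function(scores, labels, positive = "neurofibroma") {
  pos <- labels == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) abort("both classes must be present.", class = "serds_error_degenerate")
  r <- rank(scores, ties.method = "average")
  100 * (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

cv_one_comparison <- function(X, labels, positive, k, seed, var_threshold) {
  labels <- factor(labels)
  fold <- stratified_folds(labels, k = k, seed = seed)
  pred <- factor(rep(NA_character_, length(labels)), levels = levels(labels))
  score <- rep(NA_real_, length(labels))
  for (f in sort(unique(fold))) {
    test <- fold == f
    fm <- fit_fold(X[!test, , drop = FALSE], labels[!test],
                   var_threshold = var_threshold, fold = f)
    pr <- predict_fold(fm, X[test, , drop = FALSE])
    pred[test] <- pr$class
    if (positive %in% colnames(pr$posterior)) {
      score[test] <- pr$posterior[, positive]
    }
  }
  list(truth = labels, pred = pred, score = score, fold = fold)
}

#' Cross-validated PCA-LDA classification with binary panels
#'
#' Runs stratified k-fold cross-validation in which PCA and LDA are refitted
#' from scratch on each fold's training rows (leakage-safe). Produces the
#' multiclass overall report plus one binary panel per requested comparison:
#' the tumor class against all physiological tissue pooled, and pairwise
#' against each physiological class (each panel restricted to the rows of
#' the two groups involved). AUC is computed on pooled out-of-fold posterior
#' scores.
#'
#' @param data A `serds_dataset` tibble (`label`, `spectrum`).
#' @param k Folds (default 5, i.e. 80/20 splits).
#' @param seed Partition seed.
#' @param positive Positive (tumor) class for the binary panels.
#' @param var_threshold PCA retention threshold passed to [fit_fold()].
#' @return A `serds_cv` object; see [tidy.serds_cv()] and
#'   [glance.serds_cv()].
#' @export
cross_validate <- function(data, k = 5, seed = 1, positive = "neurofibroma",
                           var_threshold = 0.95) {
  X <- as_spectra_matrix(data)
  labels <- factor(data$label)
  if (nlevels(labels) < 2) abort("need >= 2 classes.", class = "serds_error_class")

  multi <- cv_one_comparison(X, labels, positive, k, seed, var_threshold)
  confusion <- table(truth = multi$truth, predicted = multi$pred)

  comparisons <- list()
  if (positive %in% levels(labels)) {
    others <- setdiff(levels(labels), positive)
    # pooled: positive vs all physiological tissue
    lab_all <- factor(ifelse(labels == positive, positive, "physiological"),
                      levels = c(positive, "physiological"))
    comparisons[["all"]] <- list(rows = rep(TRUE, length(labels)), labels = lab_all)
    for (cl in others) {
      rows <- labels %in% c(positive, cl)
      comparisons[[cl]] <- list(
        rows = rows,
        labels = factor(as.character(labels[rows]), levels = c(positive, cl))
      )
    }
  }

  reports <- purrr::imap(comparisons, function(cmp, nm) {
    res <- cv_one_comparison(X[cmp$rows, , drop = FALSE], cmp$labels,
                             positive, k, seed, var_threshold)
    tp <- sum(res$truth == positive & res$pred == positive)
    fn <- sum(res$truth == positive & res$pred != positive)
    fp <- sum(res$truth != positive & res$pred == positive)
    tn <- sum(res$truth != positive & res$pred != positive)
    metrics <- binary_metrics(tp, fp, fn, tn, positive = positive)
    metrics$comparison <- paste0(positive, " vs ", nm)
    metrics$auc <- roc_auc(res$score, res$truth, positive)
    list(metrics = metrics, assignments = res)
  })

  report_tbl <- purrr::map(reports, "metrics") |>
    purrr::list_rbind() |>
    dplyr::select("comparison", dplyr::everything())

  structure(
    list(
      reports = report_tbl,
      confusion = confusion,
      overall_accuracy = 100 * mean(multi$pred == multi$truth),
      assignments = tibble(
        locus = data$locus, truth = multi$truth, predicted = multi$pred,
        fold = multi$fold
      ),
      binary_assignments = purrr::map(reports, "assignments"),
      k = k, seed = seed, positive = positive, n = nrow(data)
    ),
    class = "serds_cv"
  )
}

#' @export
print.serds_cv <- function(x, ...) {
  cat(sprintf("<serds_cv> %d loci, %d-fold, overall accuracy %.1f%%\n",
              x$n, x$k, x$overall_accuracy))
  print(as.data.frame(dplyr::mutate(x$reports, dplyr::across(
    c("sensitivity", "specificity", "accuracy", "error", "auc"),
    ~ round(.x, 1)
  ))))
  invisible(x)
}

#' Tidy a cross-validation result
#'
#' @param x A `serds_cv` object.
#' @param ... Unused.
#' @return Tibble with one row per binary comparison: confusion counts and
#'   sensitivity/specificity/accuracy/error/AUC percentages.
#' @export
tidy.serds_cv <- function(x, ...) x$reports

#' One-row summary of a cross-validation result
#'
#' @param x A `serds_cv` object.
#' @param ... Unused.
#' @return Tibble with the multiclass overall accuracy, locus count, fold
#'   count and seed.
#' @export
glance.serds_cv <- function(x, ...) {
  tibble(
    n = x$n, k = x$k, seed = x$seed,
    overall_accuracy = x$overall_accuracy,
    n_comparisons = nrow(x$reports)
  )
}
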