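# Binary-classification metrics, ROC/AUC, and the two evaluation protocols
# used for sequence-based PPI prediction: stratified k-fold cross-validation
# and train-on-one-species / test-on-another.

#' Confusion counts from predicted and true labels
#'
#' @param predicted,truth Vectors of 0/1 labels (1 = interacting).
#' @return Named integer vector `c(TP, TN, FP, FN)`.
#' @export
confusion_counts <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  predicted <- as.integer(predicted); truth <- as.integer(truth)
  stopifnot(all(predicted %in% c(0L, 1L)), all(truth %in% c(0L, 1L)))
  c(TP = sum(predicted == 1L & truth == 1L),
    TN = sum(predicted == 0L & truth == 0L),
    FP = sum(predicted == 1L & truth == 0L),
    FN = sum(predicted == 0L & truth == 1L))
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+FP+TN+FN)`, sensitivity `TP/(TP+FN)`, precision
#' `TP/(TP+FP)` and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN))`. A metric whose
#' denominator is zero is reported as 0 with a warning, so one degenerate
#' fold cannot abort a cross-validation run.
#'
#' @param counts Named vector with elements TP, TN, FP, FN (as from
#'   [confusion_counts()]).
#' @return Named numeric vector `c(accuracy, sensitivity, precision, mcc)`.
#' @export
compute_metrics <- function(counts) {
  needed <- c("TP", "TN", "FP", "FN")
  stopifnot(all(needed %in% names(counts)))
  tp <- as.numeric(counts[["TP"]]); tn <- as.numeric(counts[["TN"]])
  fp <- as.numeric(counts[["FP"]]); fn <- as.numeric(counts[["FN"]])
  if (any(c(tp, tn, fp, fn) < 0)) stop("confusion counts must be non-negative")
  total <- tp + tn + fp + fn
  if (total == 0) stop("confusion counts are all zero")
  acc <- (tp + tn) / total
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reported as 0")
      return(0)
    }
    num / den
  }
  sens <- safe_div(tp, tp + fn, "sensitivity")
  prec <- safe_div(tp, tp + fp, "precision")
  mcc_den <- sqrt((tp + fn) * (tn + fp) * (tp + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) {
    warning("MCC undefined (zero denominator); reported as 0")
    0
  } else (tp * tn - fp * fn) / mcc_den
  c(accuracy = acc, sensitivity = sens, precision = prec, mcc = mcc)
}

#' ROC curve and AUC
#'
#' AUC is computed as the normalized Mann-Whitney rank statistic: the
#' probability that a random positive sample outscores a random negative one,
#' with ties counted one half (midranks). The step-curve points (fpr, tpr,
#' threshold) are returned alongside; integrating them by the trapezoid rule
#' gives the same number, which the test suite uses as a cross-check.
#'
#' @param scores Numeric decision scores, larger = more positive.
#' @param labels 0/1 truth labels; both classes must be present.
#' @return List with `auc` and `points` (`data.frame` with columns
#'   `threshold`, `fpr`, `tpr`, ordered from the (0,0) to the (1,1) corner).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC needs both classes present (got ", n_pos, " positive, ",
         n_neg, " negative)")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  # step curve: sweep thresholds from +Inf down across unique scores
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- cumsum(vapply(thr, function(t) sum(scores == t & labels == 1L), numeric(1)))
  fp <- cumsum(vapply(thr, function(t) sum(scores == t & labels == 0L), numeric(1)))
  points <- data.frame(threshold = c(Inf, thr),
                       fpr = c(0, fp / n_neg),
                       tpr = c(0, tp / n_pos))
  list(auc = auc, points = points)
}

#' Stratified fold assignment
#'
#' @param labels 0/1 labels.
#' @param k Number of folds.
#' @param seed Integer seed controlling the shuffle.
#' @return Integer vector of fold ids (1..k), stratified so each fold has a
#'   near-equal share of each class; fold sizes differ by at most 1 per class.
#' @export
make_folds <- function(labels, k, seed) {
  stopifnot(k >= 2)
  n <- length(labels)
  if (k > n) stop("more folds than samples")
  set.seed(as.integer(seed))
  fold <- integer(n)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' k-fold cross-validation of the full pipeline
#'
#' Encodes every pair once, splits the dataset into k stratified folds with
#' the given seed, and for each fold trains a WSRC model on the remaining
#' folds and evaluates on the held-out one. Reports per-fold accuracy,
#' sensitivity, precision, MCC and AUC, plus their mean and standard
#' deviation.
#'
#' @param pairs Data frame with `id_a`, `id_b`, `label` (both classes
#'   present).
#' @param proteins Named character vector of sequences.
#' @param k Number of folds; default 5.
#' @param seed Integer seed for the fold shuffle (required: every randomized
#'   step in the package takes an explicit seed).
#' @param L Global-encoding partition parameter; default 5.
#' @param encoder `"ge"` or `"2mer"`, passed to [encode_pairs()].
#' @param sigma,epsilon,weight_mode,normalize_columns Passed to [wsrc_fit()].
#' @param normalize_transition Passed to [encode_pairs()].
#' @param symmetrize Augment each fold's training pairs with their
#'   swapped-order duplicates ([symmetrize_pairs()]); default TRUE, making
#'   the classifier invariant to the arbitrary order of a pair's proteins.
#' @param features Optional precomputed result of [encode_pairs()] on
#'   `pairs` (a list with `x` and `labels`), to avoid re-encoding in
#'   parameter sweeps.
#' @return Object of class `"wsrc_cv"`: list with `per_fold` (data.frame),
#'   `mean`, `sd`, `predictions` (score/class/fold/truth per pair) and the
#'   configuration used.
#' @export
kfold_cross_validate <- function(pairs, proteins, k = 5L, seed,
                                 L = 5L, encoder = "ge",
                                 sigma = 1.5, epsilon = 5e-5,
                                 weight_mode = "inverse_similarity",
                                 normalize_columns = FALSE,
                                 normalize_transition = TRUE,
                                 symmetrize = TRUE,
                                 features = NULL) {
  stopifnot(all(c("id_a", "id_b", "label") %in% names(pairs)))
  if (missing(seed)) stop("seed is required")
  labels <- as.integer(pairs$label)
  if (length(unique(labels)) < 2L) stop("dataset must contain both classes")
  if (is.null(features)) {
    features <- encode_pairs(pairs, proteins, L = L, encoder = encoder,
                             normalize_transition = normalize_transition)
  }
  x <- features$x
  fold <- make_folds(labels, k, seed)
  metric_names <- c("accuracy", "sensitivity", "precision", "mcc", "auc")
  per_fold <- matrix(NA_real_, nrow = k, ncol = length(metric_names),
                     dimnames = list(NULL, metric_names))
  pred_all <- data.frame(fold = fold, truth = labels,
                         class = NA_integer_, score = NA_real_)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- fold == f
    if (length(unique(labels[tr])) < 2L) {
      stop("a training split lost a class; use stratified folds or more data")
    }
    xtr <- x[tr, , drop = FALSE]; ytr <- labels[tr]
    if (symmetrize) {
      aug <- symmetrize_pairs(xtr, ytr)
      xtr <- aug$x; ytr <- aug$labels
    }
    model <- wsrc_fit(xtr, ytr,
                      sigma = sigma, epsilon = epsilon,
                      weight_mode = weight_mode,
                      normalize_columns = normalize_columns)
    pr <- suppressWarnings(predict(model, x[te, , drop = FALSE]))
    m <- suppressWarnings(compute_metrics(confusion_counts(pr$class, labels[te])))
    auc <- roc_auc(pr$score, labels[te])$auc
    per_fold[f, ] <- c(m, auc)
    pred_all$class[te] <- as.integer(pr$class)
    pred_all$score[te] <- pr$score
  }
  per_fold <- as.data.frame(per_fold)
  per_fold <- cbind(fold = seq_len(k), per_fold)
  structure(list(
    per_fold = per_fold,
    mean = colMeans(per_fold[metric_names]),
    sd = apply(per_fold[metric_names], 2, stats::sd),
    predictions = pred_all,
    config = list(k = k, seed = seed, L = L, encoder = encoder,
                  sigma = sigma, epsilon = epsilon,
                  weight_mode = weight_mode,
                  normalize_columns = normalize_columns,
                  normalize_transition = normalize_transition,
                  symmetrize = symmetrize)
  ), class = "wsrc_cv")
}

#' @export
print.wsrc_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %s, encoder %s, L = %d)\n",
              x$config$k, x$config$seed, x$config$encoder, x$config$L))
  print(round(x$per_fold, 4), row.names = FALSE)
  cat("mean:\n"); print(round(x$mean, 4))
  cat("sd:\n"); print(round(x$sd, 4))
  invisible(x)
}

#' Train on one dataset, evaluate on another
#'
#' The cross-species protocol: a single WSRC model is trained on all training
#' pairs and applied to each test pair set. When a test set contains both
#' classes the full metric panel (and AUC) is reported; a positives-only test
#' set reports accuracy, which then equals sensitivity.
#'
#' @param train_pairs,train_proteins Training pair table and sequences.
#' @param test_pairs,test_proteins Test pair table and sequences.
#' @inheritParams kfold_cross_validate
#' @return List with `metrics` (named numeric vector), `counts`, and
#'   `predictions`.
#' @export
cross_species_evaluate <- function(train_pairs, train_proteins,
                                   test_pairs, test_proteins,
                                   L = 5L, encoder = "ge",
                                   sigma = 1.5, epsilon = 5e-5,
                                   weight_mode = "inverse_similarity",
                                   normalize_columns = FALSE,
                                   normalize_transition = TRUE,
                                   symmetrize = TRUE) {
  if (nrow(test_pairs) == 0L) stop("empty test set")
  tr <- encode_pairs(train_pairs, train_proteins, L = L, encoder = encoder,
                     normalize_transition = normalize_transition)
  te <- encode_pairs(test_pairs, test_proteins, L = L, encoder = encoder,
                     normalize_transition = normalize_transition)
  xtr <- tr$x; ytr <- tr$labels
  if (symmetrize) {
    aug <- symmetrize_pairs(xtr, ytr)
    xtr <- aug$x; ytr <- aug$labels
  }
  model <- wsrc_fit(xtr, ytr, sigma = sigma, epsilon = epsilon,
                    weight_mode = weight_mode,
                    normalize_columns = normalize_columns)
  pr <- suppressWarnings(predict(model, te$x))
  truth <- as.integer(test_pairs$label)
  counts <- confusion_counts(pr$class, truth)
  metrics <- suppressWarnings(compute_metrics(counts))
  if (length(unique(truth)) == 2L) {
    metrics <- c(metrics, auc = roc_auc(pr$score, truth)$auc)
  }
  list(metrics = metrics, counts = counts,
       predictions = cbind(test_pairs, class = as.integer(pr$class),
                           score = pr$score))
}
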