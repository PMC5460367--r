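#' Confusion counts from predictions and truth
#'
#' @param predicted,truth binary 0/1 vectors of equal length (positives are
#'   the class coded 1).
#' @return list with integer fields TP, TN, FP, FN.
#' @export
confusion_counts <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  predicted <- as.integer(predicted)
  truth <- as.integer(truth)
  list(TP = sum(predicted == 1L & truth == 1L),
       TN = sum(predicted == 0L & truth == 0L),
       FP = sum(predicted == 1L & truth == 0L),
       FN = sum(predicted == 0L & truth == 1L))
}

#' Binary classification metrics from confusion counts
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy
#' (TP+TN)/(TP+TN+FP+FN) and Matthews correlation coefficient
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TN+FN)(TP+FN)(TN+FP)).  Any zero marginal
#' makes the MCC denominator zero; the MCC is then defined as 0, the
#' standard convention that keeps the statistic total.  Undefined
#' sensitivity/specificity (empty class) is reported as NA.
#'
#' @param counts list/vector with elements TP, TN, FP, FN.
#' @return named list: sensitivity, specificity, accuracy, mcc.
#' @export
compute_metrics <- function(counts) {
  tp <- as.numeric(counts$TP); tn <- as.numeric(counts$TN)
  fp <- as.numeric(counts$FP); fn <- as.numeric(counts$FN)
  n <- tp + tn + fp + fn
  if (n < 1) stop("no records to evaluate")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / n
  denom <- (tp + fp) * (tn + fn) * (tp + fn) * (tn + fp)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else 0
  list(sensitivity = sens, specificity = spec, accuracy = acc, mcc = mcc)
}

#' Area under the ROC curve
#'
#' Computed by the rank method: AUC is the probability that a random
#' positive scores above a random negative, with ties contributing 1/2
#' (midranks).  Equivalent to the trapezoidal area under the empirical ROC.
#'
#' @param scores numeric propensity scores (higher = more positive).
#' @param labels binary 0/1 truth vector.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUC requires both classes in `labels`")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Stratified fold assignment
#'
#' @param y binary labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in 1..k.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  y <- as.integer(y)
  stopifnot(k >= 2L)
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

summarize_metric_rows <- function(rows, n_label = "n_folds") {
  tab <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  means <- colMeans(tab, na.rm = TRUE)
  sds <- apply(tab, 2, function(v) {
    if (length(v) > 1L) stats::sd(v, na.rm = TRUE) else 0
  })
  out <- list(per_fold = tab, mean = as.list(means), sd = as.list(sds))
  out[[n_label]] <- nrow(tab)
  class(out) <- "blp_metrics"
  out
}

#' @export
print.blp_metrics <- function(x, ...) {
  cat("<blp_metrics>\n")
  for (m in names(x$mean))
    cat(sprintf("  %-12s %.3f ± %.3f\n", m, x$mean[[m]], x$sd[[m]]))
  invisible(x)
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' Splits the labelled dataset into `k` stratified folds; for each fold the
#' entire pipeline — motif discovery, feature assembly, optional feature
#' selection, grid-search SVM training — is re-run on the training folds
#' only, and the held-out fold is predicted.  This keeps the motif catalog
#' and standardization free of information from the validation fold.
#' Supplying a pre-built catalog via `config$catalog` emulates the laxer
#' protocol in which motifs are discovered once on the full set.
#'
#' @param data labelled `blp_dataset`.
#' @param config pipeline configuration, see [default_config()].
#' @param k number of folds (default 5).
#' @param seed integer seed controlling fold assignment and training.
#' @return a `blp_metrics` report (mean, sd and per-fold values of
#'   sensitivity, specificity, accuracy, MCC, AUC).
#' @export
kfold_cv <- function(data, config = default_config(), k = 5L, seed = 1L) {
  cc <- class_counts(data)
  if (any(cc == 0L)) stop("both classes required for cross-validation")
  labelled <- data[!is.na(data$label), , drop = FALSE]
  fold <- stratified_folds(labelled$label, k, seed)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    train <- labelled[fold != f, , drop = FALSE]
    test <- labelled[fold == f, , drop = FALSE]
    if (length(unique(train$label)) < 2L || length(unique(test$label)) < 2L)
      stop("fold ", f, " has a single class; use more data or fewer folds")
    model <- train_pipeline(train, config, seed = seed + f)
    pred <- stats::predict(model, test)
    m <- compute_metrics(confusion_counts(pred$label, test$label))
    m$auc <- roc_auc(pred$score, test$label)
    rows[[f]] <- m
  }
  summarize_metric_rows(rows, "n_folds")
}

#' Repeated balanced under-sampling evaluation
#'
#' Evaluates a trained model (or lineage ensemble) on `repeats` balanced
#' resamples of an imbalanced labelled dataset, retaining the per-repeat
#' metric vectors so that predictors sharing the resampling seeds can be
#' compared by a paired significance test.  With `fraction` set (e.g. 0.8),
#' each repeat instead draws that fraction of each class at random.
#'
#' @param model a `blp_model` or `blp_ensemble`.
#' @param data labelled `blp_dataset`.
#' @param repeats number of resamples (default 10).
#' @param seed integer seed; repeat r uses seed + r.
#' @param fraction optional per-class sampling fraction in (0, 1\];
#'   `NULL` (default) means balanced under-sampling of the majority class.
#' @return a `blp_metrics` report with `n_repeats` and per-repeat rows.
#' @export
repeated_undersample_eval <- function(model, data, repeats = 10L, seed = 1L,
                                      fraction = NULL) {
  cc <- class_counts(data)
  if (any(cc == 0L)) stop("both classes must be present")
  rows <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    sub <- if (is.null(fraction)) {
      undersample_balanced(data, seed = seed + r)
    } else {
      stopifnot(fraction > 0, fraction <= 1)
      pos <- data$id[!is.na(data$label) & data$label == 1L]
      neg <- data$id[!is.na(data$label) & data$label == 0L]
      keep <- with_seed(seed + r, c(sample(pos, round(fraction * length(pos))),
                                    sample(neg, round(fraction * length(neg)))))
      data[data$id %in% keep, , drop = FALSE]
    }
    pred <- stats::predict(model, sub)
    m <- compute_metrics(confusion_counts(pred$label, sub$label))
    m$auc <- roc_auc(pred$score, sub$label)
    rows[[r]] <- m
  }
  summarize_metric_rows(rows, "n_repeats")
}

#' Paired significance test between two predictors
#'
#' Implements the normality-gated protocol: both metric vectors are first
#' checked with the Shapiro-Wilk test at alpha = 0.05; if both pass, a
#' paired two-sided t-test is used, otherwise the Wilcoxon signed-rank test.
#' Identical vectors return p = 1 by convention.  Significance is declared
#' at p < 0.05.
#'
#' @param metric_a,metric_b equal-length paired metric vectors (length >= 5,
#'   e.g. MCC across the same resamples for two methods).
#' @return list: `test_used` (`"t_test"` or `"wilcoxon"`), `normality_p`
#'   (smaller of the two Shapiro-Wilk p-values), `p_value`, `significant`.
#' @export
compare_methods <- function(metric_a, metric_b) {
  stopifnot(length(metric_a) == length(metric_b), length(metric_a) >= 5L)
  if (isTRUE(all.equal(metric_a, metric_b, tolerance = 0)) ||
      all(metric_a == metric_b))
    return(list(test_used = "t_test", normality_p = NA_real_,
                p_value = 1, significant = FALSE))
  sw <- function(v) {
    if (stats::sd(v) == 0) return(0)  # degenerate: treat as non-normal
    stats::shapiro.test(v)$p.value
  }
  normality_p <- min(sw(metric_a), sw(metric_b))
  if (normality_p > 0.05) {
    test_used <- "t_test"
    p <- stats::t.test(metric_a, metric_b, paired = TRUE)$p.value
  } else {
    test_used <- "wilcoxon"
    p <- suppressWarnings(
      stats::wilcox.test(metric_a, metric_b, paired = TRUE,
                         exact = FALSE)$p.value)
  }
  list(test_used = test_used, normality_p = normality_p,
       p_value = p, significant = p < 0.05)
}
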