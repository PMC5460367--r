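test_that("compute_metrics evaluates the four binary criteria exactly", {
  perfect <- compute_metrics(list(TP = 5, TN = 5, FP = 0, FN = 0))
  expect_equal(unlist(perfect),
               c(sensitivity = 1, specificity = 1, accuracy = 1, mcc = 1))
  m <- compute_metrics(list(TP = 3, TN = 2, FP = 1, FN = 2))
  expect_equal(m$accuracy, 0.625)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 2 / 3)
  expect_equal(m$mcc, 4 / sqrt(240))
  # all-positive prediction on balanced data: zero-denominator MCC rule
  ap <- compute_metrics(list(TP = 5, TN = 0, FP = 5, FN = 0))
  expect_equal(ap$sensitivity, 1)
  expect_equal(ap$specificity, 0)
  expect_equal(ap$mcc, 0)
})

test_that("metrics agree with a per-record tally oracle on random vectors", {
  set.seed(71)
  for (i in 1:1000) {
    n <- sample(4:40, 1)
    truth <- stats::rbinom(n, 1, 0.5)
    pred <- stats::rbinom(n, 1, 0.5)
    cc <- confusion_counts(pred, truth)
    expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, n)
    m <- compute_metrics(cc)
    # brute-force oracle: direct per-record tallies and Pearson correlation
    expect_equal(m$accuracy, mean(pred == truth))
    if (any(truth == 1)) expect_equal(m$sensitivity, mean(pred[truth == 1] == 1))
    if (any(truth == 0)) expect_equal(m$specificity, mean(pred[truth == 0] == 0))
    if (stats::sd(pred) > 0 && stats::sd(truth) > 0)
      expect_equal(m$mcc, stats::cor(pred, truth))
  }
})

test_that("MCC respects class-flip symmetries", {
  set.seed(72)
  for (i in 1:50) {
    truth <- stats::rbinom(20, 1, 0.5)
    pred <- stats::rbinom(20, 1, 0.5)
    m <- compute_metrics(confusion_counts(pred, truth))
    flip <- compute_metrics(confusion_counts(1 - pred, 1 - truth))
    expect_equal(flip$mcc, m$mcc)
    expect_equal(flip$sensitivity, m$specificity)
    expect_equal(flip$specificity, m$sensitivity)
  }
})

test_that("roc_auc handles perfect ordering, ties and the null", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(73)
  null_auc <- roc_auc(stats::runif(10000), stats::rbinom(10000, 1, 0.5))
  expect_gt(null_auc, 0.47)
  expect_lt(null_auc, 0.53)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("roc_auc equals the Mann-Whitney U normalization", {
  set.seed(74)
  for (i in 1:200) {
    n1 <- sample(3:30, 1); n0 <- sample(3:30, 1)
    scores <- round(c(stats::rnorm(n1, 0.5), stats::rnorm(n0)), 1)  # force ties
    labels <- rep(c(1, 0), c(n1, n0))
    u <- suppressWarnings(stats::wilcox.test(scores[labels == 1],
                                             scores[labels == 0]))$statistic
    expect_equal(roc_auc(scores, labels), unname(u) / (n1 * n0))
  }
})

test_that("stratified folds are balanced within one record", {
  y <- rep(c(0L, 1L), each = 50)
  fold <- stratified_folds(y, 5, seed = 1)
  tab <- table(fold, y)
  expect_true(all(tab == 10))
  expect_identical(fold, stratified_folds(y, 5, seed = 1))
})

test_that("kfold_cv is reproducible and reports per-fold spread", {
  d <- tiny_planted(seed = 30, n = 20)
  cfg <- test_config(blocks = c("AAC", "MTF"), folds = 3)
  r1 <- kfold_cv(d, cfg, k = 3, seed = 5)
  r2 <- kfold_cv(d, cfg, k = 3, seed = 5)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_equal(r1$n_folds, 3L)
  expect_named(r1$mean, c("sensitivity", "specificity", "accuracy",
                          "mcc", "auc"))
})

test_that("repeated_undersample_eval retains per-repeat metric vectors", {
  train <- tiny_planted(seed = 31, n = 20)
  m <- train_pipeline(train, test_config(blocks = c("AAC", "MTF")), seed = 1)
  test <- simulate_dataset(simulation_spec(
    n_pos = 10, n_neg = 40, length_range = c(50, 80),
    planted_motifs = list(list(pattern = "EHH", rate_pos = 0.8,
                               rate_neg = 0.05)),
    seed = 32))
  r <- repeated_undersample_eval(m, test, repeats = 10, seed = 2)
  expect_equal(nrow(r$per_fold), 10L)
  expect_equal(r$n_repeats, 10L)
  r1 <- repeated_undersample_eval(m, test, repeats = 1, seed = 2)
  expect_equal(r1$sd$mcc, 0)
  expect_identical(repeated_undersample_eval(m, test, repeats = 3, seed = 4)$per_fold,
                   repeated_undersample_eval(m, test, repeats = 3, seed = 4)$per_fold)
  # the 80%-draw variant samples each class proportionally
  r8 <- repeated_undersample_eval(m, test, repeats = 2, seed = 2, fraction = 0.8)
  expect_equal(r8$n_repeats, 2L)
})

test_that("compare_methods gates on normality and detects a real shift", {
  set.seed(75)
  b <- stats::rnorm(10, 0.7, 0.02)
  a <- b + 0.2 + stats::rnorm(10, 0, 0.01)
  res <- compare_methods(a, b)
  expect_true(res$significant)
  expect_lt(res$p_value, 0.05)
  # identical vectors: p = 1 convention
  same <- compare_methods(b, b)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)
  # heavy-tailed inputs route to the signed-rank test
  set.seed(76)
  routed <- replicate(20, {
    x <- stats::rcauchy(10); y <- stats::rcauchy(10)
    compare_methods(x, y)$test_used
  })
  expect_gt(mean(routed == "wilcoxon"), 0.5)
})
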