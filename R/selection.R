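#' Filter-type feature ranking (Fisher-Markov-style)
#'
#' Scores every feature by class separation on the standardized column:
#' `score_j = d_j^2 - gamma * w_j`, where `d_j` is the difference of class
#' means and `w_j` the pooled within-class variance of standardized feature
#' j.  With `gamma = 0` the ranking reduces to ordering by absolute
#' difference of class means.  This is a fully specified two-class
#' linear-kernel variant of the Fisher-Markov family of filters; an exact
#' published selector can be dropped in through the same interface.
#'
#' @param X numeric feature matrix (rows = samples, named columns).
#' @param y binary 0/1 labels, at least 2 samples per class.
#' @param gamma within-class-spread regularization weight (default 0).
#' @return a `blp_ranking`: data frame with columns `feature` and `score`,
#'   sorted by score descending (ties broken by feature name), with
#'   attribute `gamma`.
#' @export
fisher_markov_rank <- function(X, y, gamma = 0) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("labels are constant; need two classes")
  if (min(table(y)) < 2L) stop("need at least 2 samples per class")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  sdev[sdev == 0] <- 1  # constant columns standardize to all-zero
  Xs <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  i1 <- y == 1L; i0 <- y == 0L
  d <- colMeans(Xs[i1, , drop = FALSE]) - colMeans(Xs[i0, , drop = FALSE])
  v1 <- apply(Xs[i1, , drop = FALSE], 2, stats::var)
  v0 <- apply(Xs[i0, , drop = FALSE], 2, stats::var)
  n1 <- sum(i1); n0 <- sum(i0)
  w <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  score <- d^2 - gamma * w
  ord <- order(-score, colnames(X))
  structure(
    data.frame(feature = colnames(X)[ord], score = unname(score[ord]),
               stringsAsFactors = FALSE),
    gamma = gamma, class = c("blp_ranking", "data.frame"))
}

## Default wrapper criterion: mean stratified-CV MCC of a fixed-parameter
## RBF SVM.  Folds depend only on (y, folds, seed), so every candidate
## subset is evaluated on identical partitions (paired comparisons).
default_sbs_trainer <- function(C = 1, gamma_svm = NULL) {
  function(X, y, folds, seed) {
    fold <- stratified_folds(y, folds, seed)
    g <- gamma_svm %||% (1 / max(1L, ncol(X)))
    mccs <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      fit <- e1071::svm(X[tr, , drop = FALSE], factor(y[tr], levels = c(0, 1)),
                        kernel = "radial", cost = C, gamma = g, scale = FALSE)
      pred <- as.integer(as.character(
        stats::predict(fit, X[!tr, , drop = FALSE])))
      compute_metrics(confusion_counts(pred, y[!tr]))$mcc
    }, numeric(1))
    mean(mccs)
  }
}

#' Sequential backward selection (SBS)
#'
#' Walks backwards from the full feature set, eliminating the lowest-ranked
#' remaining feature (per the filter ranking) one step at a time and
#' re-evaluating the cross-validated criterion (mean MCC) after each
#' elimination; an eliminated feature is never reconsidered.  The walk stops
#' when `patience` consecutive steps have scored more than `slack` below the
#' best criterion seen (further elimination no longer achieves better
#' results), or at `min_features`.  The selected subset is the one at the
#' criterion's maximum along the walk — the smallest such subset when
#' several steps tie — so the final criterion is always at least the
#' all-features criterion, and steps explored beyond the maximum are
#' discarded rather than kept.
#'
#' `slack` absorbs the granularity of cross-validated MCC: at the validation
#' sizes the wrapper is used on, a single flipped prediction moves the mean
#' fold MCC by roughly 0.02, so treating every chance dip as a degradation
#' would halt the walk on the first fluctuation and defeat the purpose of
#' backward elimination.
#'
#' Features are standardized once (full-data mean/sd) before the wrapper
#' loop; the criterion re-runs CV training for every candidate subset on
#' fold partitions fixed by `seed`, so comparisons between subsets are
#' paired.
#'
#' @param X numeric feature matrix with named columns.
#' @param y binary 0/1 labels.
#' @param ranking a `blp_ranking` covering `X`'s columns; defaults to
#'   [fisher_markov_rank()] on (X, y).
#' @param trainer criterion callable `function(X, y, folds, seed) -> numeric`;
#'   defaults to mean stratified-CV MCC of a fixed-parameter RBF SVM whose
#'   kernel width is held at `1/ncol(X)` of the full matrix throughout the
#'   search (so the criterion responds to feature removal only, not to
#'   hyperparameter drift).
#' @param folds CV folds inside the wrapper (default 5).
#' @param seed integer seed (fold assignment).
#' @param patience consecutive below-best steps tolerated before stopping
#'   early; the default `Inf` walks the whole ranking, which is cheap at the
#'   dimensionalities the wrapper is used on and immune to chance spikes in
#'   the criterion.
#' @param slack tolerated criterion decrease while exploring (default 0.02).
#' @param min_features lower bound on subset size (default 1).
#' @return a `blp_selection`: list with `selected` (feature names),
#'   `trajectory` (data frame, one row per explored step: n_features,
#'   criterion; row 1 is the full set) and `criterion` ("mcc").
#' @export
sbs_select <- function(X, y, ranking = NULL, trainer = NULL, folds = 5L,
                       seed = 1L, patience = Inf, slack = 0.02,
                       min_features = 1L) {
  y <- as.integer(y)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (is.null(ranking)) ranking <- fisher_markov_rank(X, y)
  if (!setequal(ranking$feature, colnames(X)))
    stop("ranking does not cover X's columns")
  if (is.null(trainer)) trainer <- default_sbs_trainer(gamma_svm = 1 / ncol(X))
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  sdev[sdev == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdev, "/")

  current <- colnames(X)
  crits <- trainer(Xs[, current, drop = FALSE], y, folds, seed)
  best <- crits[1]
  removed <- character(0)
  below <- 0L
  # eliminate in ascending score order: worst-ranked features go first
  for (f in rev(ranking$feature)) {
    if (length(current) <= min_features) break
    current <- setdiff(current, f)
    removed <- c(removed, f)
    c2 <- trainer(Xs[, current, drop = FALSE], y, folds, seed)
    crits <- c(crits, c2)
    if (c2 >= best - slack) {
      below <- 0L
      best <- max(best, c2)
    } else {
      below <- below + 1L
      if (below >= patience) break
    }
  }
  # smallest subset whose criterion is within slack of the best: prefers
  # parsimony across the plateau that backward elimination typically traces
  hits <- which(crits >= max(crits) - slack)
  pick <- hits[length(hits)]
  selected <- setdiff(colnames(X), removed[seq_len(pick - 1L)])
  structure(list(selected = selected,
                 trajectory = data.frame(
                   n_features = ncol(X) - (seq_along(crits) - 1L),
                   criterion = crits),
                 criterion = "mcc"),
            class = "blp_selection")
}

#' @export
print.blp_selection <- function(x, ...) {
  cat(sprintf("<blp_selection> %d features kept (criterion %s = %.3f)\n",
              length(x$selected), x$criterion,
              x$trajectory$criterion[nrow(x$trajectory)]))
  invisible(x)
}

#' Serialize a selection result to JSON
#' @param result a `blp_selection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(result, path) {
  jsonlite::write_json(
    list(selected = result$selected,
         trajectory = result$trajectory,
         criterion = result$criterion),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
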