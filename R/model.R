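MODEL_VERSION <- 1L

#' Pipeline configuration
#'
#' Collects every tunable of the training pipeline with the method's
#' published defaults where stated: motif frequency threshold `T = 0.10`,
#' `top_k = 10` motifs, five CV folds, and the canonical coarse
#' log2-spaced SVM grid.
#'
#' @param threshold_T motif occurrence-frequency threshold.
#' @param top_k number of motifs kept in the catalog.
#' @param folds CV folds used in grid search (and SBS).
#' @param blocks feature blocks to assemble.
#' @param cost_grid,gamma_grid SVM grid-search ranges.
#' @param gamma_fms regularization of the filter ranking.
#' @param do_sbs run the SBS wrapper inside training (off by default; the
#'   wrapper multiplies training cost and is usually run once, standalone).
#' @param sbs_patience,sbs_slack,sbs_min_features SBS stopping knobs, see
#'   [sbs_select()].
#' @param property_table a `pcp_table` (defaults to the shipped scales).
#' @param catalog optional pre-built `motif_catalog`; when supplied, motif
#'   discovery is skipped (e.g. to emulate discovery on a full dataset
#'   rather than inside each CV fold).
#' @param dispatch_policy lineage dispatch for ensembles.
#' @return a named list of class `blp_config`.
#' @export
default_config <- function(threshold_T = 0.10,
                           top_k = 10L,
                           folds = 5L,
                           blocks = c("AAC", "DC", "MTF", "PCP"),
                           cost_grid = 2^seq(-5, 15, by = 2),
                           gamma_grid = 2^seq(-15, 3, by = 2),
                           gamma_fms = 0,
                           do_sbs = FALSE,
                           sbs_patience = 2L,
                           sbs_slack = 0.02,
                           sbs_min_features = 1L,
                           property_table = NULL,
                           catalog = NULL,
                           dispatch_policy = c("lineage_if_available_else_universal",
                                               "universal_only")) {
  structure(list(
    threshold_T = threshold_T, top_k = top_k, folds = folds,
    blocks = blocks, cost_grid = cost_grid, gamma_grid = gamma_grid,
    gamma_fms = gamma_fms, do_sbs = do_sbs, sbs_patience = sbs_patience,
    sbs_slack = sbs_slack, sbs_min_features = sbs_min_features,
    property_table = property_table %||% load_property_table(),
    catalog = catalog,
    dispatch_policy = match.arg(dispatch_policy)
  ), class = "blp_config")
}

#' A reduced grid for quick experiments
#'
#' Same structure as [default_config()] but with a coarse 4x4 SVM grid
#' bracketing `gamma = 1/d` for the feature dimensionalities this package
#' produces (tens to hundreds of standardized features); useful for
#' simulations and examples where the full 110-point grid is unnecessary.
#' @param ... overrides passed on to [default_config()].
#' @return a `blp_config`.
#' @export
fast_config <- function(...) {
  default_config(cost_grid = 2^c(-1, 2, 5, 8),
                 gamma_grid = 2^c(-11, -8, -5, -2), ...)
}

#' Train an RBF-SVM with grid search
#'
#' Evaluates every (C, gamma) combination by stratified k-fold CV, choosing
#' the pair maximizing mean CV MCC (ties: smaller C, then smaller gamma);
#' refits on all data with the winning pair.  Standardization parameters are
#' learned from the training data only and stored with the model.  A
#' monotone sigmoid calibration (logistic fit of the training labels on the
#' SVM decision values) maps margins to \[0, 1\] propensity scores; being a
#' deterministic monotone map, it leaves ROC ordering untouched.
#'
#' @param X numeric feature matrix with named columns.
#' @param y binary 0/1 labels.
#' @param cost_grid,gamma_grid grid ranges (defaults: the canonical coarse
#'   grid `C = 2^(-5..15)`, `gamma = 2^(-15..3)`, log2 step 2).
#' @param folds CV folds for the grid search (default 5).
#' @param seed integer seed (fold assignment only; fitting is
#'   deterministic).
#' @return a `blp_model`: SVM fit plus feature mask, scaling, calibration,
#'   chosen (C, gamma), CV MCC and lineage scope.
#' @export
grid_search_train <- function(X, y,
                              cost_grid = 2^seq(-5, 15, by = 2),
                              gamma_grid = 2^seq(-15, 3, by = 2),
                              folds = 5L, seed = 1L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("need both classes to train")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (min(table(y)) < folds)
    stop("fewer samples than folds in one class; stratification impossible")
  fold <- stratified_folds(y, folds, seed)
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  sdev[sdev == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdev, "/")

  grid <- expand.grid(C = sort(cost_grid), gamma = sort(gamma_grid))
  yf <- factor(y, levels = c(0, 1))
  cv_mcc <- vapply(seq_len(nrow(grid)), function(i) {
    mean(vapply(seq_len(folds), function(f) {
      tr <- fold != f
      fit <- e1071::svm(Xs[tr, , drop = FALSE], yf[tr], kernel = "radial",
                        cost = grid$C[i], gamma = grid$gamma[i], scale = FALSE)
      pred <- as.integer(as.character(
        stats::predict(fit, Xs[!tr, , drop = FALSE])))
      compute_metrics(confusion_counts(pred, y[!tr]))$mcc
    }, numeric(1)))
  }, numeric(1))
  best <- which(cv_mcc == max(cv_mcc))[1]  # grid ordered by C then gamma

  fit <- e1071::svm(Xs, yf, kernel = "radial",
                    cost = grid$C[best], gamma = grid$gamma[best],
                    scale = FALSE)
  dv <- as.numeric(attr(stats::predict(fit, Xs, decision.values = TRUE),
                        "decision.values"))
  calib <- suppressWarnings(
    stats::glm.fit(cbind(1, dv), y, family = stats::binomial())$coefficients)
  calib[is.na(calib)] <- 0  # constant decision values: flat calibration
  structure(list(
    svm = fit, feature_mask = colnames(X),
    center = mu, scale = sdev, calibration = calib,
    C = grid$C[best], gamma = grid$gamma[best], cv_mcc = max(cv_mcc),
    lineage_scope = "universal", featurizer = NULL,
    n_train = nrow(X), version = MODEL_VERSION
  ), class = "blp_model")
}

#' @export
print.blp_model <- function(x, ...) {
  cat(sprintf("<blp_model> scope=%s, %d features, C=%g, gamma=%g, CV MCC=%.3f\n",
              x$lineage_scope, length(x$feature_mask), x$C, x$gamma, x$cv_mcc))
  invisible(x)
}

featurize_for_model <- function(model, data) {
  fz <- model$featurizer
  if (is.null(fz))
    stop("model has no featurizer; supply a feature matrix instead of sequences")
  feature_matrix(data, catalog = fz$catalog, table = fz$property_table,
                 blocks = fz$blocks)
}

#' Predict with a trained model
#'
#' Accepts either a numeric feature matrix whose columns cover the model's
#' feature mask, or a `blp_dataset` (sequences are encoded with the
#' featurizer stored at training time).  Masking, standardization and score
#' calibration are applied internally.
#'
#' @param object a `blp_model`.
#' @param newdata feature matrix or `blp_dataset`.
#' @param ... unused.
#' @return data frame with columns `id`, `score` (propensity in \[0, 1\])
#'   and `label` (0/1 at the 0.5 threshold).
#' @export
predict.blp_model <- function(object, newdata, ...) {
  if (inherits(newdata, "blp_dataset")) {
    ids <- newdata$id
    X <- featurize_for_model(object, newdata)
  } else {
    X <- as.matrix(newdata)
    ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
  }
  missing <- setdiff(object$feature_mask, colnames(X))
  if (length(missing) > 0L)
    stop("missing feature(s): ", paste(utils::head(missing, 10), collapse = ", "))
  X <- X[, object$feature_mask, drop = FALSE]
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  dv <- as.numeric(attr(stats::predict(object$svm, Xs, decision.values = TRUE),
                        "decision.values"))
  score <- stats::plogis(object$calibration[1] + object$calibration[2] * dv)
  data.frame(id = ids, score = score,
             label = as.integer(score >= 0.5),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Train the full pipeline on a labelled dataset
#'
#' Runs, on the given data only: motif discovery (unless a catalog is
#' supplied in the config), feature assembly, optional filter+wrapper
#' feature selection, and grid-search SVM training.  The returned model
#' carries everything needed to encode and score raw sequences.
#'
#' @param data labelled `blp_dataset`.
#' @param config a `blp_config`, see [default_config()].
#' @param seed integer seed.
#' @param scope lineage scope label stored on the model.
#' @return a `blp_model` with an embedded featurizer (motif catalog,
#'   property table, block set) and, when selection ran, the `blp_selection`
#'   in field `selection`.
#' @export
train_pipeline <- function(data, config = default_config(), seed = 1L,
                           scope = "universal") {
  cc <- class_counts(data)
  if (any(cc == 0L)) stop("both classes required for training")
  labelled <- data[!is.na(data$label), , drop = FALSE]
  catalog <- config$catalog
  if ("MTF" %in% config$blocks && is.null(catalog)) {
    catalog <- suppressWarnings(discover_motifs(
      labelled[labelled$label == 1L, , drop = FALSE],
      labelled[labelled$label == 0L, , drop = FALSE],
      threshold_T = config$threshold_T, top_k = config$top_k))
  }
  blocks <- config$blocks
  if ("MTF" %in% blocks && (is.null(catalog) || nrow(catalog) == 0L)) {
    warning("empty motif catalog; MTF block dropped for this model")
    blocks <- setdiff(blocks, "MTF")
  }
  X <- feature_matrix(labelled, catalog = catalog,
                      table = config$property_table, blocks = blocks)
  y <- labelled$label
  sel <- NULL
  if (isTRUE(config$do_sbs)) {
    ranking <- fisher_markov_rank(X, y, gamma = config$gamma_fms)
    sel <- sbs_select(X, y, ranking = ranking, folds = config$folds,
                      seed = seed, patience = config$sbs_patience,
                      slack = config$sbs_slack,
                      min_features = config$sbs_min_features)
    X <- X[, sel$selected, drop = FALSE]
  }
  model <- grid_search_train(X, y, cost_grid = config$cost_grid,
                             gamma_grid = config$gamma_grid,
                             folds = config$folds, seed = seed)
  model$featurizer <- list(catalog = catalog,
                           property_table = config$property_table,
                           blocks = blocks)
  model$selection <- sel
  model$lineage_scope <- scope
  model
}

#' Train a lineage-specific model ensemble
#'
#' Fits one universal model on the pooled dataset and, for every lineage
#' dataset with at least `min_per_class` records per class, an independent
#' lineage-specific model (each with its own motif catalog, selection and
#' grid search).  Queries are dispatched by lineage tag, falling back to the
#' universal model for lineages without their own model.
#'
#' @param datasets named list of labelled `blp_dataset`s; must contain
#'   `universal`, may contain `bacteria`, `eukaryota`, `archaea`.
#' @param config a `blp_config`.
#' @param seed integer seed.
#' @param min_per_class minimum class size for a lineage model (default 10).
#' @return a `blp_ensemble`.
#' @export
train_ensemble <- function(datasets, config = default_config(), seed = 1L,
                           min_per_class = 10L) {
  if (is.null(datasets$universal)) stop("`datasets$universal` is required")
  universal <- train_pipeline(datasets$universal, config, seed = seed,
                              scope = "universal")
  per_lineage <- list()
  for (lin in intersect(c("bacteria", "eukaryota", "archaea"),
                        names(datasets))) {
    cc <- class_counts(datasets[[lin]])
    if (any(cc < min_per_class)) {
      warning("lineage ", lin, " has fewer than ", min_per_class,
              " records per class; skipped (universal fallback applies)")
      next
    }
    per_lineage[[lin]] <- train_pipeline(datasets[[lin]], config,
                                         seed = seed, scope = lin)
  }
  structure(list(universal = universal, per_lineage = per_lineage,
                 dispatch_policy = config$dispatch_policy),
            class = "blp_ensemble")
}

#' Which model serves a lineage tag?
#' @param ensemble a `blp_ensemble`.
#' @param lineage a lineage tag.
#' @return the scope name of the dispatched model.
#' @export
dispatch_scope <- function(ensemble, lineage) {
  if (ensemble$dispatch_policy == "universal_only") return("universal")
  if (lineage %in% names(ensemble$per_lineage)) lineage else "universal"
}

#' Predict with a lineage ensemble
#'
#' Every record is routed to exactly one model according to its lineage tag
#' and the ensemble's dispatch policy.
#'
#' @param object a `blp_ensemble`.
#' @param newdata a `blp_dataset` (lineage tags drive dispatch).
#' @param ... unused.
#' @return data frame `id`, `score`, `label`, `model_used`.
#' @export
predict.blp_ensemble <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "blp_dataset"))
  scope <- vapply(newdata$lineage, function(l) dispatch_scope(object, l),
                  character(1), USE.NAMES = FALSE)
  out <- vector("list", length(unique(scope)))
  names(out) <- unique(scope)
  for (s in unique(scope)) {
    sub <- newdata[scope == s, , drop = FALSE]
    model <- if (s == "universal") object$universal else object$per_lineage[[s]]
    p <- stats::predict(model, sub)
    p$model_used <- s
    out[[s]] <- p
  }
  res <- do.call(rbind, out)
  res <- res[match(newdata$id, res$id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Save / load a trained model or ensemble
#'
#' Persists a versioned archive (RDS) of the model, its feature mask,
#' scaling, calibration and featurizer; loading refuses archives written by
#' an incompatible package version.  Predictions after a save/load round
#' trip are bit-identical.
#'
#' @param model a `blp_model` or `blp_ensemble`.
#' @param path archive path.
#' @return `path` (save) / the model (load).
#' @export
save_model <- function(model, path) {
  saveRDS(list(format_version = MODEL_VERSION, payload = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  archive <- readRDS(path)
  if (!identical(archive$format_version, MODEL_VERSION))
    stop("incompatible model archive version: ", archive$format_version,
         " (this package reads version ", MODEL_VERSION, ")")
  archive$payload
}
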