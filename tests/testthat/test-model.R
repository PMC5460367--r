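sep2d <- function(seed, n = 60) {
  # two well-separated Gaussian blobs in 2-D
  y <- rep(c(0L, 1L), each = n / 2)
  X <- lumipred:::with_seed(seed,
    cbind(x1 = stats::rnorm(n, mean = ifelse(y == 1, 3, 0), sd = 0.5),
          x2 = stats::rnorm(n, mean = ifelse(y == 1, -3, 0), sd = 0.5)))
  list(X = X, y = y)
}

test_that("grid_search_train separates separable data and is seed-deterministic", {
  d <- sep2d(1)
  m <- grid_search_train(d$X, d$y, cost_grid = 2^c(0, 3),
                         gamma_grid = 2^c(-3, 0), folds = 5, seed = 1)
  expect_s3_class(m, "blp_model")
  pred <- predict(m, d$X)
  expect_equal(pred$label, d$y)            # training accuracy 1.0
  expect_equal(m$cv_mcc, 1)
  m2 <- grid_search_train(d$X, d$y, cost_grid = 2^c(0, 3),
                          gamma_grid = 2^c(-3, 0), folds = 5, seed = 1)
  expect_identical(c(m$C, m$gamma), c(m2$C, m2$gamma))
})

test_that("permuted labels give near-zero cross-validated MCC", {
  mccs <- sapply(1:3, function(s) {
    n <- 200
    y <- rep(c(0L, 1L), each = n / 2)
    X <- lumipred:::with_seed(s, {
      X <- cbind(a = stats::rnorm(n, ifelse(y == 1, 2, 0)),
                 b = stats::rnorm(n))
      X[sample(n), ]  # decouple rows from labels
    })
    grid_search_train(X, y, cost_grid = 2^c(0, 4), gamma_grid = 2^c(-5, -1),
                      folds = 5, seed = s)$cv_mcc
  })
  expect_true(all(abs(mccs) < 0.2))
})

test_that("predict applies masking and scaling, and is row-independent", {
  d <- sep2d(2)
  m <- grid_search_train(d$X, d$y, cost_grid = 2, gamma_grid = 0.25,
                         folds = 3, seed = 2)
  p <- predict(m, d$X)
  expect_true(all(p$score >= 0 & p$score <= 1))
  perm <- c(5, 1, 30, 12)
  p2 <- predict(m, d$X[perm, ])
  expect_equal(p2$score, p$score[perm])
  # extra columns are ignored; missing columns are named in the error
  extra <- cbind(d$X, junk = 1)
  expect_equal(predict(m, extra)$score, p$score)
  expect_error(predict(m, d$X[, "x1", drop = FALSE]), "x2")
})

test_that("models survive a save/load round trip bit-exactly", {
  d <- tiny_planted(seed = 9, n = 15)
  m <- train_pipeline(d, test_config(), seed = 9)
  before <- predict(m, d)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict(m2, d)$score, before$score)
  # version guard
  raw <- readRDS(path)
  raw$format_version <- 999L
  saveRDS(raw, path)
  expect_error(load_model(path), "incompatible")
})

test_that("train_pipeline embeds a featurizer and respects block choice", {
  d <- tiny_planted(seed = 10, n = 15)
  m <- train_pipeline(d, test_config(blocks = c("AAC", "MTF")), seed = 1)
  expect_length(m$feature_mask, 20 + 10)
  expect_s3_class(m$featurizer$catalog, "motif_catalog")
  # prediction from raw sequences works end to end
  p <- predict(m, d)
  expect_equal(nrow(p), nrow(d))
})

test_that("the lineage ensemble dispatches by tag with universal fallback", {
  duni <- tiny_planted(seed = 12, n = 14)
  dbac <- tiny_planted(seed = 13, n = 12)
  dbac$lineage <- "bacteria"
  dbac$id <- paste0("bac_", dbac$id)
  cfg <- test_config(blocks = c("AAC", "PCP"))
  ens <- train_ensemble(list(universal = duni, bacteria = dbac), cfg, seed = 3)
  expect_s3_class(ens, "blp_ensemble")
  expect_equal(dispatch_scope(ens, "bacteria"), "bacteria")
  expect_equal(dispatch_scope(ens, "eukaryota"), "universal")
  expect_equal(dispatch_scope(ens, "unknown"), "universal")
  q <- rbind(as.data.frame(dbac[1:3, ]), as.data.frame(duni[1:3, ]))
  q <- new_dataset(q$id, q$sequence, q$label, q$lineage)
  p <- predict(ens, q)
  expect_equal(p$model_used, rep(c("bacteria", "universal"), each = 3))
  expect_equal(p$id, q$id)
  # universal_only policy routes everything to the universal model
  cfg2 <- test_config(blocks = c("AAC", "PCP"),
                      dispatch_policy = "universal_only")
  ens2 <- train_ensemble(list(universal = duni, bacteria = dbac), cfg2, seed = 3)
  expect_equal(predict(ens2, q)$model_used, rep("universal", 6))
})

test_that("undersized lineage datasets are skipped with a warning", {
  duni <- tiny_planted(seed = 14, n = 14)
  tiny <- tiny_planted(seed = 15, n = 4)
  tiny$lineage <- "archaea"
  tiny$id <- paste0("arc_", tiny$id)
  cfg <- test_config(blocks = c("AAC", "PCP"))
  expect_warning(
    ens <- train_ensemble(list(universal = duni, archaea = tiny), cfg, seed = 1),
    "fewer than")
  expect_length(ens$per_lineage, 0L)
  expect_equal(dispatch_scope(ens, "archaea"), "universal")
})
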