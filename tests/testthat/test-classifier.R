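test_that("train_forest honours its contract on a separable toy set", {
  d <- separable_xy(n = 60, seed = 1L)
  model <- train_forest(d$X, d$y, rng_seed = 1L)
  expect_s3_class(model, "ggi_forest")
  expect_length(model$trees, 100)                 # default tree count
  expect_equal(model$features_per_split, floor(log2(22)) + 1)
  p <- predict(model, d$X)
  expect_equal(p$labels, d$y)                     # separable: training acc 1
  expect_true(all(p$scores >= 0 & p$scores <= 1))

  # split features always within the feature set
  for (tr in model$trees[1:10]) {
    f <- tr[, "feature"]
    expect_true(all(f >= 0 & f <= ncol(d$X)))
  }
  expect_error(train_forest(d$X, rep(1L, 60)), "single class")
})

test_that("training is deterministic given data and seed", {
  d <- separable_xy(n = 40, seed = 2L)
  m1 <- train_forest(d$X, d$y, t = 30, rng_seed = 9L)
  m2 <- train_forest(d$X, d$y, t = 30, rng_seed = 9L)
  set.seed(123)
  grid <- matrix(rnorm(50 * 22), 50, 22, dimnames = list(NULL, colnames(d$X)))
  expect_identical(predict(m1, grid), predict(m2, grid))
  m3 <- train_forest(d$X, d$y, t = 30, rng_seed = 10L)
  expect_false(identical(predict(m1, grid)$scores, predict(m3, grid)$scores))
})

test_that("vote aggregation and the 50/50 tie-break follow the contract", {
  X <- matrix(0, 1, 2, dimnames = list(NULL, c("x", "y")))
  expect_equal(predict(stub_forest(c(1, 1, 1, 1)), X)$labels, 1L)
  expect_equal(predict(stub_forest(c(1, 1, 1, 1)), X)$scores, 1)
  tie <- predict(stub_forest(rep(c(0, 1), 50)), X)
  expect_equal(tie$scores, 0.5)
  expect_equal(tie$labels, 0L)                    # tie resolves to class 0
  expect_error(predict(stub_forest(1), matrix(0, 1, 3)), "feature columns")
})

test_that("a single unlimited-depth tree memorises distinct instances", {
  # bootstrap_n = n with one tree cannot be asserted instance-wise (the
  # bootstrap omits ~37%), so use many trees: every training point with a
  # unique feature signature must be reproduced by the ensemble
  set.seed(4)
  X <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rep(c(0L, 1L), 10)
  model <- train_forest(X, y, t = 200, features_per_split = 3, rng_seed = 4L)
  expect_equal(predict(model, X)$labels, y)
})

test_that("cross_validate stratifies, reports and orders sanely", {
  d <- separable_xy(n = 80, seed = 3L)
  ev <- cross_validate(d$X, d$y, folds = 10, rng_seed = 3L, t = 50)
  expect_s3_class(ev, "ggi_evaluation")
  w <- ev$weighted
  expect_true(all(unlist(w) >= 0 & unlist(w) <= 1))
  expect_equal(w$accuracy, 1)                     # separable case
  expect_equal(w$roc_area, 1)
  expect_equal(nrow(ev$per_fold), 10)
  expect_equal(sum(ev$per_fold$n), 80)
  # training-set accuracy >= out-of-fold accuracy
  model <- train_forest(d$X, d$y, rng_seed = 3L)
  train_acc <- mean(predict(model, d$X)$labels == d$y)
  expect_gte(train_acc, w$accuracy)
  expect_error(cross_validate(d$X[1:12, ], d$y[1:12], folds = 10),
               "at least")
})

test_that("weighted metrics equal hand-computed confusion arithmetic", {
  truth <- c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0)
  pred  <- c(1, 1, 1, 1, 0, 0, 0, 0, 1, 0)
  m <- confusion_metrics(truth, pred)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.6 * 4 / 5 + 0.4 * 3 / 5)
  expect_equal(m$recall, 0.6 * 4 / 6 + 0.4 * 3 / 4)
  f1 <- 2 * (4 / 5) * (4 / 6) / (4 / 5 + 4 / 6)
  f0 <- 2 * (3 / 5) * (3 / 4) / (3 / 5 + 3 / 4)
  expect_equal(m$f_measure, 0.6 * f1 + 0.4 * f0)
  expect_equal(unname(m$confusion["1", "1"]), 4)
})

test_that("ROC area behaves at its analytic anchors", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  # all-tied scores give 0.5 exactly (single diagonal segment)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(11)
  expect_equal(roc_auc(runif(2000), rep(c(0, 1), 1000)), 0.5,
               tolerance = 0.05)
})

test_that("impurity importance is normalised and finds a planted signal", {
  d <- separable_xy(n = 100, seed = 5L)
  model <- train_forest(d$X, d$y, rng_seed = 5L)
  imp <- feature_importance(model)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_equal(imp$feature[1], "f1")              # the only informative one
  expect_true(all(diff(imp$importance) <= 0))
})

test_that("a saved model reloads to identical predictions", {
  dir <- withr::local_tempdir()
  d <- separable_xy(n = 40, seed = 6L)
  model <- train_forest(d$X, d$y, t = 20, rng_seed = 6L)
  save_forest(model, file.path(dir, "m.json"))
  back <- load_forest(file.path(dir, "m.json"))
  set.seed(99)
  grid <- matrix(rnorm(30 * 22), 30, 22, dimnames = list(NULL, colnames(d$X)))
  expect_identical(predict(back, grid), predict(model, grid))
  expect_equal(back$importance, model$importance)
})

test_that("more trees do not hurt median CV accuracy", {
  acc <- sapply(1:5, function(s) {
    sim <- simulate_dataset(small_config(100L + s))
    ds <- suppressMessages(zscore_normalise(sim$dataset))
    ls <- build_labeled_set(sim$answer_set, sim$net, sim$seeds, ds, rng_seed = s)
    pairs <- Map(pair_from_dataset, list(ds), ls$pairs$gene_a, ls$pairs$gene_b)
    X <- feature_matrix(pairs, rng_seed = s)
    c(t10 = cross_validate(X, ls$pairs$label, folds = 5, rng_seed = s,
                           t = 10)$weighted$accuracy,
      t100 = cross_validate(X, ls$pairs$label, folds = 5, rng_seed = s,
                            t = 100)$weighted$accuracy)
  })
  expect_gte(median(acc["t100", ]), median(acc["t10", ]))
})

test_that("evaluation report exports the five weighted metrics as JSON", {
  dir <- withr::local_tempdir()
  d <- separable_xy(n = 40, seed = 7L)
  ev <- cross_validate(d$X, d$y, folds = 5, rng_seed = 7L, t = 20)
  write_evaluation(ev, file.path(dir, "ev.json"))
  back <- jsonlite::fromJSON(file.path(dir, "ev.json"))
  expect_named(back$weighted,
               c("accuracy", "precision", "recall", "f_measure", "roc_area"))
  expect_equal(back$weighted$accuracy, ev$weighted$accuracy)
  expect_equal(nrow(back$per_fold), 5)
})
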