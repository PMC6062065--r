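#' Train a random forest on pair feature vectors
#'
#' Grows `t` CART-style trees, each on a bootstrap sample of the training
#' instances, choosing at every node the best Gini-impurity split among a
#' random subset of `features_per_split` features, until leaves are pure
#' or hold fewer than two instances.  Class votes are aggregated at
#' prediction time.  Fully deterministic given `rng_seed`.
#'
#' `features_per_split` defaults to `floor(log2(M)) + 1` (5 for the 22
#' pair features), the standard convention for classification forests.
#' `bootstrap_n` defaults to the training-set size; a fixed value (e.g.
#' 100) reproduces the fixed-instance-count variant literally.
#'
#' @param X numeric feature matrix (rows = pairs, columns = features).
#' @param y 0/1 labels, both classes present.
#' @param t number of trees (default 100).
#' @param features_per_split candidate features per node; default
#'   `floor(log2(ncol(X))) + 1`.
#' @param bootstrap_n bootstrap sample size per tree; default `nrow(X)`.
#' @param rng_seed integer seed.
#' @return an object of class `ggi_forest` with elements `trees` (list of
#'   node matrices), `importance`, `n_trees`, `features_per_split`,
#'   `feature_names`, `class_counts`, `rng_seed`.
#' @export
train_forest <- function(X, y, t = 100L, features_per_split = NULL,
                         bootstrap_n = NULL, rng_seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  if (any(!is.finite(X))) stop("non-finite feature value")
  if (is.null(features_per_split)) {
    features_per_split <- floor(log2(ncol(X))) + 1L
  }
  if (is.null(bootstrap_n)) bootstrap_n <- nrow(X)
  fit <- with_seed(rng_seed,
                   grow_forest_cpp(X, y, as.integer(t),
                                   as.integer(features_per_split),
                                   as.integer(bootstrap_n), 2L))
  structure(
    list(trees = fit$trees,
         importance = setNames(fit$importance, colnames(X)),
         n_trees = as.integer(t),
         features_per_split = as.integer(features_per_split),
         bootstrap_n = as.integer(bootstrap_n),
         feature_names = colnames(X),
         class_counts = c(`0` = sum(y == 0L), `1` = sum(y == 1L)),
         rng_seed = as.integer(rng_seed)),
    class = "ggi_forest"
  )
}

#' @export
print.ggi_forest <- function(x, ...) {
  cat(sprintf(
    "ggi_forest: %d trees, %d features/split, trained on %d+%d instances\n",
    x$n_trees, x$features_per_split, x$class_counts[["0"]],
    x$class_counts[["1"]]))
  invisible(x)
}

#' Predict interaction labels and vote scores
#'
#' Each tree votes the majority class of the leaf an instance falls into;
#' the score is the fraction of trees voting class 1.  The label is 1 when
#' the score exceeds 0.5; an exact 50/50 tie is resolved to class 0.
#'
#' @param object a `ggi_forest`.
#' @param X feature matrix with the model's feature columns in order.
#' @param ... unused.
#' @return list with integer `labels` and numeric `scores`.
#' @export
predict.ggi_forest <- function(object, X, ...) {
  X <- as.matrix(X)
  if (!is.null(colnames(X)) &&
      !identical(colnames(X), object$feature_names)) {
    stop("feature columns do not match the trained model")
  }
  if (ncol(X) != length(object$feature_names)) {
    stop("feature columns do not match the trained model")
  }
  scores <- predict_forest_cpp(object$trees, X)
  list(labels = as.integer(scores > 0.5), scores = as.numeric(scores))
}

#' Impurity-based feature importance ranking
#'
#' Mean decrease in Gini impurity per feature (weighted by the fraction of
#' bootstrap instances reaching each split, averaged over trees),
#' normalised to sum to 1, in descending order; ties keep the fixed
#' feature-column order.
#'
#' @param model a `ggi_forest`.
#' @return data frame with columns `feature` and `importance`, sorted
#'   descending.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "ggi_forest"))
  imp <- model$importance
  total <- sum(imp)
  if (total > 0) imp <- imp / total
  ord <- order(-imp, seq_along(imp))
  data.frame(feature = names(imp)[ord], importance = unname(imp[ord]),
             stringsAsFactors = FALSE)
}

#' Serialise a trained forest to a JSON file
#'
#' Versioned plain-text format; [load_forest()] restores a model making
#' bit-identical predictions (thresholds are written with full double
#' precision).
#'
#' @param model a `ggi_forest`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_forest <- function(model, path) {
  stopifnot(inherits(model, "ggi_forest"))
  payload <- list(
    format = "ggiforest-model", version = 1L,
    n_trees = model$n_trees, features_per_split = model$features_per_split,
    bootstrap_n = model$bootstrap_n, rng_seed = model$rng_seed,
    feature_names = model$feature_names,
    class_counts = as.list(model$class_counts),
    importance = as.list(model$importance),
    trees = lapply(model$trees, function(m) unclass(as.data.frame(m)))
  )
  writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' Load a forest saved by [save_forest()]
#' @param path JSON path.
#' @return a `ggi_forest`.
#' @export
load_forest <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE)
  if (!identical(p$format, "ggiforest-model")) {
    stop("not a ggiforest model file: ", path)
  }
  cols <- c("feature", "threshold", "left", "right", "n0", "n1")
  trees <- lapply(p$trees, function(df) {
    m <- as.matrix(as.data.frame(df)[, cols])
    dimnames(m) <- list(NULL, cols)
    m
  })
  structure(
    list(trees = trees,
         importance = setNames(as.numeric(p$importance), names(p$importance)),
         n_trees = as.integer(p$n_trees),
         features_per_split = as.integer(p$features_per_split),
         bootstrap_n = as.integer(p$bootstrap_n),
         feature_names = as.character(p$feature_names),
         class_counts = setNames(as.integer(unlist(p$class_counts)),
                                 names(p$class_counts)),
         rng_seed = as.integer(p$rng_seed)),
    class = "ggi_forest"
  )
}
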