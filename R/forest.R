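# Random-forest classifier wrapper (compact CART forest implemented in C++).

#' Train a random forest on a feature table
#'
#' Bootstrap-aggregated CART trees with Gini splits; `mtry = floor(sqrt(p))`
#' features per split; trees grown to purity (unlimited depth up to a safety
#' cap). Class probabilities are the vote fractions of per-tree majority
#' leaves. Training is deterministic given `seed`.
#'
#' @param features Numeric matrix (rows = voxels) with feature column names.
#' @param labels Integer class labels in 0..4 (at least two classes).
#' @param n_trees Number of trees (default 100).
#' @param mtry Features per split; default `floor(sqrt(ncol(features)))`.
#' @param min_node Minimum node size (default 1).
#' @param max_depth Depth safety cap (default 30).
#' @param seed Integer RNG seed.
#' @return An object of class `gx_forest`.
#' @export
train_forest <- function(features, labels, n_trees = 100L, mtry = NULL,
                         min_node = 1L, max_depth = 30L, seed = 1L) {
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    stop("feature matrix must have column names")
  labels <- as.integer(labels)
  stopifnot(nrow(features) == length(labels))
  if (length(unique(labels)) < 2L)
    stop("training table contains a single class; need >= 2")
  if (any(labels < 0L | labels > 4L)) stop("labels must be in 0..4")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(features))))
  trees <- .rf_train_cpp(features, labels, 5L, as.integer(n_trees),
                         as.integer(mtry), as.integer(min_node),
                         as.integer(max_depth), as.integer(seed))
  structure(list(trees = trees, feature_names = colnames(features),
                 n_trees = as.integer(n_trees), mtry = as.integer(mtry),
                 classes = 0:4, seed = as.integer(seed),
                 class_counts = tabulate(labels + 1L, 5L)),
            class = "gx_forest")
}

#' @export
print.gx_forest <- function(x, ...) {
  cat("<gx_forest>", x$n_trees, "trees,", length(x$feature_names),
      "features, mtry", x$mtry, "\n")
  invisible(x)
}

.align_features <- function(model, features) {
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    stop("feature matrix must have column names")
  missing <- setdiff(model$feature_names, colnames(features))
  if (length(missing))
    stop("feature mismatch with model; missing: ",
         paste(head(missing, 5L), collapse = ", "))
  features[, model$feature_names, drop = FALSE]
}

#' Per-class probabilities from a trained forest
#'
#' Columns are realigned to the model's training feature names, so column
#' order does not matter.
#'
#' @param model A `gx_forest`.
#' @param features Numeric matrix with named columns.
#' @return n x 5 matrix of probabilities (columns = classes 0..4), rows
#'   summing to 1.
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "gx_forest"))
  p <- .rf_predict_cpp(model$trees, .align_features(model, features), 5L)
  colnames(p) <- as.character(0:4)
  p
}

#' Predicted classes from a trained forest
#'
#' Argmax of [predict_proba()]; probability ties break toward the lower
#' class label.
#'
#' @inheritParams predict_proba
#' @return Integer vector of class labels in 0..4.
#' @export
predict_class <- function(model, features) {
  p <- predict_proba(model, features)
  max.col(p, ties.method = "first") - 1L
}
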