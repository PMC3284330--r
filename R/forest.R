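# Ensemble-of-trees binary classifier contract shared by the per-term
# gene classifiers and the gene-pair edge classifiers: bootstrap-aggregated
# decision trees with out-of-bag vote fractions for training objects,
# predicted vote fractions for new objects, and per-feature importance.
# Backed by ranger (standard Breiman forest: bootstrap per tree,
# sqrt(n_features) candidates per split, Gini impurity, grown to purity).

#' Train a binary random forest with out-of-bag scores
#'
#' @param X feature table (matrix or sparse `dgCMatrix`), rows = objects;
#'   rownames identify objects.
#' @param y binary labels (0/1), one per row; both classes required.
#' @param n_trees ensemble size (default 100).
#' @param seed integer seed; fixed seed gives identical fits
#'   (training is single-threaded for exact reproducibility).
#' @param importance `"impurity"` (mean Gini decrease, default) or
#'   `"permutation"`.
#' @return object of class `forest_model`: the fitted ensemble plus
#'   `oob` (named out-of-bag positive-vote fractions; objects never
#'   out of bag — vanishingly rare at 100 trees — fall back to 0.5) and
#'   `importance` (named, nonnegative).
#' @export
train_forest <- function(X, y, n_trees = 100, seed = 1,
                         importance = c("impurity", "permutation")) {
  importance <- match.arg(importance)
  y <- as.integer(y)
  stopifnot(length(y) == nrow(X), all(y %in% 0:1))
  if (length(unique(y)) < 2)
    stop("single-class labels: cannot train a binary forest")
  df <- as.data.frame(as.matrix(X))
  colnames(df) <- make.names(colnames(df), unique = TRUE)
  fit <- ranger::ranger(
    x = df, y = factor(y, levels = 0:1),
    num.trees = n_trees, probability = TRUE,
    min.node.size = 1,   # grow to purity
    importance = importance, seed = seed, num.threads = 1
  )
  oob <- fit$predictions[, "1"]
  oob[is.nan(oob)] <- 0.5
  names(oob) <- rownames(X)
  imp <- fit$variable.importance
  names(imp) <- colnames(X)   # undo make.names
  structure(
    list(fit = fit, n_trees = n_trees, seed = seed,
         features = colnames(X), oob = oob, importance = imp),
    class = "forest_model"
  )
}

#' Predict positive-vote fractions for new objects
#'
#' @param object a `forest_model`.
#' @param X_new feature table with the training columns; rownames identify
#'   objects.
#' @param ... unused.
#' @return named numeric vector in `[0, 1]`.
#' @export
predict.forest_model <- function(object, X_new, ...) {
  df <- as.data.frame(as.matrix(X_new[, object$features, drop = FALSE]))
  colnames(df) <- make.names(colnames(df), unique = TRUE)
  p <- predict(object$fit, data = df, num.threads = 1)$predictions[, "1"]
  stats::setNames(p, rownames(X_new))
}

#' Ranked variable importance
#'
#' @param model a `forest_model`.
#' @return data frame `feature`, `importance`, sorted decreasing.
#' @export
variable_importance <- function(model) {
  stopifnot(inherits(model, "forest_model"))
  imp <- sort(model$importance, decreasing = TRUE)
  data.frame(feature = names(imp), importance = unname(imp),
             stringsAsFactors = FALSE)
}

#' @export
print.forest_model <- function(x, ...) {
  cat(sprintf("forest_model: %d trees, %d features, %d training objects\n",
              x$n_trees, length(x$features), length(x$oob)))
  invisible(x)
}
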