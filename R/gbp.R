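# Guilt by profiling: one random forest per selected term over the
# gene-centric feature set. Training genes annotated to the term are
# positives, the remaining training genes negatives (closed world);
# undetermined genes are never used in fitting. Training genes receive
# out-of-bag scores, undetermined genes predicted scores, and raw scores
# are mapped to log-likelihood ratios by class-conditional kernel density
# estimation so they can enter the combined log-odds.

#' Train the per-term guilt-by-profiling classifier
#'
#' @param term a selected term identifier.
#' @param fm the gene-centric [build_feature_matrix()] result (rows must
#'   cover training and undetermined genes).
#' @param a a filtered, propagated [annotation_set()].
#' @param training,undetermined the gene split from
#'   [split_training_undetermined()].
#' @param n_trees,seed forest parameters (see [train_forest()]).
#' @return object of class `gbp_term_result`: `term`, `scores` (named raw
#'   forest scores — OOB for training genes, predicted for undetermined),
#'   `set` (named factor: `train_pos`, `train_neg`, `undetermined`), `llr`
#'   (named log-likelihood ratios), `labels` (training genes only),
#'   `importance`.
#' @export
train_gbp_term <- function(term, fm, a, training, undetermined,
                           n_trees = 100, seed = 1) {
  pos <- intersect(training, term_index(a)[[term]])
  if (length(pos) < 1 || length(pos) >= length(training))
    stop("term ", term, " has no two-class training split")
  y <- stats::setNames(as.integer(training %in% pos), training)
  model <- train_forest(fm$matrix[training, , drop = FALSE], y,
                        n_trees = n_trees, seed = seed)
  scores <- model$oob
  undetermined <- intersect(undetermined, rownames(fm$matrix))
  if (length(undetermined))
    scores <- c(scores,
                predict(model, fm$matrix[undetermined, , drop = FALSE]))
  set <- stats::setNames(
    c(ifelse(training %in% pos, "train_pos", "train_neg"),
      rep("undetermined", length(undetermined))),
    c(training, undetermined)
  )
  llr <- gbp_score_to_llr(scores, y)
  structure(
    list(term = term, scores = scores, set = set, llr = llr,
         labels = y, importance = variable_importance(model)),
    class = "gbp_term_result"
  )
}

#' Map raw classifier scores to log-likelihood ratios
#'
#' `LLR(s) = log p_pos(s) - log p_neg(s)`, with `p_pos` and `p_neg`
#' Gaussian kernel densities of the positive and negative training-gene
#' out-of-bag scores, each augmented with the uniform `[0,1]` pseudo-count
#' component (see [fl_kde()]) and floored at `eps` so every LLR is finite.
#' The raw-score-to-LLR map for profile classifiers is an interpretive
#' choice of this package: only the likelihood-ratio scale is dictated by
#' the combination equation, not the calibration route (see the methods
#' vignette).
#'
#' @param scores named numeric vector of raw scores (any genes).
#' @param labels named 0/1 vector over the training genes.
#' @param eps density floor (default `1e-12`).
#' @param bw optional common bandwidth override.
#' @return named numeric vector of LLRs aligned to `scores`.
#' @export
gbp_score_to_llr <- function(scores, labels, eps = 1e-12, bw = NULL) {
  train <- intersect(names(labels), names(scores))
  pos <- scores[train][labels[train] == 1]
  neg <- scores[train][labels[train] == 0]
  stopifnot(length(pos) >= 1, length(neg) >= 1)
  kp <- fl_kde(pos, bw = bw)
  kn <- fl_kde(neg, bw = bw)
  llr <- log(pmax(kde_density(kp, scores), eps)) -
         log(pmax(kde_density(kn, scores), eps))
  stats::setNames(llr, names(scores))
}

#' @export
print.gbp_term_result <- function(x, ...) {
  cat(sprintf("gbp_term_result: %s (%d positives / %d training, %d undetermined)\n",
              x$term, sum(x$labels == 1), length(x$labels),
              sum(x$set == "undetermined")))
  invisible(x)
}
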