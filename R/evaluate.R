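# Precision-recall machinery: per-term curves on cross-validated scores,
# average precision, precision at fixed recall, decile-contour aggregation
# across a category's terms, and the prospective (temporal holdout)
# protocol.

#' Precision-recall curve
#'
#' One point per distinct score threshold `tau` (descending): precision is
#' the fraction of positives among objects scoring at least `tau`, recall
#' the fraction of all positives scoring at least `tau`. Tied scores are
#' handled pessimistically: every member of a tie block receives the
#' block's worst (block-end) precision, so the curve is deterministic and
#' independent of input order. Average precision is the mean, over
#' positives, of precision at that positive's threshold — the area under
#' the precision-recall step curve under this tie convention.
#'
#' @param scores named numeric vector (all scored objects).
#' @param positives character vector of true-positive names (at least 1).
#' @return data frame of class `pr_curve` with columns `threshold`,
#'   `n_pred`, `tp`, `precision`, `recall`, and attributes
#'   `average_precision` and `n_pos`.
#' @export
pr_curve <- function(scores, positives) {
  stopifnot(!is.null(names(scores)), length(positives) >= 1)
  positives <- unique(positives)
  n_pos <- length(positives)   # unscored positives cap the reachable recall
  if (!any(positives %in% names(scores)))
    stop("no positive is among the scored objects")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  lab <- names(s) %in% positives
  block_end <- !duplicated(s, fromLast = TRUE)   # last index of each tie block
  n_pred <- which(block_end)
  tp <- cumsum(lab)[block_end]
  curve <- data.frame(
    threshold = s[block_end],
    n_pred = n_pred,
    tp = tp,
    precision = tp / n_pred,
    recall = tp / n_pos
  )
  rownames(curve) <- NULL
  # each positive's precision = precision at its own threshold (block end);
  # positives missing from the score list are never retrieved
  ap <- sum(curve$precision[match(s[lab], curve$threshold)]) / n_pos
  attr(curve, "average_precision") <- ap
  attr(curve, "n_pos") <- n_pos
  class(curve) <- c("pr_curve", "data.frame")
  curve
}

#' Average precision
#'
#' @inheritParams pr_curve
#' @return scalar in `[0, 1]`.
#' @export
average_precision <- function(scores, positives) {
  attr(pr_curve(scores, positives), "average_precision")
}

#' Precision at fixed recall
#'
#' Precision at the first (largest) threshold reaching recall at least
#' `r`. If the curve never reaches `r` (possible when some positives are
#' unscored), the full-ranking precision is returned with attribute
#' `recall_ceiling = TRUE`.
#'
#' @param curve a [pr_curve()].
#' @param r target recall (default 0.20).
#' @return scalar precision.
#' @export
precision_at_recall <- function(curve, r = 0.20) {
  stopifnot(inherits(curve, "pr_curve"))
  hit <- which(curve$recall >= r)
  if (!length(hit)) {
    out <- curve$precision[nrow(curve)]
    attr(out, "recall_ceiling") <- TRUE
    return(out)
  }
  curve$precision[hit[1]]
}

#' Aggregate many precision-recall curves into decile contours
#'
#' On a fixed recall grid, each curve is summarized by its cumulative
#' precision — the best precision attained at recall at least `r` (step
#' reading; set `cumulative = FALSE` for raw step values carried from the
#' first point reaching `r`). The `q` contour at recall `r` is the
#' `(1 - q)` quantile across curves, so the 10% contour is the envelope
#' that the best tenth of terms meet or exceed, the 50% contour the median
#' term, and contours are pointwise ordered by construction.
#'
#' @param curves list of [pr_curve()] objects (one per term).
#' @param recall_grid default `seq(0, 1, 0.01)`.
#' @param deciles contour fractions, default `seq(0.1, 0.9, 0.1)`.
#' @param cumulative use best-precision-at-recall-at-least-r (default).
#' @return object of class `contour_summary`: `recall` grid, `contours`
#'   matrix (deciles x grid), `mean`, `median`, `p20r` (per-curve
#'   precision at 20% recall with mean and median).
#' @export
aggregate_contours <- function(curves, recall_grid = seq(0, 1, 0.01),
                               deciles = seq(0.1, 0.9, 0.1),
                               cumulative = TRUE) {
  stopifnot(length(curves) >= 1)
  cp <- vapply(curves, function(cv) {
    vapply(recall_grid, function(r) {
      hit <- cv$recall >= r
      if (!any(hit)) return(0)
      if (cumulative) max(cv$precision[hit]) else cv$precision[which(hit)[1]]
    }, numeric(1))
  }, numeric(length(recall_grid)))
  cp <- matrix(cp, nrow = length(recall_grid))
  contours <- t(apply(cp, 1, stats::quantile, probs = 1 - deciles,
                      names = FALSE))
  contours <- t(contours)   # deciles x grid
  rownames(contours) <- sprintf("%g%%", 100 * deciles)
  colnames(contours) <- NULL
  p20r <- vapply(curves, precision_at_recall, numeric(1), r = 0.20)
  structure(
    list(recall = recall_grid, contours = contours,
         mean = rowMeans(cp), median = apply(cp, 1, stats::median),
         p20r = list(values = p20r, mean = mean(p20r),
                     median = stats::median(p20r)),
         n_terms = length(curves)),
    class = "contour_summary"
  )
}

#' @export
print.contour_summary <- function(x, ...) {
  cat(sprintf("contour_summary: %d terms; mean P20R = %.3f, median P20R = %.3f\n",
              x$n_terms, x$p20r$mean, x$p20r$median))
  invisible(x)
}

#' Prospective (temporal holdout) evaluation
#'
#' Frozen predictions are scored against annotations added after a start
#' date. For each term: genes already positive for the term before the
#' start date are removed from its score list; the remaining genes are
#' restricted to those that received at least one new association anywhere
#' in the ontology on or after the start date (genes never revisited by
#' curators had no opportunity to gain the annotation); the surviving
#' genes newly associated with the term are the positives.
#'
#' @param scores data frame `gene`, `term`, `score` — the frozen
#'   predictions.
#' @param old a filtered, propagated [annotation_set()] as of the start
#'   date.
#' @param new the later filtered, propagated [annotation_set()].
#' @param start_date integer `YYYYMMDD`; records with unparseable dates are
#'   excluded from the date comparisons.
#' @return list with `retained` (genes with any new association) and
#'   `terms`: per term a list `eval_genes`, `positives`, `curve`
#'   ([pr_curve()], `NULL` when the term gained no surviving positive).
#' @export
prospective_evaluate <- function(scores, old, new, start_date) {
  stopifnot(all(c("gene", "term", "score") %in% names(scores)))
  nr <- new$records
  retained <- unique(nr$gene[!is.na(nr$date) & nr$date >= start_date])
  old_idx <- term_index(old)
  new_idx <- term_index(new)
  or <- old$records
  out <- list()
  for (t in unique(scores$term)) {
    st <- scores[scores$term == t, ]
    prior_pos <- unique(or$gene[or$term == t & !is.na(or$date) &
                                or$date < start_date])
    eval_genes <- setdiff(intersect(st$gene, retained), prior_pos)
    positives <- intersect(eval_genes, new_idx[[t]])
    s <- stats::setNames(st$score, st$gene)[eval_genes]
    out[[t]] <- list(
      eval_genes = sort(eval_genes),
      positives = sort(positives),
      curve = if (length(positives)) pr_curve(s, positives) else NULL
    )
  }
  list(retained = sort(retained), terms = out)
}
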