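# Combination of the two score sources into posterior log-odds:
#   LO = alpha * LLR_profile + (1 - alpha) * LLR_association + LO_prior,
# with the mixing coefficient alpha chosen per term (or per category for
# the narrowest terms) to maximize average precision of the internal
# cross-validation (out-of-bag / leave-one-out) score estimates.

#' Prior log-odds of term membership
#'
#' `log(n_pos / (n_total - n_pos))`: the log-odds that a training gene
#' drawn at random carries the term. Constant across genes for a given
#' term, so it shifts but never reorders the combined scores.
#'
#' @param n_pos number of genes annotated to the term.
#' @param n_total size of the gene universe the odds refer to.
#' @return a scalar log-odds.
#' @export
prior_log_odds <- function(n_pos, n_total) {
  stopifnot(n_pos > 0, n_pos < n_total)
  log(n_pos / (n_total - n_pos))
}

#' Combined posterior log-odds
#'
#' Exact affine combination of the two log-likelihood ratios plus the
#' prior. `alpha = 1` ignores the association scores, `alpha = 0` the
#' profile scores.
#'
#' @param llr_gbp,llr_gba numeric vectors (recycled) of per-gene LLRs from
#'   the profile and association models.
#' @param alpha mixing coefficient in `[0, 1]`.
#' @param lo_prior the term's prior log-odds.
#' @return numeric vector of combined log-odds.
#' @export
combine_hf <- function(llr_gbp, llr_gba, alpha, lo_prior) {
  stopifnot(alpha >= 0, alpha <= 1)
  alpha * llr_gbp + (1 - alpha) * llr_gba + lo_prior
}

#' Optimize the mixing coefficient for one term
#'
#' Grid search for the `alpha` maximizing average precision of the
#' combined score over the training genes, using cross-validation (OOB /
#' leave-one-out) score estimates. Ties resolve to the smallest `alpha`.
#' The per-term-constant prior cannot change the ranking, so it is omitted
#' from the objective.
#'
#' @param llr_gbp,llr_gba named numeric vectors over training genes.
#' @param labels named 0/1 vector over the same genes.
#' @param grid candidate values (default `seq(0, 1, 0.01)`).
#' @return list `alpha`, `ap` (average precision at the optimum), and
#'   `ap_grid` (the full profile).
#' @export
optimize_alpha <- function(llr_gbp, llr_gba, labels, grid = seq(0, 1, 0.01)) {
  genes <- intersect(names(labels), intersect(names(llr_gbp), names(llr_gba)))
  stopifnot(length(genes) > 0)
  pos <- genes[labels[genes] == 1]
  ap_grid <- vapply(grid, function(alpha) {
    average_precision(alpha * llr_gbp[genes] + (1 - alpha) * llr_gba[genes],
                      pos)
  }, numeric(1))
  best <- which.max(ap_grid)   # first max = smallest alpha on an ascending grid
  list(alpha = grid[best], ap = ap_grid[best],
       ap_grid = stats::setNames(ap_grid, grid))
}

#' Optimize a single mixing coefficient for a whole category
#'
#' For categories of very narrow terms a per-term coefficient overfits;
#' one `alpha` is chosen to maximize the mean of the member terms' average
#' precisions.
#'
#' @param term_data list, one element per term, each a list with
#'   `llr_gbp`, `llr_gba`, `labels` as in [optimize_alpha()].
#' @param grid candidate values.
#' @return list `alpha`, `mean_ap`, `ap_grid`.
#' @export
optimize_alpha_category <- function(term_data, grid = seq(0, 1, 0.01)) {
  profiles <- vapply(term_data, function(td) {
    optimize_alpha(td$llr_gbp, td$llr_gba, td$labels, grid = grid)$ap_grid
  }, numeric(length(grid)))
  mean_ap <- if (is.matrix(profiles)) rowMeans(profiles) else profiles
  best <- which.max(mean_ap)
  list(alpha = grid[best], mean_ap = mean_ap[best],
       ap_grid = stats::setNames(mean_ap, grid))
}
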