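# Gene-pair feature construction for functional-linkage network training.
#
# Each shared-annotation source (domains, disease ids, phenotypes,
# phylogenetic profiles) yields a frequency-weighted shared-feature score
# per pair, discretized into five nested top-quantile bins; each expression
# dataset yields a minimum-jackknife-1 Pearson correlation per pair,
# discretized into three nested bins; protein-protein interactions enter as
# a single binary column.

#' Frequency-weighted shared-feature similarity between two genes
#'
#' `sum of f_i^2` over features carried by both genes, where `f_i` is the
#' carrier frequency of feature `i`. Pairs sharing nothing score 0. Common
#' shared features dominate by construction; `weighting = "inverse"`
#' substitutes `(1 - f_i)^2` for callers wanting rare shared features to
#' dominate instead (see the methods vignette).
#'
#' @param g1,g2 gene identifiers present in `fm`.
#' @param fm a [build_feature_matrix()] result.
#' @param freq [feature_frequencies()] of the full gene universe.
#' @param weighting `"frequency"` (default) or `"inverse"`.
#' @return a nonnegative scalar.
#' @export
pair_similarity_score <- function(g1, g2, fm, freq,
                                  weighting = c("frequency", "inverse")) {
  weighting <- match.arg(weighting)
  m <- fm$matrix
  if (!all(c(g1, g2) %in% rownames(m)))
    stop("unknown gene(s): ", paste(setdiff(c(g1, g2), rownames(m)), collapse = ", "))
  shared <- (m[g1, ] * m[g2, ]) > 0
  f <- freq[colnames(m)][shared]
  if (weighting == "inverse") f <- 1 - f
  sum(f^2)
}

#' Shared-feature similarity for all pairs, per source
#'
#' Vectorized form of [pair_similarity_score()] over every unordered pair
#' of `genes`, restricted to one feature source.
#'
#' @param genes gene identifiers (rows of `fm`).
#' @param fm,freq,weighting as in [pair_similarity_score()].
#' @param source restrict to columns of this source tag (default: all).
#' @return data frame `g1`, `g2` (canonical order), `score`.
#' @export
pair_similarity_scores <- function(genes, fm, freq, source = NULL,
                                   weighting = c("frequency", "inverse")) {
  weighting <- match.arg(weighting)
  m <- fm$matrix[genes, , drop = FALSE]
  if (!is.null(source)) m <- m[, fm$source == source, drop = FALSE]
  f <- freq[colnames(m)]
  if (weighting == "inverse") f <- 1 - f
  # S = M diag(f^2) M^T ; entry (i,j) = sum over shared features of f^2
  s <- m %*% Matrix::Diagonal(x = f^2) %*% Matrix::t(m)
  p <- all_pairs(genes)
  p$score <- s[cbind(match(p$g1, rownames(s)), match(p$g2, rownames(s)))]
  p
}

#' Discretize scores into nested top-quantile bins
#'
#' One binary column per quantile `q`: a score is flagged when it is at
#' least the `q`-th-from-the-top threshold of the reference distribution —
#' the `ceiling(q * n)`-th largest reference score, ties included (so a tie
#' block straddling the boundary is flagged whole, and the columns are
#' nested by construction). For sparse shared-annotation scores the
#' reference distribution is the positive scores only (`positive_only =
#' TRUE`, the default): top quantiles of all pairs would be degenerate when
#' almost every pair scores 0. Set `positive_only = FALSE` for dense scores
#' such as correlations; `NA` scores are never flagged and never enter the
#' reference distribution.
#'
#' @param scores numeric vector (optionally named by pair key).
#' @param quantiles fractions in `(0, 1)`, e.g. `c(.1, .2, .3, .4, .5)`.
#' @param positive_only reference distribution: positive scores only?
#' @param prefix column-name prefix.
#' @return binary matrix, `length(scores)` rows, one column per quantile,
#'   named `<prefix>_top<percent>`.
#' @export
discretize_top_quantiles <- function(scores, quantiles = c(.1, .2, .3, .4, .5),
                                     positive_only = TRUE, prefix = "q") {
  stopifnot(all(quantiles > 0), all(quantiles < 1))
  ref <- scores[!is.na(scores)]
  if (positive_only) ref <- ref[ref > 0]
  out <- matrix(0L, length(scores), length(quantiles),
                dimnames = list(names(scores),
                                sprintf("%s_top%g", prefix, 100 * quantiles)))
  if (length(ref) == 0) return(out)
  for (j in seq_along(quantiles)) {
    thr <- kth_largest(ref, ceiling(quantiles[j] * length(ref)))
    hit <- !is.na(scores) & scores >= thr
    if (positive_only) hit <- hit & scores > 0
    out[hit, j] <- 1L
  }
  out
}

#' Minimum-jackknife-1 Pearson correlation
#'
#' The minimum, over samples `i`, of the Pearson correlation computed with
#' sample `i` left out. A single extreme sample can manufacture a large
#' plain Pearson correlation; taking the worst leave-one-out value guards
#' against exactly that failure mode.
#'
#' @param x,y numeric vectors of equal length `>= 4`.
#' @return the minimum leave-one-out correlation, or `NA` (with a warning)
#'   when some leave-one-out subvector is constant.
#' @export
min_jackknife1_pearson <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 4)
  r <- jackknife1_pearson_all(x, y)
  if (anyNA(r)) {
    warning("constant leave-one-out subvector; correlation undefined")
    return(NA_real_)
  }
  min(r)
}

# all n leave-one-out Pearson correlations in O(n), from running sums
jackknife1_pearson_all <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); syy <- sum(y^2); sxy <- sum(x * y)
  m <- n - 1
  cov_i <- (sxy - x * y) - (sx - x) * (sy - y) / m
  vx_i <- (sxx - x^2) - (sx - x)^2 / m
  vy_i <- (syy - y^2) - (sy - y)^2 / m
  bad <- vx_i <= 1e-12 * pmax(1, (sxx - x^2)) | vy_i <= 1e-12 * pmax(1, (syy - y^2))
  r <- cov_i / sqrt(pmax(vx_i, 0) * pmax(vy_i, 0))
  r[bad] <- NA_real_
  r
}

#' Pairwise minimum-jackknife-1 correlations over an expression matrix
#'
#' @param expr numeric matrix, genes x samples (rownames = genes).
#' @param pairs data frame `g1`, `g2`; rows with a gene absent from `expr`
#'   get `NA` (absence is not evidence).
#' @return numeric vector aligned to `pairs`, named by pair key.
#' @export
pairwise_min_jackknife <- function(expr, pairs) {
  out <- rep(NA_real_, nrow(pairs))
  present <- pairs$g1 %in% rownames(expr) & pairs$g2 %in% rownames(expr)
  for (k in which(present)) {
    r <- jackknife1_pearson_all(expr[pairs$g1[k], ], expr[pairs$g2[k], ])
    out[k] <- if (anyNA(r)) NA_real_ else min(r)
  }
  names(out) <- pair_key(pairs$g1, pairs$g2)
  out
}

#' Discretize coexpression into nested bins
#'
#' Top 1%, 5% and 10% quantiles of each dataset's pair correlations; three
#' nested binary columns per expression dataset. Pairs with undefined
#' correlation in a dataset get 0 in that dataset's columns.
#'
#' @param corr_list named list, one numeric vector of pair correlations per
#'   dataset (same pair order in each).
#' @param quantiles default `c(0.01, 0.05, 0.10)`.
#' @return binary matrix, `3 * length(corr_list)` columns.
#' @export
coexpression_bins <- function(corr_list, quantiles = c(.01, .05, .10)) {
  if (is.null(names(corr_list)))
    names(corr_list) <- paste0("expr", seq_along(corr_list))
  do.call(cbind, lapply(names(corr_list), function(d) {
    discretize_top_quantiles(corr_list[[d]], quantiles,
                             positive_only = FALSE, prefix = d)
  }))
}

#' Binary interaction column over gene pairs
#'
#' Self-pairs (homodimers) are removed; `(a,b)` and `(b,a)` collapse onto
#' the canonical key.
#'
#' @param edges data frame with two columns of interacting genes.
#' @param pairs data frame `g1`, `g2` (canonical) to align the column to.
#' @return integer vector of 0/1 aligned to `pairs`.
#' @export
ppi_column <- function(edges, pairs) {
  e <- canonical_pair_frame(as.character(edges[[1]]), as.character(edges[[2]]),
                            warn_self = FALSE)
  as.integer(pair_key(pairs$g1, pairs$g2) %in% pair_key(e$g1, e$g2))
}

#' Build the full gene-pair feature table
#'
#' Assembles, for every unordered pair of `genes`: five nested
#' shared-annotation bins per feature source, three nested coexpression
#' bins per expression dataset, and one interaction column.
#'
#' @param genes gene universe for the network.
#' @param fm gene-centric [build_feature_matrix()] result.
#' @param freq [feature_frequencies()] over the full universe.
#' @param expr_list named list of expression matrices (genes x samples),
#'   or `NULL`.
#' @param ppi_edges two-column interaction data frame, or `NULL`.
#' @param ann_quantiles,expr_quantiles bin definitions.
#' @param weighting passed to [pair_similarity_scores()].
#' @return object of class `pair_feature_table`: list with `g1`, `g2`
#'   (canonical pair order) and sparse binary `X`.
#' @export
build_pair_feature_table <- function(genes, fm, freq, expr_list = NULL,
                                     ppi_edges = NULL,
                                     ann_quantiles = c(.1, .2, .3, .4, .5),
                                     expr_quantiles = c(.01, .05, .10),
                                     weighting = "frequency") {
  pairs <- all_pairs(genes)
  blocks <- list()
  for (src in sort(unique(fm$source))) {
    sc <- pair_similarity_scores(genes, fm, freq, source = src,
                                 weighting = weighting)
    stopifnot(identical(sc$g1, pairs$g1), identical(sc$g2, pairs$g2))
    blocks[[src]] <- discretize_top_quantiles(sc$score, ann_quantiles,
                                              positive_only = TRUE,
                                              prefix = src)
  }
  if (!is.null(expr_list) && length(expr_list)) {
    corr <- lapply(expr_list, pairwise_min_jackknife, pairs = pairs)
    blocks[["coexpr"]] <- coexpression_bins(corr, expr_quantiles)
  }
  if (!is.null(ppi_edges) && nrow(ppi_edges))
    blocks[["ppi"]] <- matrix(ppi_column(ppi_edges, pairs),
                              ncol = 1, dimnames = list(NULL, "ppi"))
  X <- methods::as(do.call(cbind, blocks), "CsparseMatrix")
  rownames(X) <- pair_key(pairs$g1, pairs$g2)
  structure(list(g1 = pairs$g1, g2 = pairs$g2, genes = sort(unique(genes)),
                 X = X),
            class = "pair_feature_table")
}

#' @export
print.pair_feature_table <- function(x, ...) {
  cat(sprintf("pair_feature_table: %d pairs (%d genes) x %d features\n",
              nrow(x$X), length(x$genes), ncol(x$X)))
  invisible(x)
}
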