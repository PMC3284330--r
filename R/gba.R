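# Guilt by association: category-specific functional-linkage networks
# (FLNs) trained on gene-pair features, and kernel-density log-likelihood
# ratio transfer of annotations from each term's core set through the
# network edges.
#
# One FLN per evaluation category. Training pairs are pairs of training
# genes, labeled 1 when the two genes share any term of the category's
# branch whose annotation breadth lies in [3, category upper bound] (the
# cumulative rule: the [31,100] network is trained on terms with fewer
# than 101 associations), 0 otherwise. Training pairs carry out-of-bag
# edge weights; every other pair gets a predicted weight, so the network
# is complete.

#' Training-network labels for a category
#'
#' @param a a filtered, propagated [annotation_set()].
#' @param og an [ontology_graph()] (branch lookup).
#' @param category a [categorize_term()] result or a list with `branch`
#'   and `upper` (and `lower` for the strict rule).
#' @param training character vector of training genes.
#' @param rule `"cumulative"` (terms with 3..upper associations qualify;
#'   default) or `"strict"` (lower..upper only).
#' @param min_n lower selection bound (default 3).
#' @return data frame `g1`, `g2` (canonical, all pairs of training genes),
#'   `label` (0/1).
#' @export
build_training_labels <- function(a, og, category, training,
                                  rule = c("cumulative", "strict"),
                                  min_n = 3) {
  rule <- match.arg(rule)
  idx <- term_index(a)
  counts <- lengths(idx)
  lower <- if (rule == "strict") category$lower else min_n
  qual <- names(counts)[og$branch[names(counts)] == category$branch &
                        counts >= lower & counts <= category$upper]
  pairs <- all_pairs(training)
  if (length(qual)) {
    # membership matrix training genes x qualifying terms; co-membership
    # in >= 1 term marks the pair functionally linked
    tab <- do.call(rbind, lapply(qual, function(t) {
      g <- intersect(idx[[t]], training)
      if (length(g)) data.frame(gene = g, term = t) else NULL
    }))
    m <- Matrix::sparseMatrix(
      i = match(tab$gene, sort(training)),
      j = match(tab$term, qual),
      x = 1, dims = c(length(training), length(qual)),
      dimnames = list(sort(training), qual)
    )
    shared <- Matrix::tcrossprod(m)
    pairs$label <- as.integer(
      shared[cbind(match(pairs$g1, rownames(shared)),
                   match(pairs$g2, rownames(shared)))] > 0)
  } else {
    pairs$label <- 0L
  }
  pairs
}

#' Train a functional-linkage network
#'
#' Fits the edge classifier on the labeled training pairs and fills a
#' complete symmetric weight matrix over the pair table's gene universe:
#' out-of-bag weights for pairs the forest trained on, predicted weights
#' for every other pair. With `n` genes of which `m` are training genes,
#' `C(n,2) - C(m,2)` pairs receive predicted weights (see
#' [n_predicted_pairs()]).
#'
#' @param pft a [build_pair_feature_table()] result.
#' @param labels output of [build_training_labels()] (its pairs must be in
#'   the table).
#' @param n_trees,seed forest parameters.
#' @param negative_subsample optional fraction in `(0, 1]` of negative
#'   training pairs to keep for fitting (seeded); positives are always
#'   kept, and dropped negatives receive predicted rather than out-of-bag
#'   weights. Default `NULL`: train on all pairs.
#' @param category optional category descriptor carried along.
#' @return object of class `fln`: `genes`, symmetric `weights` matrix
#'   (`NA` diagonal), `training_genes`, `labels` (named by pair key),
#'   `oob_keys` (pairs whose weight is out-of-bag), `importance`.
#' @export
train_fln <- function(pft, labels, n_trees = 100, seed = 1,
                      negative_subsample = NULL, category = NULL) {
  stopifnot(inherits(pft, "pair_feature_table"))
  keys <- pair_key(labels$g1, labels$g2)
  if (!all(keys %in% rownames(pft$X)))
    stop("some labeled pairs are missing from the pair feature table")
  y <- stats::setNames(labels$label, keys)
  fit_keys <- keys
  if (!is.null(negative_subsample)) {
    stopifnot(negative_subsample > 0, negative_subsample <= 1)
    neg <- keys[y == 0L]
    set.seed(seed)
    keep_neg <- sample(neg, ceiling(negative_subsample * length(neg)))
    fit_keys <- c(keys[y == 1L], keep_neg)
  }
  model <- train_forest(pft$X[fit_keys, , drop = FALSE], y[fit_keys],
                        n_trees = n_trees, seed = seed)
  genes <- pft$genes
  W <- matrix(NA_real_, length(genes), length(genes),
              dimnames = list(genes, genes))
  fill <- function(k, w) {
    gg <- do.call(rbind, strsplit(k, "|", fixed = TRUE))
    W[cbind(gg[, 1], gg[, 2])] <<- w
    W[cbind(gg[, 2], gg[, 1])] <<- w
  }
  fill(fit_keys, model$oob)
  rest <- setdiff(rownames(pft$X), fit_keys)
  if (length(rest))
    fill(rest, predict(model, pft$X[rest, , drop = FALSE]))
  training_genes <- sort(unique(c(labels$g1, labels$g2)))
  structure(
    list(genes = genes, weights = W, training_genes = training_genes,
         labels = y, oob_keys = fit_keys, category = category,
         importance = model$importance),
    class = "fln"
  )
}

#' Edge weights of a functional-linkage network
#'
#' @param fln an `fln`.
#' @param g1,g2 gene vectors (recycled); omit both for the full edge list.
#' @return numeric weights, or a data frame `g1`, `g2`, `weight` of all
#'   `C(n,2)` edges when called without genes.
#' @export
fln_weights <- function(fln, g1 = NULL, g2 = NULL) {
  stopifnot(inherits(fln, "fln"))
  if (is.null(g1)) {
    p <- all_pairs(fln$genes)
    p$weight <- fln$weights[cbind(p$g1, p$g2)]
    return(p)
  }
  fln$weights[cbind(g1, g2)]
}

#' @export
print.fln <- function(x, ...) {
  cat(sprintf("fln%s: %d genes (%d training), %d labeled pairs (%.1f%% positive)\n",
              if (!is.null(x$category)) paste0(" ", x$category$label) else "",
              length(x$genes), length(x$training_genes), length(x$labels),
              100 * mean(x$labels)))
  invisible(x)
}

# -- densities and transfer --------------------------------------------------

#' Core / noncore edge-weight densities
#'
#' The core-to-core density is estimated from the `C(|C|,2)` edge weights
#' of the core clique; the noncore-to-core density from all edges between
#' non-core training genes and the core. Both carry the uniform `[0,1]`
#' pseudo-count (see [fl_kde()]).
#'
#' @param fln an `fln`.
#' @param C core set: genes annotated to the term (at least 2; smaller
#'   cores must use [pooled_densities()]).
#' @param training training-gene universe.
#' @param pseudo,bw passed to [fl_kde()].
#' @param eps density floor for LLR computation.
#' @return object of class `density_pair`: `core`, `noncore` ([fl_kde()]
#'   objects), sample sizes, `eps`.
#' @export
estimate_densities <- function(fln, C, training, pseudo = "mixture",
                               bw = NULL, eps = 1e-12) {
  stopifnot(inherits(fln, "fln"))
  if (length(C) < 2)
    stop("core set has fewer than 2 genes; use pooled_densities()")
  core_sample <- clique_weights(fln, C)
  noncore <- setdiff(training, C)
  if (!length(noncore)) stop("no noncore training genes")
  noncore_sample <- as.vector(fln$weights[noncore, C])
  density_pair(core_sample, noncore_sample, pseudo = pseudo, bw = bw,
               eps = eps)
}

# upper-triangle weights of the clique on C
clique_weights <- function(fln, C) {
  W <- fln$weights[C, C, drop = FALSE]
  W[upper.tri(W)]
}

#' @rdname estimate_densities
#' @param core_sample,noncore_sample raw edge-weight samples.
#' @export
density_pair <- function(core_sample, noncore_sample, pseudo = "mixture",
                         bw = NULL, eps = 1e-12) {
  structure(
    list(core = fl_kde(core_sample, bw = bw, pseudo = pseudo),
         noncore = fl_kde(noncore_sample, bw = bw, pseudo = pseudo),
         n_core = length(core_sample), n_noncore = length(noncore_sample),
         n_pseudo = 1L, eps = eps),
    class = "density_pair"
  )
}

#' @export
print.density_pair <- function(x, ...) {
  cat(sprintf("density_pair: core n = %d (+%d pseudo), noncore n = %d (+%d pseudo)\n",
              x$n_core, x$n_pseudo, x$n_noncore, x$n_pseudo))
  invisible(x)
}

#' Annotation transfer by log-likelihood ratio
#'
#' Sums, over the edges from gene `g` to every core gene, the log ratio of
#' the core-to-core to the noncore-to-core density at the observed edge
#' weight. Positive values mean `g`'s connectivity to the core looks like
#' the connectivity among core genes.
#'
#' @param g a gene not in `C`.
#' @param C the core set.
#' @param d a [density_pair()].
#' @param fln the `fln` supplying edge weights.
#' @return a finite scalar LLR.
#' @export
llr_transfer <- function(g, C, d, fln) {
  stopifnot(!(g %in% C), length(C) >= 1)
  w <- fln$weights[g, C]
  sum(log(pmax(kde_density(d$core, w), d$eps)) -
      log(pmax(kde_density(d$noncore, w), d$eps)))
}

#' Pooled core / noncore densities for a category
#'
#' Terms with few annotated genes give too few core-clique edges for a
#' stable density; their densities are instead estimated from core-to-core
#' and noncore-to-core pair sets pooled across all the category's terms
#' (multiset pooling: an edge lying in two cores contributes twice).
#'
#' @param fln an `fln`.
#' @param terms the category's term identifiers.
#' @param a a filtered, propagated [annotation_set()].
#' @param training training genes.
#' @param exclude_gene optional gene whose incident edges are excluded
#'   from every pooled sample (leave-one-out re-estimation).
#' @param pseudo,bw,eps see [estimate_densities()].
#' @return a [density_pair()].
#' @export
pooled_densities <- function(fln, terms, a, training, exclude_gene = NULL,
                             pseudo = "mixture", bw = NULL, eps = 1e-12) {
  idx <- term_index(a)
  core_sample <- numeric(0); noncore_sample <- numeric(0)
  for (t in terms) {
    C <- setdiff(intersect(idx[[t]], training), exclude_gene)
    if (length(C) >= 2) core_sample <- c(core_sample, clique_weights(fln, C))
    noncore <- setdiff(training, c(C, exclude_gene))
    if (length(C) >= 1 && length(noncore))
      noncore_sample <- c(noncore_sample,
                          as.vector(fln$weights[noncore, C]))
  }
  if (!length(core_sample) || !length(noncore_sample))
    stop("pooled samples are empty for this category")
  density_pair(core_sample, noncore_sample, pseudo = pseudo, bw = bw,
               eps = eps)
}

#' Transfer a term's annotation to candidate genes
#'
#' Prediction-mode transfer: scores each gene outside the core set with
#' [llr_transfer()], using per-term densities when the term has more than
#' `pooled_max` annotated genes and the category-pooled densities
#' otherwise.
#'
#' @param term term identifier.
#' @param fln the category's `fln`.
#' @param a filtered, propagated [annotation_set()].
#' @param training training genes.
#' @param genes genes to score (core genes are skipped: they are the
#'   label source, not targets).
#' @param category_terms the category's terms (needed for pooling).
#' @param pooled_max association count at or below which pooled densities
#'   are used (default 10).
#' @param pseudo,bw,eps density options.
#' @return object of class `gba_transfer`: `term`, named `llr` over the
#'   scored genes, `core`, `pooled` flag.
#' @export
gba_transfer <- function(term, fln, a, training, genes,
                         category_terms = NULL, pooled_max = 10,
                         pseudo = "mixture", bw = NULL, eps = 1e-12) {
  idx <- term_index(a)
  C <- intersect(idx[[term]], training)
  n_assoc <- length(idx[[term]])
  pooled <- n_assoc <= pooled_max || length(C) < 2
  d <- if (pooled) {
    if (is.null(category_terms))
      stop("pooled transfer for ", term, " needs category_terms")
    pooled_densities(fln, category_terms, a, training,
                     pseudo = pseudo, bw = bw, eps = eps)
  } else {
    estimate_densities(fln, C, training, pseudo = pseudo, bw = bw, eps = eps)
  }
  targets <- setdiff(genes, C)
  llr <- vapply(targets, llr_transfer, numeric(1), C = C, d = d, fln = fln)
  structure(list(term = term, llr = llr, core = C, pooled = pooled),
            class = "gba_transfer")
}

#' Leave-one-out transfer scores for training genes
#'
#' For each training gene `g`, densities are re-estimated with every edge
#' incident to `g` excluded from both samples, and `g` is scored against
#' the core set minus itself using the network's out-of-bag edge weights.
#' Terms in pooled mode (association count at or below `pooled_max`), and
#' any gene whose removal leaves fewer than 2 core genes, fall back to
#' category-pooled densities (likewise excluding `g`'s edges).
#'
#' @inheritParams gba_transfer
#' @param genes training genes to score (default: all).
#' @return named numeric vector of LLRs over `genes`.
#' @export
loo_gba_scores <- function(term, fln, a, training, genes = training,
                           category_terms = NULL, pooled_max = 10,
                           pseudo = "mixture", bw = NULL, eps = 1e-12) {
  idx <- term_index(a)
  C <- intersect(idx[[term]], training)
  n_assoc <- length(idx[[term]])
  pooled_term <- n_assoc <= pooled_max
  out <- stats::setNames(rep(NA_real_, length(genes)), genes)
  for (g in genes) {
    Cg <- setdiff(C, g)
    use_pooled <- pooled_term || length(Cg) < 2
    if (length(Cg) < 1) next   # nothing to transfer from
    d <- if (use_pooled) {
      if (is.null(category_terms))
        stop("pooled fallback for ", term, " needs category_terms")
      pooled_densities(fln, category_terms, a, training, exclude_gene = g,
                       pseudo = pseudo, bw = bw, eps = eps)
    } else {
      core_sample <- clique_weights(fln, Cg)
      noncore <- setdiff(training, c(C, g))
      density_pair(core_sample, as.vector(fln$weights[noncore, Cg]),
                   pseudo = pseudo, bw = bw, eps = eps)
    }
    out[g] <- llr_transfer(g, Cg, d, fln)
  }
  out
}

#' Serialize an FLN edge list
#'
#' Triplet TSV `gene1 <TAB> gene2 <TAB> weight` in canonical gene order.
#'
#' @param fln an `fln`.
#' @param path output path (`.gz` for compressed).
#' @return `read_fln_edges` returns the edge data frame.
#' @export
write_fln_edges <- function(fln, path) {
  utils::write.table(fln_weights(fln), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_fln_edges
#' @export
read_fln_edges <- function(path) {
  utils::read.delim(path, colClasses = c("character", "character", "numeric"))
}
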