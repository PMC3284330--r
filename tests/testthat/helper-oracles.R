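# Hand-built fixtures and independent brute-force oracles. The oracles
# deliberately use straight-line loops and first-principles formulas so
# they share no code path with the implementation they check.

# -- tiny ontologies ---------------------------------------------------------

# A -> B -> C chain, all BP
chain_ontology <- function() {
  ontology_graph(
    terms = c("A", "B", "C"),
    parents = list(A = "B", B = "C", C = character(0)),
    branch = c(A = "BP", B = "BP", C = "BP")
  )
}

# diamond: L has two parents P1, P2, both children of R
diamond_ontology <- function() {
  ontology_graph(
    terms = c("L", "P1", "P2", "R"),
    parents = list(L = c("P1", "P2"), P1 = "R", P2 = "R", R = character(0)),
    branch = c(L = "BP", P1 = "BP", P2 = "BP", R = "BP")
  )
}

toy_annotations <- function(genes, terms, evidence = "IDA", date = 20080101) {
  annotation_set(data.frame(gene = genes, term = terms,
                            evidence = evidence, date = date))
}

# -- brute-force precision-recall -------------------------------------------

# O(n^2) threshold sweep; pessimistic ties by construction (>= threshold)
bf_pr_curve <- function(scores, positives) {
  taus <- sort(unique(scores), decreasing = TRUE)
  data.frame(
    threshold = taus,
    precision = vapply(taus, function(tau) {
      sum(names(scores)[scores >= tau] %in% positives) / sum(scores >= tau)
    }, numeric(1)),
    recall = vapply(taus, function(tau) {
      sum(names(scores)[scores >= tau] %in% positives) / length(positives)
    }, numeric(1))
  )
}

bf_average_precision <- function(scores, positives) {
  cv <- bf_pr_curve(scores, positives)
  mean(vapply(scores[names(scores) %in% positives], function(s) {
    cv$precision[match(s, cv$threshold)]
  }, numeric(1)))
}

# -- counting oracle for top-quantile flags ---------------------------------

# object is in the top-q bin iff fewer than ceiling(q * n_ref) reference
# scores strictly exceed it (tie blocks enter whole)
bf_top_quantile_flags <- function(scores, q, positive_only = TRUE) {
  ref <- scores[!is.na(scores)]
  if (positive_only) ref <- ref[ref > 0]
  k <- ceiling(q * length(ref))
  vapply(scores, function(s) {
    if (is.na(s) || (positive_only && s <= 0)) return(0L)
    as.integer(sum(ref > s) < k)
  }, integer(1))
}

# -- straight-line reimplementation of the GBA transfer ----------------------

# Gaussian KDE with uniform pseudo-count, written out longhand
bf_kde_eval <- function(sample, x, bw = NULL) {
  if (is.null(bw)) {
    bw <- if (length(sample) >= 2 && stats::sd(sample) > 0)
      stats::bw.nrd0(sample) else 0.05
  }
  n <- length(sample)
  vapply(x, function(xi) {
    g <- 0
    for (s in sample) g <- g + exp(-(xi - s)^2 / (2 * bw^2)) / (bw * sqrt(2 * pi))
    (n / (n + 1)) * (g / n) + (1 / (n + 1)) * (xi >= 0 && xi <= 1)
  }, numeric(1))
}

# per-term transfer LLR of gene g, rebuilt from the weight matrix alone
bf_gba_llr <- function(W, g, C, training, eps = 1e-12) {
  core <- c()
  for (i in seq_along(C)) for (j in seq_along(C))
    if (i < j) core <- c(core, W[C[i], C[j]])
  noncore <- c()
  for (a in setdiff(training, C)) for (b in C) noncore <- c(noncore, W[a, b])
  llr <- 0
  for (b in C) {
    w <- W[g, b]
    llr <- llr + log(max(bf_kde_eval(core, w), eps)) -
                 log(max(bf_kde_eval(noncore, w), eps))
  }
  llr
}

# leave-one-out scores for all training genes, rebuilding densities per gene
bf_loo_gba <- function(W, C, training, eps = 1e-12) {
  out <- stats::setNames(rep(NA_real_, length(training)), training)
  for (g in training) {
    Cg <- setdiff(C, g)
    if (length(Cg) < 2) next
    rest <- setdiff(training, c(C, g))
    core <- c()
    for (i in seq_along(Cg)) for (j in seq_along(Cg))
      if (i < j) core <- c(core, W[Cg[i], Cg[j]])
    noncore <- c()
    for (a in rest) for (b in Cg) noncore <- c(noncore, W[a, b])
    llr <- 0
    for (b in Cg) {
      w <- W[g, b]
      llr <- llr + log(max(bf_kde_eval(core, w), eps)) -
                   log(max(bf_kde_eval(noncore, w), eps))
    }
    out[g] <- llr
  }
  out
}

# wrap a bare weight matrix as a linkage network for transfer-stage tests
fln_from_matrix <- function(W, training) {
  structure(list(genes = rownames(W), weights = W,
                 training_genes = training,
                 labels = NULL, oob_keys = NULL, category = NULL),
            class = "fln")
}

# random symmetric weight matrix on [0,1], NA diagonal
random_weight_matrix <- function(genes) {
  n <- length(genes)
  W <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    W[i, j] <- W[j, i] <- stats::runif(1)
  W
}

# small planted-signal config reused by gbp/gba/pipeline property tests
# Sized so the annotated training universe exceeds the widest category
# bound exercised (> 30 genes): propagated root terms then stay too broad
# to qualify as shared-term evidence, as in a full-scale ontology.
small_planted_config <- function(seed) {
  sim_config(
    n_genes = 70, n_modules = c(BP = 5), module_size = c(10, 18),
    n_signal_features = 3,
    n_background_features = c(domain = 20, disease = 10, phenotype = 4,
                              phylo = 8),
    rho_f = 0.7, background_rate = 0.05, phylo_rate = 0.4,
    n_samples = 20, rho_x = 0.6,
    n_interactions = 80, interaction_precision = 0.8,
    epoch_frac = 0.8, iea_rate = 0.1, seed = seed
  )
}

# mean AP across a pipeline's terms for one score source, and the matched
# label-permutation null (labels shuffled among the same training genes)
pipeline_ap_and_null <- function(res, source = c("gbp", "gba", "hf")) {
  source <- match.arg(source)
  col <- c(gbp = "llr_gbp", gba = "llr_gba", hf = "lo_hf")[[source]]
  ap <- null_ap <- numeric(0)
  for (t in res$terms) {
    st <- res$score_table[res$score_table$term == t &
                          res$score_table$set != "undetermined", ]
    s <- stats::setNames(st[[col]], st$gene)
    pos <- st$gene[st$set == "train_pos"]
    ap <- c(ap, average_precision(s, pos))
    null_ap <- c(null_ap, average_precision(s, sample(st$gene, length(pos))))
  }
  c(ap = mean(ap), null = mean(null_ap))
}
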