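# Synthetic fixture generator: a toy ontology, genes, gene-centric
# features, expression, interactions, and two-epoch annotations with
# planted, tunable signal, so every stage of the pipeline is testable
# end-to-end without downloads. Planted truth is returned alongside the
# data for scoring.

#' Simulation configuration
#'
#' Defaults describe a desk-scale study with the structural properties the
#' models assume: functional modules (terms) whose member genes share
#' enriched features, co-express through a common latent factor, and
#' interact preferentially (see the methods vignette for the rationale
#' behind each default).
#'
#' @param n_genes gene universe size.
#' @param n_modules named integer vector: planted module terms per branch.
#' @param module_size inclusive range of module sizes (genes per term).
#' @param n_signal_features signal features planted per module.
#' @param n_background_features named integer vector of uninformative
#'   features per source.
#' @param rho_f probability a module member carries each of the module's
#'   signal features (the feature-leak rate; background genes carry it at
#'   `background_rate`).
#' @param background_rate background carrier probability for all features
#'   (phylogenetic-profile features use `phylo_rate`: presence/absence
#'   across species is dense in real profiles).
#' @param phylo_rate background carrier probability for phylo features.
#' @param n_samples,n_datasets expression design.
#' @param rho_x variance fraction of a module gene's expression explained
#'   by the module's latent factor (coexpression boost).
#' @param n_interactions,interaction_precision number of interaction edges
#'   and the fraction of them drawn within modules.
#' @param epoch_frac fraction of true gene/term associations revealed in
#'   the first annotation epoch (the rest appear after `start_date`).
#' @param iea_rate electronically-inferred (IEA) records added to the GAF,
#'   as a fraction of true records; they exercise evidence filtering.
#' @param date_old,start_date,date_new integer `YYYYMMDD` epoch dates.
#' @param seed master seed; a fixed seed regenerates the bundle
#'   byte-identically.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 120,
                       n_modules = c(BP = 6, CC = 3, MF = 3),
                       module_size = c(6, 24),
                       n_signal_features = 3,
                       n_background_features = c(domain = 40, disease = 20,
                                                 phenotype = 8, phylo = 12),
                       rho_f = 0.8, background_rate = 0.04, phylo_rate = 0.4,
                       n_samples = 30, n_datasets = 1, rho_x = 0.7,
                       n_interactions = 150, interaction_precision = 0.8,
                       epoch_frac = 0.7, iea_rate = 0.1,
                       date_old = 20080115, start_date = 20080719,
                       date_new = 20090301, seed = 1) {
  cfg <- as.list(environment())
  probs <- c(cfg$rho_f, cfg$background_rate, cfg$phylo_rate, cfg$rho_x,
             cfg$interaction_precision, cfg$epoch_frac, cfg$iea_rate)
  stopifnot(all(probs >= 0), all(probs <= 1),
            cfg$module_size[1] >= 3, cfg$n_genes >= sum(cfg$module_size))
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic fixture bundle
#'
#' @param cfg a [sim_config()].
#' @return a `sim_bundle` list: `config`, `genes`, `ontology`
#'   ([ontology_graph()]), `modules` (term -> member genes),
#'   `annotations_old` / `annotations_new` (raw [annotation_set()]s,
#'   IEA records included, unpropagated — exactly what a GAF delivers),
#'   `feature_table` (long `gene`/`feature`/`source`), `expression`
#'   (named list of matrices), `interactions` (`g1`, `g2`), and `truth`
#'   (`gene`, `term`, `epoch`).
#' @export
simulate_bundle <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  sources <- c("domain", "disease", "phenotype", "phylo")

  # ontology: per branch a root, an intermediate (when the branch has >= 2
  # modules), and the module terms; the second module of a branch gets the
  # root as an extra part_of parent so both edge types occur
  tid <- local({ i <- 0L; function() { i <<- i + 1L; sprintf("GO:%07d", i) } })
  terms <- character(0); parents <- list(); branch <- character(0)
  modules <- list()
  for (br in names(cfg$n_modules)) {
    k <- cfg$n_modules[[br]]
    if (k == 0) next
    root <- tid(); terms <- c(terms, root); parents[[root]] <- character(0)
    branch[root] <- br
    inter <- NULL
    if (k >= 2) {
      inter <- tid(); terms <- c(terms, inter); parents[[inter]] <- root
      branch[inter] <- br
    }
    for (j in seq_len(k)) {
      t <- tid(); terms <- c(terms, t); branch[t] <- br
      parents[[t]] <- if (j == 1 && !is.null(inter)) inter
                      else if (j == 2 && !is.null(inter)) c(inter, root)
                      else root
      size <- sample(seq(cfg$module_size[1], cfg$module_size[2]), 1)
      modules[[t]] <- sort(sample(genes, size))
    }
  }
  og <- ontology_graph(terms, parents, branch)

  # two-epoch annotations over the planted memberships; every module keeps
  # at least 3 members in the first epoch so the term is trainable
  truth <- do.call(rbind, lapply(names(modules), function(t) {
    g <- modules[[t]]
    n1 <- max(3L, round(cfg$epoch_frac * length(g)))
    n1 <- min(n1, length(g))
    epoch <- rep(2L, length(g))
    epoch[sample(length(g), n1)] <- 1L
    data.frame(gene = g, term = t, epoch = epoch, stringsAsFactors = FALSE)
  }))
  ev_codes <- c("IDA", "IMP", "IGI", "TAS")
  rec <- data.frame(
    gene = truth$gene, term = truth$term,
    evidence = sample(ev_codes, nrow(truth), replace = TRUE),
    date = ifelse(truth$epoch == 1L, cfg$date_old, cfg$date_new),
    stringsAsFactors = FALSE
  )
  n_iea <- round(cfg$iea_rate * nrow(rec))
  if (n_iea > 0) {
    iea <- data.frame(
      gene = sample(genes, n_iea, replace = TRUE),
      term = sample(names(modules), n_iea, replace = TRUE),
      evidence = "IEA", date = cfg$date_old, stringsAsFactors = FALSE
    )
    rec <- rbind(rec, iea)
  }
  annotations_old <- annotation_set(rec[rec$date < cfg$start_date, ])
  annotations_new <- annotation_set(rec)

  # gene-centric features: per-module signal features in a cycling source,
  # plus uninformative background columns; phylo background is dense
  feat <- list()
  carry <- function(p, g) g[stats::runif(length(g)) < p]
  for (mi in seq_along(modules)) {
    t <- names(modules)[mi]
    src <- sources[(mi - 1L) %% length(sources) + 1L]
    for (s in seq_len(cfg$n_signal_features)) {
      fid <- sprintf("SIG_%s_%d", sub("GO:", "", t), s)
      inm <- carry(cfg$rho_f, modules[[t]])
      outm <- carry(cfg$background_rate, setdiff(genes, modules[[t]]))
      g <- c(inm, outm)
      if (length(g))
        feat[[length(feat) + 1L]] <-
          data.frame(gene = g, feature = fid, source = src)
    }
  }
  for (src in names(cfg$n_background_features)) {
    rate <- if (src == "phylo") cfg$phylo_rate else cfg$background_rate
    for (s in seq_len(cfg$n_background_features[[src]])) {
      g <- carry(rate, genes)
      if (length(g))
        feat[[length(feat) + 1L]] <-
          data.frame(gene = g, feature = sprintf("BG_%s_%d", src, s),
                     source = src)
    }
  }
  feature_table <- unique(do.call(rbind, feat))
  bare <- setdiff(genes, feature_table$gene)
  if (length(bare))   # the modeled universe requires >= 1 feature per gene
    feature_table <- rbind(feature_table,
                           data.frame(gene = bare, feature = "BG_phylo_1",
                                      source = "phylo"))
  feature_table <-
    feature_table[order(feature_table$gene, feature_table$source,
                        feature_table$feature), ]
  rownames(feature_table) <- NULL

  # expression: module latent factor + independent noise; a gene in
  # several modules loads on its first module's factor
  first_module <- vapply(genes, function(g) {
    hits <- names(modules)[vapply(modules, function(m) g %in% m, logical(1))]
    if (length(hits)) hits[1] else NA_character_
  }, character(1))
  expression <- stats::setNames(lapply(seq_len(cfg$n_datasets), function(d) {
    z <- matrix(stats::rnorm(length(modules) * cfg$n_samples),
                length(modules), cfg$n_samples,
                dimnames = list(names(modules), NULL))
    e <- matrix(stats::rnorm(cfg$n_genes * cfg$n_samples),
                cfg$n_genes, cfg$n_samples, dimnames = list(genes, NULL))
    inmod <- !is.na(first_module)
    e[inmod, ] <- sqrt(cfg$rho_x) * z[first_module[inmod], , drop = FALSE] +
      sqrt(1 - cfg$rho_x) * e[inmod, , drop = FALSE]
    colnames(e) <- sprintf("s%02d", seq_len(cfg$n_samples))
    e
  }), sprintf("expr%d", seq_len(cfg$n_datasets)))

  # interactions: mostly within-module pairs, the rest random
  within <- unique(do.call(rbind, lapply(modules, function(m) all_pairs(m))))
  n_within <- min(round(cfg$interaction_precision * cfg$n_interactions),
                  nrow(within))
  inter_edges <- within[sample(nrow(within), n_within), ]
  n_rand <- cfg$n_interactions - n_within
  if (n_rand > 0) {
    rnd <- data.frame(g1 = sample(genes, n_rand, replace = TRUE),
                      g2 = sample(genes, n_rand, replace = TRUE))
    rnd <- rnd[rnd$g1 != rnd$g2, ]
    inter_edges <- rbind(inter_edges, rnd)
  }
  interactions <- canonical_pair_frame(inter_edges$g1, inter_edges$g2)
  interactions <- interactions[order(interactions$g1, interactions$g2), ]
  rownames(interactions) <- NULL

  structure(
    list(config = cfg, genes = genes, ontology = og, modules = modules,
         annotations_old = annotations_old, annotations_new = annotations_new,
         feature_table = feature_table, expression = expression,
         interactions = interactions, truth = truth),
    class = "sim_bundle"
  )
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf("sim_bundle: %d genes, %d module terms, %d true associations (seed %d)\n",
              length(x$genes), length(x$modules), nrow(x$truth),
              x$config$seed))
  invisible(x)
}

#' Write a fixture bundle to plain-text files
#'
#' Emits `ontology.obo`, `annotations_old.gaf`, `annotations_new.gaf`,
#' `features.tsv`, `expression_<k>.tsv`, `interactions.tsv`, `truth.tsv` —
#' each readable by the package's own parsers. Regeneration from the same
#' seed is byte-identical.
#'
#' @param bundle a [simulate_bundle()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  og <- bundle$ontology
  write_obo(og, file.path(dir, "ontology.obo"))
  aspect <- stats::setNames(c(BP = "P", CC = "C", MF = "F")[og$branch],
                            og$terms)
  write_gaf(bundle$annotations_old, file.path(dir, "annotations_old.gaf"),
            aspect = aspect)
  write_gaf(bundle$annotations_new, file.path(dir, "annotations_new.gaf"),
            aspect = aspect)
  utils::write.table(bundle$feature_table, file.path(dir, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (d in names(bundle$expression)) {
    m <- bundle$expression[[d]]
    utils::write.table(data.frame(gene = rownames(m), m,
                                  check.names = FALSE),
                       file.path(dir, paste0(d, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(bundle$interactions, file.path(dir, "interactions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read an expression matrix written by [write_fixture()]
#' @param path TSV with a `gene` column followed by sample columns.
#' @return numeric matrix, genes x samples.
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene
  m
}

#' Read a two-column undirected edge list
#' @param path TSV with columns `g1`, `g2`.
#' @return data frame `g1`, `g2`.
#' @export
read_edge_list <- function(path) {
  utils::read.delim(path, colClasses = "character")[, c("g1", "g2")]
}

#' A tiny fixed worked fixture
#'
#' Twelve genes, four module terms (plus roots and one intermediate),
#' hand-checkable; used in documentation examples and oracle-equivalence
#' tests. Fully deterministic.
#'
#' @return a `sim_bundle`.
#' @export
make_worked_fixture <- function() {
  simulate_bundle(sim_config(
    n_genes = 12, n_modules = c(BP = 2, CC = 1, MF = 0),
    module_size = c(3, 4), n_signal_features = 2,
    n_background_features = c(domain = 4, disease = 2, phenotype = 2,
                              phylo = 3),
    rho_f = 1, background_rate = 0.05, phylo_rate = 0.5,
    n_samples = 8, rho_x = 0.8, n_interactions = 10,
    epoch_frac = 0.75, iea_rate = 0.1, seed = 42
  ))
}
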