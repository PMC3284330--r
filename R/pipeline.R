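# End-to-end orchestration: ontology processing -> gene features ->
# per-term profile classifiers -> pair features -> per-category linkage
# networks and annotation transfer -> combined log-odds -> evaluation.

#' Run the full prediction pipeline on a data bundle
#'
#' @param bundle a [simulate_bundle()] result, or any list with the same
#'   components (`ontology`, `annotations_old`, `feature_table`,
#'   `expression`, `interactions`, `genes`).
#' @param n_trees forest size for both gene and edge classifiers.
#' @param seed master seed for every stochastic step.
#' @param min_n,max_n term selection bounds (defaults 3 and 300).
#' @param pooled_max association count at or below which a term uses
#'   category-pooled transfer densities (default 10).
#' @param alpha_grid mixing-coefficient grid (default step 0.01).
#' @param negative_subsample optional negative-pair subsampling fraction
#'   for linkage-network training (see [train_fln()]).
#' @param excluded_evidence evidence codes removed before training
#'   (default `"IEA"`).
#' @return a `pipeline_result` list: `terms`, `categories` (per-term
#'   descriptors), `split`, `alphas`, `score_table` (one row per scored
#'   gene/term: `gene`, `term`, `set`, `llr_gbp`, `llr_gba`, `lo_prior`,
#'   `alpha`, `lo_hf`), `curves` (per term, per score source, on
#'   cross-validated training scores), `contours` (per category, for the
#'   combined scores), `flns`, `gbp`, and bookkeeping in `info`.
#' @export
run_pipeline <- function(bundle, n_trees = 100, seed = 1,
                         min_n = 3, max_n = 300, pooled_max = 10,
                         alpha_grid = seq(0, 1, 0.01),
                         negative_subsample = NULL,
                         excluded_evidence = "IEA") {
  og <- bundle$ontology
  ann <- propagate_annotations(
    filter_evidence(bundle$annotations_old, excluded_evidence), og)
  fm <- build_feature_matrix(bundle$feature_table, genes = bundle$genes)
  universe <- rownames(fm$matrix)
  freq <- feature_frequencies(fm)

  terms <- select_terms(ann, min_n, max_n)
  split <- split_training_undetermined(ann, universe, terms)
  training <- split$training; undetermined <- split$undetermined
  idx <- term_index(ann)
  # a term must leave a two-class training split
  terms <- terms[vapply(terms, function(t) {
    np <- length(intersect(idx[[t]], training))
    np >= 1 && np < length(training)
  }, logical(1))]
  categories <- lapply(terms, categorize_term, a = ann, og = og)
  names(categories) <- terms
  cat_label <- vapply(categories, `[[`, character(1), "label")

  # guilt by profiling, one forest per term
  gbp <- lapply(terms, train_gbp_term, fm = fm, a = ann,
                training = training, undetermined = undetermined,
                n_trees = n_trees, seed = seed)
  names(gbp) <- terms

  # linkage networks, one per category present
  pft <- build_pair_feature_table(universe, fm, freq,
                                  expr_list = bundle$expression,
                                  ppi_edges = bundle$interactions)
  flns <- list(); gba_train <- list(); gba_undet <- list()
  for (lab in unique(cat_label)) {
    cat_terms <- terms[cat_label == lab]
    category <- categories[[cat_terms[1]]]
    labels <- build_training_labels(ann, og, category, training)
    if (length(unique(labels$label)) < 2) {
      warning("category ", lab, " has single-class pair labels; skipped")
      next
    }
    fln <- train_fln(pft, labels, n_trees = n_trees, seed = seed,
                     negative_subsample = negative_subsample,
                     category = category)
    flns[[lab]] <- fln
    for (t in cat_terms) {
      gba_train[[t]] <- loo_gba_scores(t, fln, ann, training,
                                       category_terms = cat_terms,
                                       pooled_max = pooled_max)
      tr <- gba_transfer(t, fln, ann, training, genes = undetermined,
                         category_terms = cat_terms, pooled_max = pooled_max)
      gba_undet[[t]] <- tr$llr
    }
  }
  terms <- intersect(terms, names(gba_train))

  # mixing coefficients: per term, except one shared alpha per [3,10]
  # category; then combined log-odds for every scored gene/term
  alphas <- stats::setNames(numeric(length(terms)), terms)
  term_data <- lapply(terms, function(t) list(
    llr_gbp = gbp[[t]]$llr[training],
    llr_gba = gba_train[[t]],
    labels = gbp[[t]]$labels
  ))
  names(term_data) <- terms
  for (lab in unique(cat_label[terms])) {
    cat_terms <- terms[cat_label[terms] == lab]
    if (categories[[cat_terms[1]]]$lower == 3) {
      alphas[cat_terms] <- optimize_alpha_category(term_data[cat_terms],
                                                   grid = alpha_grid)$alpha
    } else {
      for (t in cat_terms)
        alphas[t] <- optimize_alpha(term_data[[t]]$llr_gbp,
                                    term_data[[t]]$llr_gba,
                                    term_data[[t]]$labels,
                                    grid = alpha_grid)$alpha
    }
  }

  score_table <- do.call(rbind, lapply(terms, function(t) {
    lg <- c(gba_train[[t]], gba_undet[[t]])
    genes_t <- intersect(names(gbp[[t]]$llr), names(lg))
    n_pos <- sum(gbp[[t]]$labels == 1)
    lo_prior <- prior_log_odds(n_pos, length(training))
    data.frame(
      gene = genes_t, term = t,
      set = unname(gbp[[t]]$set[genes_t]),
      llr_gbp = unname(gbp[[t]]$llr[genes_t]),
      llr_gba = unname(lg[genes_t]),
      lo_prior = lo_prior, alpha = unname(alphas[t]),
      lo_hf = unname(combine_hf(gbp[[t]]$llr[genes_t], lg[genes_t],
                                alphas[t], lo_prior)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(score_table) <- NULL

  # cross-validated evaluation on training genes, per score source
  curves <- lapply(terms, function(t) {
    pos <- names(gbp[[t]]$labels)[gbp[[t]]$labels == 1]
    st <- score_table[score_table$term == t & score_table$set != "undetermined", ]
    lapply(stats::setNames(c("llr_gbp", "llr_gba", "lo_hf"),
                           c("gbp", "gba", "hf")),
           function(col) pr_curve(stats::setNames(st[[col]], st$gene), pos))
  })
  names(curves) <- terms
  contours <- lapply(split(terms, cat_label[terms]), function(ts) {
    aggregate_contours(lapply(curves[ts], `[[`, "hf"))
  })

  structure(
    list(terms = terms, categories = categories, split = split,
         alphas = alphas, score_table = score_table, curves = curves,
         contours = contours, flns = flns, gbp = gbp,
         gba = list(train = gba_train, undetermined = gba_undet),
         feature_matrix = fm, pair_features = pft,
         annotations = ann,
         info = list(seed = seed, n_trees = n_trees,
                     n_genes = length(universe),
                     n_training = length(training),
                     n_undetermined = length(undetermined))),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  ap <- vapply(x$curves, function(cv)
    attr(cv$hf, "average_precision"), numeric(1))
  cat(sprintf(
    "pipeline_result: %d terms over %d genes (%d training); mean AP (combined, cross-validated) = %.3f\n",
    length(x$terms), x$info$n_genes, x$info$n_training, mean(ap)))
  invisible(x)
}

#' Mean cross-validated average precision per score source
#'
#' Convenience summary over a [run_pipeline()] result.
#'
#' @param result a `pipeline_result`.
#' @return named numeric: `gbp`, `gba`, `hf`.
#' @export
pipeline_mean_ap <- function(result) {
  vapply(c(gbp = "gbp", gba = "gba", hf = "hf"), function(m) {
    mean(vapply(result$curves, function(cv)
      attr(cv[[m]], "average_precision"), numeric(1)))
  }, numeric(1))
}
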