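# Dated, evidence-coded gene -> term associations: GAF input, evidence
# filtering, up-propagation, term selection and categorization, and the
# training/undetermined gene split.

#' Construct an annotation set
#'
#' @param records data frame with columns `gene`, `term`, `evidence`,
#'   `date` (integer `YYYYMMDD`; `NA` allowed — such records are excluded
#'   from date-based filtering only).
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(records) {
  stopifnot(all(c("gene", "term", "evidence", "date") %in% names(records)))
  records <- records[, c("gene", "term", "evidence", "date")]
  records$gene <- as.character(records$gene)
  records$term <- as.character(records$term)
  records$evidence <- as.character(records$evidence)
  records$date <- suppressWarnings(as.integer(records$date))
  records <- unique(records)
  rownames(records) <- NULL
  structure(list(records = records), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d records, %d genes, %d terms\n",
              nrow(x$records), length(unique(x$records$gene)),
              length(unique(x$records$term))))
  invisible(x)
}

#' Term-to-genes index of an annotation set
#'
#' @param a an [annotation_set()].
#' @return named list: term -> character vector of distinct annotated genes.
#' @export
term_index <- function(a) {
  stopifnot(inherits(a, "annotation_set"))
  r <- unique(a$records[, c("gene", "term")])
  split(r$gene, r$term)
}

#' Read a GAF 2.x association file
#'
#' Tab-separated, `!` comment lines; gene identifier from column 2,
#' term from column 5, evidence code from column 7, date (`YYYYMMDD`)
#' from column 14.
#'
#' @param path file path.
#' @return an [annotation_set()].
#' @export
read_gaf <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, comment.char = "!",
                           quote = "", colClasses = "character")
  if (ncol(tab) < 14) stop("GAF input has fewer than 14 columns")
  annotation_set(data.frame(
    gene = tab[[2]], term = tab[[5]], evidence = tab[[7]],
    date = suppressWarnings(as.integer(tab[[14]])),
    stringsAsFactors = FALSE
  ))
}

# GAF writer for generated fixtures (17 columns, unused ones blank)
write_gaf <- function(a, path, db = "SYN", aspect = NULL) {
  r <- a$records
  asp <- if (is.null(aspect)) rep("P", nrow(r)) else aspect[r$term]
  cols <- list(db, r$gene, r$gene, "", r$term, "SYN:ref", r$evidence, "",
               asp, "", "", "gene", "taxon:9606",
               sprintf("%08d", ifelse(is.na(r$date), 0L, r$date)),
               db, "", "")
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(c("!gaf-version: 2.1", lines), path)
  invisible(path)
}

#' Filter annotation records by evidence code
#'
#' Removes every record whose evidence code is in `excluded`. The standard
#' use is dropping IEA (electronically inferred) associations so that
#' models train on ground truth rather than on earlier predictions.
#'
#' @param a an [annotation_set()].
#' @param excluded character vector of GAF evidence codes; default `"IEA"`.
#' @return a filtered [annotation_set()].
#' @export
filter_evidence <- function(a, excluded = "IEA") {
  stopifnot(inherits(a, "annotation_set"))
  annotation_set(a$records[!(a$records$evidence %in% excluded), ])
}

#' Up-propagate annotations through the ontology
#'
#' A gene annotated to a term becomes annotated to every ancestor of the
#' term (set semantics: an ancestor reachable along several paths is
#' counted once). Propagated records inherit the evidence code and date of
#' the record they derive from. Records whose term is absent from the
#' ontology are dropped with a warning. Idempotent.
#'
#' @param a an [annotation_set()].
#' @param og an [ontology_graph()].
#' @return a propagated [annotation_set()].
#' @export
propagate_annotations <- function(a, og) {
  stopifnot(inherits(a, "annotation_set"), inherits(og, "ontology_graph"))
  r <- a$records
  unknown <- !(r$term %in% og$terms)
  if (any(unknown)) {
    warning(sum(unknown), " record(s) with terms absent from the ontology dropped")
    r <- r[!unknown, ]
  }
  if (!nrow(r)) return(annotation_set(r))
  anc <- ancestors(og, unique(r$term))
  n_up <- lengths(anc)[r$term]
  up <- data.frame(
    gene = rep(r$gene, n_up),
    term = unlist(anc[r$term], use.names = FALSE),
    evidence = rep(r$evidence, n_up),
    date = rep(r$date, n_up),
    stringsAsFactors = FALSE
  )
  annotation_set(rbind(r, up))
}

#' Select terms by annotation breadth
#'
#' Keeps terms with at least `min_n` and at most `max_n` distinct annotated
#' genes. Apply after evidence filtering and propagation.
#'
#' @param a an [annotation_set()] (filtered, propagated).
#' @param min_n,max_n inclusive bounds on the per-term gene count
#'   (defaults 3 and 300).
#' @return sorted character vector of term identifiers.
#' @export
select_terms <- function(a, min_n = 3, max_n = 300) {
  counts <- lengths(term_index(a))
  sort(names(counts)[counts >= min_n & counts <= max_n])
}

#' The 12 evaluation categories
#'
#' Categories cross the three ontology branches with four annotation-breadth
#' bins that partition `[3, 300]`.
#'
#' @return data frame with columns `branch`, `lower`, `upper`, `label`.
#' @export
term_categories <- function() {
  bins <- data.frame(lower = c(3L, 11L, 31L, 101L),
                     upper = c(10L, 30L, 100L, 300L))
  out <- merge(data.frame(branch = c("BP", "CC", "MF")), bins)
  out$label <- sprintf("%s [%d,%d]", out$branch, out$lower, out$upper)
  out[order(out$branch, out$lower), c("branch", "lower", "upper", "label")]
}

#' Categorize a selected term
#'
#' @param term a term identifier.
#' @param a a filtered, propagated [annotation_set()].
#' @param og an [ontology_graph()] supplying the branch.
#' @return list with `branch`, `lower`, `upper`, `label`, `n_genes`;
#'   class `term_category`.
#' @export
categorize_term <- function(term, a, og) {
  n <- length(term_index(a)[[term]])
  if (is.null(n) || n < 3 || n > 300)
    stop("term ", term, " has ", if (is.null(n)) 0 else n,
         " genes; categories cover counts 3..300 only")
  cats <- term_categories()
  row <- cats[cats$branch == og$branch[[term]] & cats$lower <= n & n <= cats$upper, ]
  structure(list(branch = row$branch, lower = row$lower, upper = row$upper,
                 label = row$label, n_genes = n),
            class = "term_category")
}

#' @export
print.term_category <- function(x, ...) {
  cat(x$label, "\n"); invisible(x)
}

#' Split the gene universe into training and undetermined sets
#'
#' Training genes carry at least one association to a selected term; the
#' rest of the universe is undetermined (scored by prediction only, never
#' used in fitting). The two sets partition `all_genes`.
#'
#' @param a a filtered, propagated [annotation_set()].
#' @param all_genes the full gene universe.
#' @param terms the selected terms (default [select_terms()] of `a`).
#' @return list with character vectors `training` and `undetermined`.
#' @export
split_training_undetermined <- function(a, all_genes, terms = select_terms(a)) {
  idx <- term_index(a)
  annotated <- unique(unlist(idx[intersect(names(idx), terms)], use.names = FALSE))
  training <- intersect(all_genes, annotated)
  list(training = sort(training),
       undetermined = sort(setdiff(all_genes, training)))
}
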