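# Ontology graph: parsing, ancestor closure, and term bookkeeping.
#
# The term graph is a DAG over GO-style identifiers with is_a and part_of
# edges (treated identically for propagation) and a branch label per term
# (BP, CC, MF). Obsolete terms are dropped at parse time.

BRANCHES <- c(biological_process = "BP", cellular_component = "CC",
              molecular_function = "MF")

#' Construct an ontology graph
#'
#' @param terms character vector of term identifiers.
#' @param parents named list mapping each term to its parent terms
#'   (is_a and part_of combined); roots map to `character(0)`.
#' @param branch named character vector, one of `"BP"`, `"CC"`, `"MF"`
#'   per term.
#' @param name optional named character vector of human-readable labels.
#' @return an object of class `ontology_graph`.
#' @export
ontology_graph <- function(terms, parents, branch, name = NULL) {
  terms <- unique(terms)
  parents <- parents[terms]
  names(parents) <- terms
  parents <- lapply(parents, function(p) intersect(unique(p), terms))
  branch <- branch[terms]
  if (any(is.na(branch))) stop("every term needs a branch label")
  og <- structure(
    list(terms = terms, parents = parents,
         branch = branch, name = name),
    class = "ontology_graph"
  )
  check_acyclic(og)
  og
}

# Kahn's algorithm; errors on a cycle, returns topological order
# (parents before children is not guaranteed; we only need acyclicity
# and a valid elimination order for the ancestor closure).
check_acyclic <- function(og) {
  remaining <- og$terms
  parents <- og$parents
  order <- character(0)
  repeat {
    deg <- vapply(parents[remaining],
                  function(p) length(intersect(p, remaining)), integer(1))
    free <- remaining[deg == 0L]
    if (length(free) == 0L) {
      if (length(remaining) > 0L) stop("ontology graph contains a cycle")
      break
    }
    order <- c(order, free)
    remaining <- setdiff(remaining, free)
  }
  invisible(order)
}

#' Ancestor closure of ontology terms
#'
#' Transitive closure over is_a and part_of edges; the term itself is not
#' included.
#'
#' @param og an [ontology_graph()].
#' @param terms terms to query (default: all).
#' @return named list of character vectors of ancestors.
#' @export
ancestors <- function(og, terms = og$terms) {
  stopifnot(inherits(og, "ontology_graph"))
  unknown <- setdiff(terms, og$terms)
  if (length(unknown)) stop("unknown term(s): ", paste(unknown, collapse = ", "))
  order <- check_acyclic(og)   # every term's parents appear earlier
  clo <- vector("list", length(og$terms))
  names(clo) <- og$terms
  for (t in order) {
    p <- og$parents[[t]]
    clo[[t]] <- unique(c(p, unlist(clo[p], use.names = FALSE)))
  }
  clo[terms]
}

#' Root terms of an ontology graph
#' @param og an [ontology_graph()].
#' @return character vector of terms with no parents.
#' @export
ontology_roots <- function(og) {
  og$terms[vapply(og$parents, length, integer(1)) == 0L]
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("ontology_graph: %d terms (%s), %d roots\n",
              length(x$terms),
              paste(sprintf("%s %d", names(table(x$branch)), table(x$branch)),
                    collapse = ", "),
              length(ontology_roots(x))))
  invisible(x)
}

#' Parse an OBO 1.2 ontology file
#'
#' Loads all non-obsolete `[Term]` stanzas, keeping `is_a` and
#' `relationship: part_of` edges. Edges pointing at terms that are not
#' loaded (e.g. obsolete targets) are dropped. A cyclic graph is a hard
#' failure.
#'
#' @param path path to an OBO file, or a character vector of OBO lines.
#' @return an [ontology_graph()].
#' @export
parse_obo <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  lines <- sub("\\s*!.*$", "", lines)   # strip trailing comments
  stanza_starts <- grep("^\\[", lines)
  if (!length(stanza_starts)) stop("no stanzas found in OBO input")
  ids <- character(0); parents <- list(); branch <- character(0)
  name <- character(0)
  bounds <- c(stanza_starts, length(lines) + 1L)
  for (i in seq_along(stanza_starts)) {
    block <- lines[stanza_starts[i]:(bounds[i + 1L] - 1L)]
    if (!grepl("^\\[Term\\]", block[1])) next
    get1 <- function(key) {
      v <- sub(paste0("^", key, ":\\s*"), "",
               grep(paste0("^", key, ":"), block, value = TRUE))
      trimws(v)
    }
    if (length(get1("is_obsolete")) && any(get1("is_obsolete") == "true")) next
    id <- get1("id")[1]
    if (is.na(id) || !nzchar(id)) next
    isa <- get1("is_a")
    rel <- get1("relationship")
    partof <- sub("^part_of\\s+", "", rel[grepl("^part_of\\s", rel)])
    ns <- get1("namespace")[1]
    br <- if (!is.na(ns) && ns %in% names(BRANCHES)) BRANCHES[[ns]]
          else if (!is.na(ns) && ns %in% BRANCHES) ns else NA_character_
    ids <- c(ids, id)
    parents[[id]] <- trimws(c(isa, partof))
    branch[id] <- br
    nm <- get1("name")[1]
    name[id] <- if (is.na(nm)) id else nm
  }
  if (anyDuplicated(ids)) stop("duplicate term ids in OBO input")
  # inherit missing branch labels from parents (rare in practice)
  if (any(is.na(branch))) {
    for (rep in 1:3) {
      for (t in ids[is.na(branch[ids])]) {
        pb <- stats::na.omit(branch[parents[[t]]])
        if (length(pb)) branch[t] <- pb[1]
      }
    }
    branch[is.na(branch)] <- "BP"
  }
  ontology_graph(ids, parents, branch, name = name)
}

# minimal OBO writer used by the synthetic-data generator
write_obo <- function(og, path) {
  out <- c("format-version: 1.2", "")
  ns_of <- stats::setNames(names(BRANCHES), BRANCHES)
  for (t in og$terms) {
    out <- c(out, "[Term]",
             paste0("id: ", t),
             paste0("name: ", if (!is.null(og$name)) og$name[[t]] else t),
             paste0("namespace: ", ns_of[[og$branch[[t]]]]))
    p <- og$parents[[t]]
    # first parent as is_a, any further as part_of so both edge types
    # appear in generated fixtures
    if (length(p) >= 1) out <- c(out, paste0("is_a: ", p[1]))
    if (length(p) >= 2)
      out <- c(out, paste0("relationship: part_of ", p[-1]))
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}
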