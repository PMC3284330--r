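# Network operations on functional-linkage networks: top-fraction edge
# thresholding and 1-neighborhood disease seed-set expansion into induced
# candidate subgraphs.

#' Retain the top fraction of network edges
#'
#' Keeps the `ceiling(q * C(n,2))` highest-weight edges of the complete
#' network; ties at the boundary weight are all retained (the result may
#' therefore exceed the nominal count).
#'
#' @param fln an `fln`, or a data frame `g1`, `g2`, `weight` of edges.
#' @param q fraction in `(0, 1)`, e.g. `1e-4` for the top 0.01%.
#' @return data frame `g1`, `g2`, `weight`, heaviest first.
#' @export
threshold_top_fraction <- function(fln, q) {
  stopifnot(q > 0, q < 1)
  edges <- if (inherits(fln, "fln")) fln_weights(fln) else fln
  stopifnot(all(c("g1", "g2", "weight") %in% names(edges)))
  k <- ceiling(q * nrow(edges))
  thr <- kth_largest(edges$weight, k)
  out <- edges[edges$weight >= thr, ]
  out[order(out$weight, decreasing = TRUE), ]
}

#' Expand a seed gene set through retained edges
#'
#' One-neighborhood expansion: genes connected to any seed by a retained
#' edge are recruited, and the subgraph induced on seeds plus recruits
#' (all retained edges among them, including recruit-recruit bridges) is
#' returned. Seeds absent from the edge universe are dropped with a
#' warning. Depths greater than 1 repeat the recruitment step from the
#' grown set.
#'
#' @param edges retained edge data frame (`g1`, `g2`, `weight`), e.g. from
#'   [threshold_top_fraction()].
#' @param seeds nonempty character vector of seed genes.
#' @param universe optional gene universe used to validate seeds (default:
#'   genes appearing in `edges`).
#' @param depth expansion depth (default 1).
#' @return object of class `seed_expansion`: `seeds`, `recruited`,
#'   `subgraph` (edge data frame), `nodes` (data frame `gene`, `is_seed`).
#' @export
expand_seeds <- function(edges, seeds, universe = NULL, depth = 1) {
  stopifnot(length(seeds) >= 1, depth >= 1)
  if (is.null(universe)) universe <- unique(c(edges$g1, edges$g2))
  missing <- setdiff(seeds, universe)
  if (length(missing)) {
    warning("seed(s) absent from the network: ",
            paste(missing, collapse = ", "))
    seeds <- setdiff(seeds, missing)
  }
  if (!length(seeds)) stop("no seed remains in the network")
  frontier <- seeds
  members <- seeds
  for (i in seq_len(depth)) {
    touch <- edges$g1 %in% frontier | edges$g2 %in% frontier
    frontier <- setdiff(unique(c(edges$g1[touch], edges$g2[touch])), members)
    members <- union(members, frontier)
    if (!length(frontier)) break
  }
  recruited <- sort(setdiff(members, seeds))
  sub <- edges[edges$g1 %in% members & edges$g2 %in% members, ]
  rownames(sub) <- NULL
  structure(
    list(seeds = sort(seeds), recruited = recruited, subgraph = sub,
         nodes = data.frame(gene = sort(members),
                            is_seed = sort(members) %in% seeds)),
    class = "seed_expansion"
  )
}

#' @export
print.seed_expansion <- function(x, ...) {
  cat(sprintf("seed_expansion: %d seeds recruited %d genes; %d retained edges in subgraph\n",
              length(x$seeds), length(x$recruited), nrow(x$subgraph)))
  invisible(x)
}

#' Export a seed-expansion subgraph
#'
#' Writes a node TSV (`gene`, `is_seed`) and an edge TSV (`g1`, `g2`,
#' `weight`, `source`). An external interaction edge list can be overlaid
#' as an annotation layer (it plays no part in the expansion itself).
#'
#' @param x a `seed_expansion`.
#' @param node_path,edge_path output paths.
#' @param overlay optional two-column interaction data frame; overlay
#'   edges between subgraph members are appended with `source = "overlay"`.
#' @export
write_seed_expansion <- function(x, node_path, edge_path, overlay = NULL) {
  utils::write.table(x$nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  edges <- x$subgraph
  edges$source <- rep("fln", nrow(edges))
  if (!is.null(overlay) && nrow(overlay)) {
    ov <- canonical_pair_frame(as.character(overlay[[1]]),
                               as.character(overlay[[2]]))
    ov <- ov[ov$g1 %in% x$nodes$gene & ov$g2 %in% x$nodes$gene, ]
    if (nrow(ov))
      edges <- rbind(edges, data.frame(g1 = ov$g1, g2 = ov$g2,
                                       weight = NA_real_, source = "overlay"))
  }
  utils::write.table(edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(edge_path)
}
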