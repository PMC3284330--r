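# Internal helpers shared across modules.

#' Canonical unordered gene-pair keys
#'
#' Every unordered gene pair is stored once, under the key of its
#' lexicographically sorted members. Self-pairs are rejected.
#'
#' @param g1,g2 character vectors of gene identifiers (recycled).
#' @return character vector of keys, one per pair.
#' @keywords internal
pair_key <- function(g1, g2) {
  if (any(g1 == g2)) stop("self-pairs are not valid gene pairs")
  paste(pmin(g1, g2), pmax(g1, g2), sep = "|")
}

# canonicalize a two-column pair table: sort within row, drop self-pairs
# (optionally with a warning), drop duplicates
canonical_pair_frame <- function(g1, g2, warn_self = FALSE) {
  self <- g1 == g2
  if (any(self)) {
    if (warn_self) warning(sum(self), " self-pair(s) dropped")
    g1 <- g1[!self]; g2 <- g2[!self]
  }
  a <- pmin(g1, g2); b <- pmax(g1, g2)
  keep <- !duplicated(paste(a, b, sep = "|"))
  data.frame(g1 = a[keep], g2 = b[keep], stringsAsFactors = FALSE)
}

# all C(n,2) unordered pairs of a gene vector, canonical order
all_pairs <- function(genes) {
  genes <- sort(unique(genes))
  n <- length(genes)
  if (n < 2) return(data.frame(g1 = character(), g2 = character()))
  idx <- utils::combn(n, 2)
  data.frame(g1 = genes[idx[1, ]], g2 = genes[idx[2, ]],
             stringsAsFactors = FALSE)
}

#' Number of unordered gene pairs
#'
#' Bookkeeping helpers for complete functional-linkage networks. For a
#' universe of `n` genes the network has `n(n-1)/2` logical edges;
#' when `m` of the genes form the training set, the pairs needing predicted
#' (rather than out-of-bag) weights number `C(n,2) - C(m,2)`.
#'
#' @param n number of genes in the universe.
#' @param m number of training genes (`n_predicted_pairs`).
#' @return a double (counts exceed `.Machine$integer.max` at genome scale).
#' @examples
#' n_gene_pairs(4)            # 6
#' n_predicted_pairs(4, 2)    # 5
#' @export
n_gene_pairs <- function(n) {
  stopifnot(n >= 0)
  as.numeric(n) * (as.numeric(n) - 1) / 2
}

#' @rdname n_gene_pairs
#' @export
n_predicted_pairs <- function(n, m) {
  stopifnot(m <= n)
  n_gene_pairs(n) - n_gene_pairs(m)
}

# k-th largest value of x (k >= 1); used for top-fraction thresholds
kth_largest <- function(x, k) {
  n <- length(x)
  stopifnot(k >= 1, k <= n)
  sort(x, partial = n - k + 1)[n - k + 1]
}
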