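# Gene-pair feature construction: shared-feature similarity, quantile
# discretization, jackknife correlations, interaction columns.

mini_fm <- function() {
  # g1 carries f1,f2; g2 carries f1,f2; g3 carries f3 only
  build_feature_matrix(data.frame(
    gene = c("g1", "g1", "g2", "g2", "g3", "g4"),
    feature = c("f1", "f2", "f1", "f2", "f3", "f1"),
    source = "domain"
  ))
}

test_that("shared-feature similarity is sum of squared shared frequencies", {
  fm <- mini_fm()
  freq <- feature_frequencies(fm)
  # f1 in 3/4 genes, f2 in 2/4: g1~g2 share both
  expect_equal(pair_similarity_score("g1", "g2", fm, freq),
               0.75^2 + 0.5^2)
  expect_equal(pair_similarity_score("g1", "g3", fm, freq), 0)
  expect_error(pair_similarity_score("g1", "gX", fm, freq), "unknown")
})

test_that("hand frequencies give the worked arithmetic", {
  fm <- mini_fm()
  freq <- stats::setNames(c(0.5, 0.1, 0.2), colnames(fm$matrix))
  expect_equal(pair_similarity_score("g1", "g2", fm, freq), 0.26)  # .25+.01
})

test_that("a clone pair scores the sum over all the gene's features", {
  fm <- build_feature_matrix(data.frame(
    gene = c("a", "a", "a", "b", "b", "b", "c"),
    feature = c("f1", "f2", "f3", "f1", "f2", "f3", "f1"),
    source = "domain"
  ))
  freq <- feature_frequencies(fm)
  manual <- 0
  for (f in colnames(fm$matrix))
    if (fm$matrix["a", f] == 1) manual <- manual + freq[[f]]^2
  expect_equal(pair_similarity_score("a", "b", fm, freq), manual)
})

test_that("vectorized pair similarities match the scalar computation", {
  b <- make_worked_fixture()
  fm <- build_feature_matrix(b$feature_table)
  freq <- feature_frequencies(fm)
  genes <- rownames(fm$matrix)
  sc <- pair_similarity_scores(genes, fm, freq, source = "domain")
  fm_dom <- structure(list(matrix = fm$matrix[, fm$source == "domain"],
                           source = fm$source[fm$source == "domain"]),
                      class = "feature_matrix")
  for (k in sample(nrow(sc), 10)) {
    expect_equal(sc$score[k],
                 pair_similarity_score(sc$g1[k], sc$g2[k], fm_dom, freq))
  }
})

test_that("top-quantile discretization: exact counts, ties, and nesting", {
  s <- stats::setNames(10:1, letters[1:10])
  flags <- discretize_top_quantiles(s, 0.1)
  expect_equal(sum(flags), 1)                      # exactly the max
  expect_equal(unname(flags["a", 1]), 1L)

  tied <- rep(5, 8)
  expect_true(all(discretize_top_quantiles(tied, c(.1, .5)) == 1))  # ties kept

  set.seed(11)
  r <- stats::runif(100)
  qs <- c(.1, .2, .3, .4, .5)
  flags <- discretize_top_quantiles(r, qs)
  for (j in seq_along(qs)) {
    expect_equal(unname(flags[, j]), unname(bf_top_quantile_flags(r, qs[j])))
  }
  # nested columns: membership in top-10% implies top-20% ... top-50%
  for (j in seq_len(length(qs) - 1)) {
    expect_true(all(flags[, j] <= flags[, j + 1]))
  }
})

test_that("zero scores are outside the reference distribution", {
  s <- c(rep(0, 90), stats::runif(10, 0.1, 1))
  flags <- discretize_top_quantiles(s, 0.5)
  expect_equal(sum(flags), 5)          # half of the 10 positives, not 50
  expect_true(all(flags[s == 0] == 0))
})

test_that("min-jackknife-1 Pearson is affine-invariant and outlier-aware", {
  x <- c(1, 3, 2, 5, 4, 6)
  expect_equal(min_jackknife1_pearson(x, 2 * x + 1), 1)

  # one extreme sample manufactures the correlation; the jackknife sees it
  x <- c(0.1, 0.2, 0.15, 0.1, 10)
  y <- c(0.2, 0.1, 0.12, 0.18, 9)
  loo <- vapply(1:5, function(i) stats::cor(x[-i], y[-i]), numeric(1))
  expect_equal(min_jackknife1_pearson(x, y), min(loo))
  expect_lt(min_jackknife1_pearson(x, y), stats::cor(x, y) - 0.5)

  # constant leave-one-out subvector -> undefined, with warning
  expect_warning(r <- min_jackknife1_pearson(c(1, 1, 1, 2), c(1, 2, 3, 4)),
                 "constant")
  expect_true(is.na(r))
})

test_that("near-orthogonal vectors give near-zero minimum correlation", {
  set.seed(5)
  x <- stats::rnorm(40)
  y <- stats::rnorm(40)
  y <- y - sum(x * y) / sum(x * x) * x     # orthogonal after centering-ish
  loo <- vapply(seq_along(x), function(i) stats::cor(x[-i], y[-i]), numeric(1))
  expect_equal(min_jackknife1_pearson(x, y), min(loo))
  expect_lt(abs(min_jackknife1_pearson(x, y)), 0.2)
})

test_that("coexpression bins: three nested columns per dataset", {
  set.seed(3)
  corr1 <- stats::rnorm(1000)
  corr2 <- stats::rnorm(1000)
  bins <- coexpression_bins(list(d1 = corr1, d2 = corr2))
  expect_equal(ncol(bins), 6)
  expect_equal(sum(bins[, "d1_top1"]), 10)     # top 1% of 1000
  expect_true(all(bins[, "d1_top1"] <= bins[, "d1_top5"]))
  expect_true(all(bins[, "d1_top5"] <= bins[, "d1_top10"]))
})

test_that("interaction column: homodimers dropped, orientation collapsed", {
  pairs <- all_pairs(c("a", "b", "c", "d"))
  edges <- data.frame(g1 = c("a", "b", "c", "a", "d", "b"),
                      g2 = c("b", "a", "c", "c", "a", "d"))
  col <- ppi_column(edges, pairs)
  # (a,b)+(b,a) collapse; (c,c) dropped; (a,c); (a,d); (b,d) -> 4 ones
  expect_equal(sum(col), 4)
  expect_equal(col[pair_key(pairs$g1, pairs$g2) == "a|b"], 1L)
})

test_that("pairs with missing expression get zero coexpression bins", {
  set.seed(9)
  expr <- matrix(stats::rnorm(3 * 10), 3, 10,
                 dimnames = list(c("a", "b", "c"), NULL))
  pairs <- all_pairs(c("a", "b", "c", "d"))
  corr <- pairwise_min_jackknife(expr, pairs)
  expect_true(all(is.na(corr[grepl("d", names(corr))])))
  bins <- coexpression_bins(list(d1 = corr))
  expect_true(all(bins[is.na(corr), ] == 0))
})

test_that("pair table is keyed canonically and has C(n,2) rows", {
  b <- make_worked_fixture()
  fm <- build_feature_matrix(b$feature_table)
  pft <- build_pair_feature_table(rownames(fm$matrix), fm,
                                  feature_frequencies(fm),
                                  expr_list = b$expression,
                                  ppi_edges = b$interactions)
  n <- nrow(fm$matrix)
  expect_equal(nrow(pft$X), n_gene_pairs(n))
  expect_true(all(pft$g1 < pft$g2))
  expect_equal(rownames(pft$X), pair_key(pft$g1, pft$g2))
  # 5 bins per annotation source present + 3 per dataset + ppi
  src_present <- sort(unique(fm$source))
  expect_equal(ncol(pft$X), 5 * length(src_present) + 3 + 1)
})
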