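---
title: "Predicting gene function from profiles and linkage networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting gene function from profiles and linkage networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funlink)
```

## The problem

Most genes in a mammalian genome lack experimentally grounded functional
annotation, and the evidence that could suggest functions — protein-domain
content, disease associations, orthology patterns, co-expression,
physical interactions — is scattered across heterogeneous resources.
`funlink` turns such evidence into a quantitative log-odds score for every
(gene, ontology term) combination, by combining two complementary
inference routes and evaluating them with precision–recall machinery
designed for many small, imbalanced classification problems.

The two routes formalize two different intuitions:

* **Guilt by profiling (GBP).** A gene's own attributes predict its
  functions. For each ontology term a random forest is trained on binary
  gene-centric features (domain signatures, disease identifiers,
  top-level phenotype terms, per-species ortholog presence), with the
  genes annotated to the term as positives and the remaining annotated
  ("training") genes as negatives.
* **Guilt by association (GBA).** Genes that interact, co-express, or
  share annotation patterns tend to share functions. A *functional
  linkage network* (FLN) — a complete weighted graph over the gene
  universe — is learned per term category by a random forest over
  gene-pair features, and annotations are transferred from each term's
  annotated "core set" through the network's edge weights.

## Inputs and term bookkeeping

Annotations arrive as dated, evidence-coded gene–term records (GAF);
the ontology as an OBO file whose `is_a` and `part_of` edges are treated
identically for propagation. Electronically inferred (IEA) records are
removed first — they are earlier predictions, and training on them would
launder prediction into ground truth. The remaining records are
up-propagated: a gene annotated to a term is annotated to all its
ancestors, with set semantics on diamond-shaped paths.

Terms with between 3 and 300 distinct annotated genes are selected —
below 3 a classifier has nothing to learn from, above 300 the term is too
generic to be a useful prediction target. Selected terms are stratified
into 12 evaluation categories: ontology branch (BP, CC, MF) crossed with
annotation-breadth bins [3,10], [11,30], [31,100], [101,300]. Genes with
at least one association to a selected term form the *training set*; the
rest of the universe is *undetermined* — scored by prediction, never used
in fitting.

## Gene-pair features

Each unordered pair of genes is described by sparse binary features:

* **Shared annotation patterns.** For each gene-centric source the pair
  scores $\sum_i f_i^2$ over the features carried by *both* genes, where
  $f_i$ is the carrier frequency of feature $i$ in the full gene
  universe. The score is discretized into five nested bins — membership
  in the top 10%, 20%, 30%, 40%, 50% of positive scores. As written, the
  score rewards *common* shared features; phenotype-similarity scores in
  the tradition this score descends from reward *rare* shared features
  instead ($f_i$ small). We implement the frequency-weighted form as the
  default and expose `weighting = "inverse"` (which substitutes
  $(1-f_i)^2$) for users who want rarity weighting; the forest downstream
  is in any case free to learn either polarity from the nested bins.
* **Co-expression.** Per expression dataset, the minimum-jackknife-1
  Pearson correlation — the worst leave-one-sample-out correlation — so a
  single extreme sample cannot manufacture a link. Discretized into
  nested top 1%, 5%, 10% bins per dataset. Pairs with a gene absent from
  a dataset get zeros there: absence is not evidence.
* **Interactions.** A single binary column; self-pairs (homodimers) are
  removed and orientations collapse onto a canonical pair key.

Two deliberate conventions here: quantile thresholds are computed over
pairs with a *defined, positive* score (for the sparse shared-annotation
sources; over all defined values for correlations), because top quantiles
of all $\binom{n}{2}$ pairs would be degenerate when almost every pair
scores zero; and ties at a bin boundary are included wholesale, which
makes discretization deterministic and order-independent. The five bins
are nested rather than exclusive — membership in a tighter bin implies
membership in every looser one — which gives the downstream forest
monotone threshold features rather than arbitrary decile indicators.

## Training networks and the category rule

Training labels live on pairs of training genes: a pair is positive for a
category's network when the two genes share at least one term of that
branch with annotation breadth in $[3, u]$, where $u$ is the category's
upper bound — a *cumulative* rule (the [31,100] network trains on sharing
of any term with fewer than 101 associations), with a strict-bin variant
behind `rule = "strict"`. Training pairs receive out-of-bag edge weights;
every remaining pair (anything touching an undetermined gene) receives a
predicted weight, so the network is complete: $n$ genes with $m$ training
genes leave $\binom{n}{2}-\binom{m}{2}$ predicted edges.

At full scale the branch roots carry thousands of annotations and never
qualify as shared-term evidence. At toy scale a propagated root can slip
under a bin's upper bound, making *every* training pair positive; the
pipeline detects the single-class degeneracy and skips that category with
a warning rather than fitting a meaningless network.

## Annotation transfer by density ratio

For a term with core set $C$ (its annotated training genes), two
edge-weight densities are estimated by Gaussian kernel density
estimation: *core-to-core*, from the $\binom{|C|}{2}$ clique weights, and
*noncore-to-core*, from all weights between non-core training genes and
$C$. A candidate gene $g$ is scored by

$$\mathrm{LLR}_{\mathrm{GBA}}(g) \;=\; \sum_{c \in C}
  \log \frac{\hat p_{\mathrm{core}}(w_{gc})}{\hat p_{\mathrm{noncore}}(w_{gc})},$$

summing evidence over its edges into the core.

Numerical choices, all tunable:

* **Pseudo-count.** Each density is augmented with one pseudo-observation
  uniform on $[0,1]$ so that neither density vanishes anywhere on the
  weight scale. The default realization is deterministic: the estimate is
  the mixture $\tfrac{n}{n+1}\,\mathrm{KDE} + \tfrac{1}{n+1}\,U(0,1)$,
  exactly the expectation of appending one uniform draw; `pseudo =
  "sample"` appends an actual seeded draw instead.
* **Bandwidth.** Silverman's rule on each sample; degenerate samples
  (fewer than two points, or zero variance) fall back to 0.05 on the unit
  weight scale — narrow enough to stay informative, wide enough not to
  spike.
* **Floor.** Densities are floored at $10^{-12}$ inside the logs, so no
  LLR is infinite even far outside both samples.

Terms with 10 or fewer annotated genes have too few clique edges for a
stable density; their densities are instead pooled across all the
category's terms, as multisets — an edge lying in two cores contributes
twice, since de-duplication would silently down-weight genes at the
intersection of related terms. Noncore-to-core samples for a term are
*not* purged of pairs that happen to be core-to-core for another term;
the literal construction keeps the two samples' definitions independent
across terms.

Training genes are scored leave-one-out: for each held-out gene, both
densities are re-estimated with every edge incident to that gene
excluded, the gene is scored against the core minus itself using
out-of-bag edge weights, and a gene whose removal leaves fewer than two
core genes falls back to the pooled densities (likewise excluding its
edges). These LOO scores are what the evaluation and the mixing
optimization consume, keeping both free of resubstitution optimism.

## Profile scores on the same scale

The combination below needs both sources as log-likelihood ratios. For
the association route the LLR is native; for the profile route the
forest's raw vote fraction must be calibrated. No canonical construction
exists for this step, so the package makes an interpretive choice,
symmetric with the transfer machinery: class-conditional Gaussian KDEs of
the positive and negative training genes' out-of-bag scores, each with
the same uniform pseudo-count augmentation and floor, give
$\mathrm{LLR}_{\mathrm{GBP}}(s) = \log \hat p_+(s) - \log \hat p_-(s)$.
One consequence of the pseudo-count is worth knowing: far outside both
score clouds the uniform components dominate and the LLR flattens toward
zero, so the map is monotone between the class modes but deliberately
conservative in the unsupported tails.

## Combination and evaluation

Per gene $i$ and term, the combined ("human function") log-odds is

$$\mathrm{LO}^{\mathrm{HF}}_i = \alpha\,\mathrm{LLR}^{\mathrm{GBP}}_i
  + (1-\alpha)\,\mathrm{LLR}^{\mathrm{GBA}}_i + \mathrm{LO}^{\mathrm{prior}},$$

where $\mathrm{LO}^{\mathrm{prior}} = \log\!\big(n_+/(n-n_+)\big)$ is the
term's prior log-odds over the training universe (constant per term, so
it shifts but never reorders genes within a term; it matters when scores
are compared across terms). The mixing coefficient $\alpha$ is chosen on
a grid of step 0.01 to maximize average precision of the cross-validated
(OOB / LOO) training scores, ties resolving to the smallest $\alpha$ —
per term, except in the [3,10] categories where one coefficient is fitted
per category to avoid optimizing a parameter on a handful of positives.
Because the grid contains 0 and 1, the optimized combination can never
fall below the better single source by more than the grid resolution on
the data it was optimized on.

Evaluation is deliberately rank-based. Precision–recall curves use one
point per distinct threshold; tied scores are resolved pessimistically
(every member of a tie block gets the block's worst precision), making
curves deterministic and order-independent. Average precision is the
mean, over positives, of precision at each positive's threshold — the
area under the PR step curve under this tie convention. Positives missing
from a score list count in the recall denominator but are never
retrieved, capping reachable recall. Many terms are summarized on a fixed
recall grid (step 0.01) by *cumulative* precision — the best precision at
recall at least $r$ (a raw step reading is available via
`cumulative = FALSE`) — from which decile contours are read off as
across-term quantiles; P20R, precision at the threshold first reaching
20% recall, is the headline single number.

The prospective protocol evaluates frozen predictions against
annotations added after a start date: per term, genes already positive
before the date are removed; the remainder is restricted to genes that
gained *any* annotation after the date (genes never revisited by curation
had no opportunity to gain the term); survivors newly annotated with the
term are the positives. Records with unparseable dates are excluded from
the date comparisons only.

## Networks as a deliverable

The FLNs are useful beyond score production. `threshold_top_fraction`
keeps the top fraction $q$ of the complete network's edges (ties at the
boundary included; the fraction is over all $\binom{n}{2}$ logical edges,
since the network is complete by construction), and `expand_seeds` grows
a disease seed set by one neighborhood and returns the induced subgraph —
including edges between two recruits, which is how two seed-centered
components can reveal a bridge. Expansion depth is fixed at 1 by default;
deeper expansion is available but quickly dilutes the seed signal. An
external interaction list can be overlaid on the exported subgraph as an
annotation layer; it plays no role in the expansion itself.

## What the generator emulates — and what it does not

`simulate_bundle()` plants exactly the structure the models assume:
module terms whose members share enriched features (each member carries a
module feature with probability `rho_f`, background genes with
`background_rate`), co-express through a shared latent factor (a module
gene's expression is $\sqrt{\rho_x}\,z_m + \sqrt{1-\rho_x}\,\varepsilon$),
and interact preferentially (`interaction_precision` of edges fall within
modules). Annotations are revealed in two dated epochs (`epoch_frac`
before the start date, the rest after, each module keeping at least three
first-epoch members so its term is trainable), with a tunable admixture
of IEA records to exercise evidence filtering. One master seed drives
everything; regeneration is byte-identical, and all outputs round-trip
through the package's own OBO/GAF/TSV readers.

The generator does *not* emulate: realistic ontology topology (its graphs
are two or three levels deep, so propagated roots sit much closer to the
leaves than in a real ontology), correlated feature redundancy (real
domain databases contain near-duplicate signatures), heavy-tailed
expression noise, study-biased annotation (which the prospective
literature documents as a real effect), or identifier drift between
resources. Passing tests on generated data therefore demonstrate that the
machinery recovers the signal it is designed for — not that any
particular real corpus carries that signal at a given strength.

## Problem sizes and reproducibility

The default generator configuration (120 genes, 12 module terms across
three branches, one 30-sample expression dataset, 150 interactions) is
sized so a full pipeline run completes in seconds while every stage —
including pooled transfer, LOO re-estimation and per-category networks —
is genuinely exercised; property suites use a 70-gene, five-module
variant across 20 seeds. Forests use 100 trees throughout, the package
default, grown to purity with $\sqrt{p}$ candidate features per split and
Gini impurity; mean-impurity-decrease importance is the default, with
permutation importance behind a flag. Training is single-threaded so a
fixed seed reproduces results exactly.

Two statistical facts matter when reading null-calibration output. At
small problem sizes the expected average precision of a *random* ranking
exceeds the raw positive rate (a finite-size property of AP), and
out-of-bag scores are mildly pessimistic on uninformative data (removing
an object from its scoring trees shifts the in-bag base rate against it).
Null checks therefore compare the procedure against the same procedure on
permuted labels — a baseline that shares both effects — rather than
against the bare positive rate.

## Known limitations

* The GBP score-to-LLR map is an interpretive construction (the
  combination equation fixes only the scale, not the calibration route);
  logistic calibration would be a reasonable alternative.
* Closed-world negatives: training genes not annotated to a term are
  treated as negatives, so missing annotations depress measured
  precision — the prospective protocol quantifies, but cannot remove,
  this effect.
* Per-term models are fitted independently; no hierarchical consistency
  is enforced between parent and child scores.
* Training a full-scale edge classifier on all training pairs is
  cluster-scale work; `negative_subsample` trades out-of-bag coverage of
  dropped negatives (they receive predicted weights instead) for
  tractability.

## A three-line tour

```{r tour, eval = FALSE}
bundle <- simulate_bundle(sim_config(seed = 1))
res <- run_pipeline(bundle, seed = 1)
pipeline_mean_ap(res)        # mean cross-validated AP: gbp, gba, hf
```
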