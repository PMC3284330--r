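# One-dimensional Gaussian kernel density estimation with a uniform
# pseudo-count component, the density machinery behind annotation transfer.
#
# Edge weights and classifier scores live on [0,1]. Class-conditional
# densities estimated from small samples can vanish where the other class
# has mass, making log-likelihood ratios blow up. Both score-to-LLR maps
# therefore augment every estimated density with one "pseudo-sample"
# uniformly distributed on [0,1]. Two equivalent-in-intent realizations are
# provided:
#   * "mixture" (default): the density is the deterministic mixture
#     n/(n+1) * KDE(sample) + 1/(n+1) * Uniform(0,1) — the uniform
#     pseudo-observation enters as its exact distribution, no draw needed;
#   * "sample": a single Uniform(0,1) draw is appended to the sample before
#     the KDE is built (reproducible only under a seed).

#' Gaussian kernel density with uniform pseudo-count
#'
#' @param sample numeric vector of observations (scores or edge weights,
#'   nominally in `[0,1]`).
#' @param bw kernel bandwidth; default Silverman's rule
#'   ([stats::bw.nrd0()]). Degenerate samples (fewer than 2 points or zero
#'   variance) fall back to `bw = 0.05`, a narrow kernel on the unit scale.
#' @param pseudo `"mixture"` (deterministic, default) or `"sample"`
#'   (append one uniform draw; caller controls the RNG state).
#' @return an object of class `fl_kde`; evaluate it with [kde_density()].
#' @export
fl_kde <- function(sample, bw = NULL, pseudo = c("mixture", "sample")) {
  pseudo <- match.arg(pseudo)
  sample <- as.numeric(sample)
  if (length(sample) < 1) stop("need at least one observation")
  n_raw <- length(sample)
  if (pseudo == "sample") sample <- c(sample, stats::runif(1))
  if (is.null(bw)) {
    bw <- if (length(sample) >= 2 && stats::sd(sample) > 0)
      stats::bw.nrd0(sample) else 0.05
  }
  if (!is.finite(bw) || bw <= 0) bw <- 0.05
  structure(
    list(sample = sample, bw = bw, n = n_raw, pseudo = pseudo),
    class = "fl_kde"
  )
}

#' Evaluate a pseudo-count-augmented kernel density
#'
#' @param kde an [fl_kde()] object.
#' @param x numeric vector of evaluation points.
#' @return densities at `x`; strictly positive on `[0,1]`.
#' @export
kde_density <- function(kde, x) {
  stopifnot(inherits(kde, "fl_kde"))
  s <- kde$sample
  d <- vapply(x, function(xi) mean(stats::dnorm(xi, mean = s, sd = kde$bw)),
              numeric(1))
  if (kde$pseudo == "mixture") {
    w <- length(s) / (length(s) + 1)
    d <- w * d + (1 - w) * stats::dunif(x, 0, 1)
  }
  d
}

#' @export
print.fl_kde <- function(x, ...) {
  cat(sprintf("Gaussian KDE: n = %d, bw = %.4g, pseudo-count = %s\n",
              x$n, x$bw, x$pseudo))
  invisible(x)
}
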