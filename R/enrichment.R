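#' @include AllClasses.R
NULL

#' Fold enrichment of a property within a gene subset
#'
#' Computes the fraction of subset genes with a property divided by the
#' background fraction, `(k/n)/(K/M)`. Optionally adds the exact
#' hypergeometric upper-tail probability of observing at least `k` property
#' genes in `n` draws from `M` genes of which `K` carry the property
#' (computed by summing the point probabilities term by term). The p-value is
#' an optional extra for users; the fold value alone describes the
#' enrichment.
#'
#' @param k subset genes with the property (e.g. oscillating target genes).
#' @param n subset size.
#' @param K background genes with the property.
#' @param M background size.
#' @param pValue also compute the exact tail probability?
#' @return an [EnrichmentResult-class]
#' @examples
#' foldEnrichment(28, 40, 2000, 5000)  # 1.75-fold
#' @export
foldEnrichment <- function(k, n, K, M, pValue = FALSE) {
  if (k < 0) stop("violated bound: k >= 0")
  if (n <= 0) stop("violated bound: n > 0")
  if (k > n) stop("violated bound: k <= n")
  if (n > M) stop("violated bound: n <= M")
  if (K <= 0) stop("violated bound: K > 0")
  if (K > M) stop("violated bound: K <= M")
  if (k > K) stop("violated bound: k <= K")
  fold <- (k / n) / (K / M)
  p <- NA_real_
  if (pValue)
    p <- sum(stats::dhyper(seq(k, min(n, K)), m = K, n = M - K, k = n))
  new("EnrichmentResult", k = k, n = n, K = K, M = M, fold = fold,
      pValue = p)
}

#' Percentage of a subset with a property
#'
#' @param k genes with the property.
#' @param n subset size (> 0).
#' @return `100 * k / n`
#' @examples
#' fractionOscillating(28, 40)  # 70
#' @export
fractionOscillating <- function(k, n) {
  if (n == 0) stop("violated bound: n > 0")
  if (k < 0 || k > n) stop("violated bound: 0 <= k <= n")
  100 * k / n
}
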