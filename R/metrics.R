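#' Coefficient-of-variation feature filter
#'
#' Ranks features by the absolute coefficient of variation |sd / mean| and
#' keeps the top fraction, the standard variance filter applied to
#' log-transformed omic matrices before clustering. Features with zero mean
#' are treated as infinitely variable (kept first) with a warning; ties
#' keep the original feature order.
#'
#' @param x Feature-by-sample matrix.
#' @param keep Fraction of features to keep, in (0, 1] (default 0.5).
#' @return The filtered matrix (top `ceiling(keep * nfeatures)` rows).
#' @export
cv_filter <- function(x, keep = 0.5) {
  if (keep <= 0 || keep > 1) stop("keep must be in (0, 1]")
  x <- as_expression_matrix(x)
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, sd)
  cv <- abs(sdv / mu)
  if (any(mu == 0)) {
    warning("zero-mean feature(s): coefficient of variation taken as Inf")
    cv[mu == 0] <- Inf
  }
  n_keep <- ceiling(keep * nrow(x))
  ord <- order(-cv, seq_along(cv))       # ties by original feature order
  x[sort(ord[seq_len(n_keep)]), , drop = FALSE]
}

#' Normalised mutual information between two partitions
#'
#' Mutual information normalised by the arithmetic mean of the two label
#' entropies, in [0, 1]; invariant to label permutation. Used to score
#' clusterings against known classes (for example cell-type labels).
#'
#' @param a,b Label vectors over the same samples (any atomic type).
#' @return NMI in [0, 1]. If either partition has a single label the score
#'   is 0 with a warning.
#' @export
nmi <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  ct <- table(a, b)
  n <- sum(ct)
  pa <- rowSums(ct) / n
  pb <- colSums(ct) / n
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha == 0 || hb == 0) {
    warning("degenerate single-label partition: NMI undefined, returning 0")
    return(0)
  }
  p <- ct / n
  e <- outer(pa, pb)
  mi <- sum(p[p > 0] * log(p[p > 0] / e[p > 0]))
  mi / mean(c(ha, hb))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected partition agreement (1 = identical, ~0 = random).
#' Thin wrapper around \code{mclust::adjustedRandIndex}.
#'
#' @param a,b Label vectors over the same samples.
#' @return The adjusted Rand index.
#' @export
ari <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  mclust::adjustedRandIndex(a, b)
}
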