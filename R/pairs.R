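#' @include AllGenerics.R
NULL

## Pairwise order counts. For a G x N matrix, L[i, j] is the number of
## samples with value_i < value_j; exact ties contribute to neither
## orientation. Dense G x G accumulation: fine up to a few thousand
## lncRNAs, which is the regime of array/RNA-seq lncRNA panels.
.lessCounts <- function(m) {
  g <- nrow(m)
  L <- matrix(0L, g, g)
  for (s in seq_len(ncol(m))) {
    v <- m[, s]
    L <- L + outer(v, v, "<")
  }
  dimnames(L) <- list(rownames(m), rownames(m))
  L
}

#' @describeIn rankTransform matrix method (columns are samples)
#' @export
setMethod("rankTransform", "matrix", function(x) {
  if (anyNA(x) || any(!is.finite(x)))
    stop("expression values must be finite")
  apply(x, 2L, rank, ties.method = "average")
})

#' @describeIn rankTransform LncExpression method; returns the rank matrix
#'   of all samples (groups unchanged, query with \code{groupLabels})
#' @export
setMethod("rankTransform", "LncExpression", function(x) {
  rankTransform(SummarizedExperiment::assay(x, "expr"))
})

#' Detect stable lncRNA pairs in normal samples
#'
#' An ordered pair (low, high) is stable when low < high holds in strictly
#' more than \code{stabilityFrac} of the usable normal samples; samples in
#' which the two values tie exactly are dropped from that pair's count.
#' The orientation is canonical: low is the member below in normals, so
#' each stable relation is stored exactly once.
#'
#' @param normal numeric matrix of normal samples (lncRNAs x samples) or
#'   an \linkS4class{LncExpression} (its normal samples are used)
#' @param stabilityFrac support threshold in (0.5, 1]; default 0.95,
#'   applied strictly (support of exactly 95\% is not stable).
#' @return a \linkS4class{StablePairSet}
#' @examples
#' m <- matrix(c(1, 2, 3, 1.1, 2.2, 3.3), 3, 2,
#'             dimnames = list(c("a", "b", "c"), c("s1", "s2")))
#' findStablePairs(m)
#' @export
findStablePairs <- function(normal, stabilityFrac = 0.95) {
  if (is(normal, "LncExpression")) normal <- normalMatrix(normal)
  if (stabilityFrac <= 0.5 || stabilityFrac > 1)
    stop("'stabilityFrac' must lie in (0.5, 1]")
  if (ncol(normal) < 2L)
    stop("at least 2 normal samples are required")
  L <- .lessCounts(normal)
  a <- L            # low < high
  b <- t(L)         # low > high
  nUsed <- a + b
  sel <- nUsed > 0L & (a / nUsed) > stabilityFrac
  diag(sel) <- FALSE
  idx <- which(sel, arr.ind = TRUE)
  ids <- rownames(normal)
  ord <- order(idx[, 1L], idx[, 2L])
  idx <- idx[ord, , drop = FALSE]
  pairs <- S4Vectors::DataFrame(
    low = ids[idx[, 1L]],
    high = ids[idx[, 2L]],
    a = as.integer(a[idx]),
    b = as.integer(b[idx]),
    nUsed = as.integer(nUsed[idx]),
    frac = a[idx] / nUsed[idx])
  new("StablePairSet", pairs = pairs,
      stabilityFrac = stabilityFrac, nNormal = ncol(normal))
}

#' One-sided binomial stability p-value
#'
#' Probability of observing at least \code{kMin} successes in \code{n}
#' fair coin flips, the null reference for a pair order holding in
#' \code{kMin} of \code{n} normal samples. Exact upper-tail summation.
#'
#' @param kMin minimum number of concordant samples, 0..n
#' @param n number of samples
#' @return the upper-tail probability P(X >= kMin | n, 1/2)
#' @examples
#' binomialStabilityPvalue(95, 100)   # 6.26e-23
#' @export
binomialStabilityPvalue <- function(kMin, n) {
  if (length(kMin) != 1L || length(n) != 1L || is.na(kMin) || is.na(n) ||
      kMin < 0 || n < 0 || kMin > n)
    stop("need 0 <= kMin <= n")
  stats::pbinom(kMin - 1, n, 0.5, lower.tail = FALSE)
}

#' One-sided Fisher p-value for order reversal
#'
#' For a stable pair with 2x2 counts a/b (normal: low<high, low>high) and
#' c/d (cancer likewise), tests whether the reversed orientation (d) is
#' enriched in cancer: the hypergeometric upper tail over tables with the
#' observed margins. Vectorised over pairs.
#'
#' @param a,b,c,d nonnegative integer counts (recycled to a common length)
#' @return p-value vector
#' @examples
#' fisherReversalPvalue(10, 0, 0, 10)   # 1 / choose(20, 10)
#' @export
fisherReversalPvalue <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n)
  c <- rep_len(c, n); d <- rep_len(d, n)
  if (any(is.na(a + b + c + d)) || any(c(a, b, c, d) < 0))
    stop("counts must be nonnegative")
  if (any(a + b + c + d == 0))
    stop("all-zero contingency table")
  stats::phyper(d - 1, b + d, a + c, c + d, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment, order-preserving with the input.
#'
#' @param pvals p-values in [0, 1]
#' @return adjusted q-values in the input order
#' @export
bhAdjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Detect reversal lncRNA pairs in cancer samples
#'
#' For every stable pair, builds the 2x2 orientation table against the
#' cancer samples, computes the one-sided Fisher p
#' (\code{\link{fisherReversalPvalue}}), adjusts by Benjamini-Hochberg
#' across the whole family of stable pairs tested, and retains pairs with
#' q below \code{fdr}. A retained flip implies the former-low member is
#' up-regulated and the former-high member down-regulated.
#'
#' @param stablePairs a \linkS4class{StablePairSet} derived from the same
#'   normal cohort
#' @param cancer numeric matrix of cancer samples (same lncRNA universe)
#'   or an \linkS4class{LncExpression} (its cancer samples are used)
#' @param fdr BH threshold, default 0.1 (strict: q < fdr)
#' @return a \linkS4class{ReversalPairSet}
#' @export
findReversalPairs <- function(stablePairs, cancer, fdr = 0.1) {
  if (is(cancer, "LncExpression")) cancer <- cancerMatrix(cancer)
  if (ncol(cancer) < 1L) stop("cancer group is empty")
  sp <- stablePairs@pairs
  if (nrow(sp) == 0L) {
    warning("empty stable pair set; no reversal pairs")
    return(new("ReversalPairSet",
               pairs = S4Vectors::DataFrame(
                 low = character(), high = character(),
                 a = integer(), b = integer(),
                 c = integer(), d = integer(),
                 p = numeric(), q = numeric()),
               fdr = fdr, nTested = 0L))
  }
  miss <- setdiff(unique(c(sp$low, sp$high)), rownames(cancer))
  if (length(miss))
    stop("lncRNA(s) absent from the cancer matrix: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  Lc <- .lessCounts(cancer)
  li <- match(sp$low, rownames(cancer))
  hi <- match(sp$high, rownames(cancer))
  cc <- Lc[cbind(li, hi)]
  d <- Lc[cbind(hi, li)]
  p <- fisherReversalPvalue(sp$a, sp$b, cc, d)
  q <- bhAdjust(p)
  keep <- q < fdr
  pairs <- S4Vectors::DataFrame(
    low = sp$low[keep], high = sp$high[keep],
    a = sp$a[keep], b = sp$b[keep],
    c = as.integer(cc[keep]), d = as.integer(d[keep]),
    p = p[keep], q = q[keep])
  new("ReversalPairSet", pairs = pairs, fdr = fdr,
      nTested = nrow(sp))
}
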