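#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' LncExpression: a lncRNA-by-sample expression container
#'
#' Thin extension of \linkS4class{SummarizedExperiment} holding one assay
#' (\code{"expr"}, log2-scale by convention) and a per-sample \code{group}
#' column restricted to \code{"normal"} / \code{"cancer"}. The rank-based
#' machinery downstream only uses within-sample orderings, so any monotone
#' preprocessing of the values is acceptable.
#'
#' Missing values are rejected: the rank machinery has no NA semantics.
#'
#' @slot .Data see \linkS4class{SummarizedExperiment}
#' @export
setClass("LncExpression", contains = "SummarizedExperiment")

.validLncExpression <- function(object) {
  msg <- NULL
  v <- SummarizedExperiment::assay(object, "expr")
  if (!is.numeric(v))
    msg <- c(msg, "assay 'expr' must be numeric")
  if (anyNA(v) || any(!is.finite(v)))
    msg <- c(msg, "expression values must be finite and non-missing")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate lncRNA identifiers")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample identifiers")
  grp <- object$group
  if (is.null(grp)) {
    msg <- c(msg, "colData must contain a 'group' column")
  } else if (!all(grp %in% c("normal", "cancer"))) {
    msg <- c(msg, "group labels must be 'normal' or 'cancer'")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("LncExpression", .validLncExpression)

#' Construct an LncExpression object
#'
#' @param values numeric matrix, lncRNAs in rows, samples in columns;
#'   dimnames required.
#' @param group character vector of per-sample labels in
#'   \code{c("normal", "cancer")}, recycled never; length \code{ncol(values)}.
#' @return an \linkS4class{LncExpression}
#' @examples
#' m <- matrix(rnorm(12, 8), 3, 4,
#'             dimnames = list(paste0("lnc", 1:3), paste0("s", 1:4)))
#' x <- LncExpression(m, rep(c("normal", "cancer"), each = 2))
#' @export
LncExpression <- function(values, group) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry lncRNA row names and sample column names")
  if (length(group) != ncol(values))
    stop("'group' must have one label per sample")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = values),
    colData = S4Vectors::DataFrame(group = as.character(group),
                                   row.names = colnames(values)))
  new("LncExpression", se)
}

#' Stable lncRNA pairs in normal tissue
#'
#' Ordered pairs (low, high) whose within-sample order low < high holds in
#' strictly more than \code{stabilityFrac} of the usable normal samples
#' (samples where the two values tie are dropped from that pair's count).
#'
#' @slot pairs DataFrame with columns \code{low}, \code{high}, \code{a}
#'   (samples with low < high), \code{b} (samples with low > high),
#'   \code{nUsed} (= a + b) and \code{frac} (= a / nUsed).
#' @slot stabilityFrac the threshold used (strict inequality).
#' @slot nNormal number of normal samples screened.
#' @export
setClass("StablePairSet",
  representation(pairs = "DataFrame", stabilityFrac = "numeric",
                 nNormal = "integer"))

setValidity("StablePairSet", function(object) {
  p <- object@pairs
  need <- c("low", "high", "a", "b", "nUsed", "frac")
  if (!all(need %in% colnames(p)))
    return(paste("pairs must have columns", paste(need, collapse = ", ")))
  if (nrow(p) && any(p$frac <= object@stabilityFrac))
    return("all stored pairs must exceed the stability threshold")
  if (object@stabilityFrac <= 0.5 || object@stabilityFrac > 1)
    return("stabilityFrac must lie in (0.5, 1]")
  TRUE
})

#' Reversal lncRNA pairs
#'
#' Stable pairs whose order is significantly flipped in cancer. For each
#' pair the 2x2 table is a/b (normal: low<high / low>high) and c/d (cancer
#' likewise); the one-sided Fisher p tests enrichment of the reversed
#' orientation d in cancer, and q is the Benjamini-Hochberg adjusted value
#' over the whole family of stable pairs tested in the run. The flip
#' implies directions for the members: the former-low member is
#' up-regulated, the former-high member down-regulated.
#'
#' @slot pairs DataFrame with columns \code{low}, \code{high}, \code{a},
#'   \code{b}, \code{c}, \code{d}, \code{p}, \code{q}.
#' @slot fdr FDR threshold applied to q.
#' @slot nTested size of the BH family (number of stable pairs tested).
#' @export
setClass("ReversalPairSet",
  representation(pairs = "DataFrame", fdr = "numeric", nTested = "integer"))

setValidity("ReversalPairSet", function(object) {
  p <- object@pairs
  need <- c("low", "high", "a", "b", "c", "d", "p", "q")
  if (!all(need %in% colnames(p)))
    return(paste("pairs must have columns", paste(need, collapse = ", ")))
  if (nrow(p) && any(p$q < p$p - 1e-12))
    return("BH-adjusted q must be >= p")
  if (nrow(p) && any(p$q >= object@fdr))
    return("stored pairs must satisfy q < fdr")
  TRUE
})

#' Per-sample differential expression calls
#'
#' The method's primary output: a lncRNA-by-cancer-sample matrix of calls
#' in \code{up} / \code{down} / \code{none}, plus the per-target audit
#' trail (population direction, selected reversal partners and their rank
#' coefficients of variation) and the reversal pairs it was built from.
#'
#' @slot calls character matrix, values in up/down/none.
#' @slot targets DataFrame, one row per callable target: \code{lnc},
#'   \code{direction}, \code{nPartners}, \code{partners} (comma-joined,
#'   CV-ascending), \code{partnerCV} (comma-joined).
#' @slot reversalPairs the \linkS4class{ReversalPairSet} used.
#' @slot params list of pipeline parameters.
#' @export
setClass("DECalls",
  representation(calls = "matrix", targets = "DataFrame",
                 reversalPairs = "ReversalPairSet", params = "list"))

setValidity("DECalls", function(object) {
  if (!all(object@calls %in% c("up", "down", "none")))
    return("calls must be 'up', 'down' or 'none'")
  tg <- object@targets
  if (nrow(tg) && !all(tg$direction %in% c("up", "down")))
    return("target directions must be 'up' or 'down'")
  TRUE
})

#' A prognostic lncRNA signature
#'
#' Ordered members retained by forward selection, each with the DE
#' direction associated with worse survival. A patient is high-risk iff at
#' least one member is called DE in its risk direction (union rule).
#'
#' @slot members DataFrame: \code{lnc}, \code{riskDirection},
#'   \code{cIndex}, \code{logrankP}, \code{coxP}, \code{hr}.
#' @slot cIndex combined Harrell C-index of the union-rule risk groups.
#' @slot path DataFrame recording each forward-selection step.
#' @export
setClass("LncSignature",
  representation(members = "DataFrame", cIndex = "numeric",
                 path = "DataFrame"))

setValidity("LncSignature", function(object) {
  m <- object@members
  if (!all(c("lnc", "riskDirection") %in% colnames(m)))
    return("members must have columns lnc, riskDirection")
  if (anyDuplicated(m$lnc)) return("signature members must be unique")
  if (nrow(m) && !all(m$riskDirection %in% c("up", "down")))
    return("risk directions must be 'up' or 'down'")
  TRUE
})
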