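#' @include AllGenerics.R
NULL

#' @describeIn LncExpression per-sample group labels
#' @param x an LncExpression
#' @export
setMethod("groupLabels", "LncExpression", function(x) {
  stats::setNames(as.character(x$group), colnames(x))
})

#' @describeIn LncExpression expression values of the normal samples
#' @export
setMethod("normalMatrix", "LncExpression", function(x) {
  SummarizedExperiment::assay(x, "expr")[, x$group == "normal", drop = FALSE]
})

#' @describeIn LncExpression expression values of the cancer samples
#' @export
setMethod("cancerMatrix", "LncExpression", function(x) {
  SummarizedExperiment::assay(x, "expr")[, x$group == "cancer", drop = FALSE]
})

setMethod("show", "LncExpression", function(object) {
  grp <- table(factor(object$group, c("normal", "cancer")))
  cat("LncExpression:", nrow(object), "lncRNAs x", ncol(object), "samples",
      sprintf("(%d normal, %d cancer)\n", grp["normal"], grp["cancer"]))
})

#' @describeIn StablePairSet per-pair statistics as a data.frame
#' @param x a StablePairSet
#' @export
setMethod("pairTable", "StablePairSet", function(x) as.data.frame(x@pairs))

#' @describeIn ReversalPairSet per-pair statistics as a data.frame,
#'   including the implied member directions (\code{upMember} is the
#'   former-low member, \code{downMember} the former-high member)
#' @param x a ReversalPairSet
#' @export
setMethod("pairTable", "ReversalPairSet", function(x) {
  df <- as.data.frame(x@pairs)
  if (nrow(df)) {
    df$upMember <- df$low
    df$downMember <- df$high
  }
  df
})

setMethod("length", "StablePairSet", function(x) nrow(x@pairs))
setMethod("length", "ReversalPairSet", function(x) nrow(x@pairs))

setMethod("show", "StablePairSet", function(object) {
  cat("StablePairSet:", nrow(object@pairs), "ordered pairs stable in >",
      sprintf("%.0f%%", 100 * object@stabilityFrac), "of",
      object@nNormal, "normal samples\n")
})

setMethod("show", "ReversalPairSet", function(object) {
  cat("ReversalPairSet:", nrow(object@pairs), "of", object@nTested,
      "stable pairs reversed in cancer at BH FDR <", object@fdr, "\n")
})

#' @describeIn DECalls the lncRNA-by-sample call matrix
#' @param x a DECalls
#' @export
setMethod("callMatrix", "DECalls", function(x) x@calls)

#' @describeIn DECalls the per-target audit table
#' @export
setMethod("targetAudit", "DECalls", function(x) as.data.frame(x@targets))

setMethod("show", "DECalls", function(object) {
  cc <- object@calls
  cat("DECalls:", nrow(cc), "lncRNAs x", ncol(cc), "cancer samples;",
      sum(cc == "up"), "up and", sum(cc == "down"), "down calls across",
      nrow(object@targets), "callable targets\n")
})

#' @describeIn LncSignature member table
#' @param x a LncSignature
#' @export
setMethod("signatureMembers", "LncSignature",
          function(x) as.data.frame(x@members))

#' @describeIn LncSignature combined Harrell C-index under the union rule
#' @export
setMethod("combinedCIndex", "LncSignature", function(x) x@cIndex)

setMethod("show", "LncSignature", function(object) {
  m <- object@members
  cat("LncSignature:", nrow(m), "lncRNA(s), combined C-index",
      sprintf("%.3f\n", object@cIndex))
  if (nrow(m))
    cat(paste0("  ", m$lnc, " (risk: ", m$riskDirection, ")",
               collapse = "\n"), "\n")
})
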