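#' @include AllClasses.R
NULL

#' Per-sample group labels
#' @param x an object with per-sample groups
#' @return character vector of labels
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' Expression submatrix of the normal samples
#' @param x an \linkS4class{LncExpression}
#' @return numeric matrix
#' @export
setGeneric("normalMatrix", function(x) standardGeneric("normalMatrix"))

#' Expression submatrix of the cancer samples
#' @param x an \linkS4class{LncExpression}
#' @return numeric matrix
#' @export
setGeneric("cancerMatrix", function(x) standardGeneric("cancerMatrix"))

#' Within-sample rank transformation
#'
#' Converts each sample (column) to ranks: the smallest expression value
#' gets rank 1, the largest rank G; exact ties receive the average rank.
#' Any strictly increasing transform of the values leaves the result
#' unchanged, which is the basis of the method's robustness to
#' normalisation and batch effects.
#'
#' @param x numeric matrix or \linkS4class{LncExpression}
#' @return object of the same shape holding per-sample ranks
#' @examples
#' rankTransform(cbind(s1 = c(2, 5, 3)))
#' @export
setGeneric("rankTransform", function(x) standardGeneric("rankTransform"))

#' Filter lncRNAs by expression support
#'
#' Retains lncRNAs with non-zero expression in at least
#' \code{minNonzeroFrac} of samples (inclusive threshold). Row order is
#' preserved and the operation is idempotent.
#'
#' @param x numeric matrix or \linkS4class{LncExpression}
#' @param minNonzeroFrac required fraction of samples with value != 0,
#'   in (0, 1]; default 0.9.
#' @return filtered object of the same class
#' @export
setGeneric("filterExpressed",
  function(x, minNonzeroFrac = 0.9) standardGeneric("filterExpressed"))

#' Aggregate probe-level values to lncRNAs
#'
#' Each lncRNA's expression is the arithmetic mean of its mapped probes'
#' values, computed on the scale provided (summarisation does not change
#' scale). Unmapped probes are dropped with a message.
#'
#' @param x numeric matrix with probe IDs as row names
#' @param probeMap data.frame with columns \code{probe_id}, \code{lnc_id};
#'   each probe maps to exactly one lncRNA.
#' @return matrix with one row per lncRNA
#' @export
setGeneric("aggregateProbes",
  function(x, probeMap) standardGeneric("aggregateProbes"))

#' Pair table of a pair set
#' @param x a \linkS4class{StablePairSet} or \linkS4class{ReversalPairSet}
#' @return data.frame of per-pair statistics
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))

#' Call matrix of a DECalls object
#' @param x a \linkS4class{DECalls}
#' @return character matrix (lncRNA x cancer sample) in up/down/none
#' @export
setGeneric("callMatrix", function(x) standardGeneric("callMatrix"))

#' Per-target audit table of a DECalls object
#' @param x a \linkS4class{DECalls}
#' @return data.frame: target, direction, selected partners and their CVs
#' @export
setGeneric("targetAudit", function(x) standardGeneric("targetAudit"))

#' Members of a signature
#' @param x a \linkS4class{LncSignature}
#' @return data.frame of members with risk directions and statistics
#' @export
setGeneric("signatureMembers",
  function(x) standardGeneric("signatureMembers"))

#' Combined C-index of a signature
#' @param x a \linkS4class{LncSignature}
#' @return numeric scalar
#' @export
setGeneric("combinedCIndex", function(x) standardGeneric("combinedCIndex"))

#' Run the individual-level DE calling pipeline
#'
#' @param normal normal-group expression (matrix) or an
#'   \linkS4class{LncExpression} holding both groups
#' @param cancer cancer-group expression matrix (omit when \code{normal}
#'   is an \linkS4class{LncExpression})
#' @param ... passed on to methods
#' @return a \linkS4class{DECalls}
#' @export
setGeneric("lncrindiv",
  function(normal, cancer, ...) standardGeneric("lncrindiv"))
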