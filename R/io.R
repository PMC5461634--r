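#' @include AllGenerics.R
NULL

## All tables in this package are tab-separated text with a header row.
## Expression files: first column = lnc_id, remaining columns = samples.
## Values are written with 10 significant digits, so a read/write round
## trip is value-exact for data carrying up to that precision.

.readTable <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read an expression matrix and its phenotype table
#'
#' @param path TSV file; first column lncRNA IDs, header row of sample IDs.
#' @param phenotypePath TSV file with columns \code{sample_id} and
#'   \code{group} (normal/cancer); may carry further phenotype columns,
#'   which are ignored here.
#' @return an \linkS4class{LncExpression} with groups attached; row and
#'   column order as in the file.
#' @export
readExpression <- function(path, phenotypePath) {
  df <- .readTable(path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated lncRNA identifier(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (anyDuplicated(colnames(m)))
    stop("duplicated sample identifier(s) in ", path)
  storage.mode(m) <- "double"
  if (anyNA(m))
    stop("missing values in expression matrix; NA is not supported")
  rownames(m) <- ids
  ph <- .readTable(phenotypePath)
  if (!all(c("sample_id", "group") %in% colnames(ph)))
    stop("phenotype file must have columns 'sample_id' and 'group'")
  miss <- setdiff(colnames(m), ph$sample_id)
  if (length(miss))
    stop("sample(s) missing from phenotype table: ",
         paste(miss, collapse = ", "))
  grp <- ph$group[match(colnames(m), ph$sample_id)]
  LncExpression(m, grp)
}

#' Write an expression matrix and phenotype table
#'
#' @param x an \linkS4class{LncExpression}
#' @param path output TSV for the matrix
#' @param phenotypePath output TSV for the sample/group table
#' @return invisibly, \code{path}
#' @export
writeExpression <- function(x, path, phenotypePath) {
  m <- SummarizedExperiment::assay(x, "expr")
  df <- data.frame(lnc_id = rownames(m),
                   matrix(sprintf("%.10g", m), nrow(m), ncol(m)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("lnc_id", colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ph <- data.frame(sample_id = colnames(m),
                   group = as.character(x$group))
  utils::write.table(ph, phenotypePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-lncRNA map
#'
#' @param path TSV with columns \code{probe_id} and \code{lnc_id}
#'   (many probes per lncRNA allowed; each probe maps to exactly one
#'   lncRNA).
#' @return data.frame with columns probe_id, lnc_id
#' @export
readProbeMap <- function(path) {
  pm <- .readTable(path)
  if (!all(c("probe_id", "lnc_id") %in% colnames(pm)))
    stop("probe map must have columns 'probe_id' and 'lnc_id'")
  pm <- unique(pm[, c("probe_id", "lnc_id")])
  if (anyDuplicated(pm$probe_id))
    stop("probe(s) mapped to more than one lncRNA: ",
         paste(unique(pm$probe_id[duplicated(pm$probe_id)]), collapse = ", "))
  pm
}

#' @describeIn aggregateProbes probe matrix with probe IDs as row names
#' @export
setMethod("aggregateProbes", "matrix", function(x, probeMap) {
  if (anyDuplicated(probeMap$probe_id))
    stop("probe(s) mapped to more than one lncRNA")
  keep <- rownames(x) %in% probeMap$probe_id
  if (!any(keep))
    stop("no probe in the matrix is present in the probe map")
  dropped <- sum(!keep)
  if (dropped)
    message(dropped, " unmapped probe(s) dropped")
  xm <- x[keep, , drop = FALSE]
  lnc <- probeMap$lnc_id[match(rownames(xm), probeMap$probe_id)]
  sums <- rowsum(xm, group = lnc, reorder = FALSE)
  n <- as.vector(table(factor(lnc, levels = rownames(sums))))
  sums / n
})

#' @describeIn aggregateProbes aggregate the assay of an LncExpression
#'   whose rows are probes; groups are preserved
#' @export
setMethod("aggregateProbes", "LncExpression", function(x, probeMap) {
  m <- aggregateProbes(SummarizedExperiment::assay(x, "expr"), probeMap)
  LncExpression(m, as.character(x$group))
})

.filterRows <- function(m, minNonzeroFrac) {
  if (minNonzeroFrac <= 0 || minNonzeroFrac > 1)
    stop("'minNonzeroFrac' must lie in (0, 1]")
  frac <- rowMeans(m != 0)
  keep <- frac >= minNonzeroFrac
  if (!any(keep))
    stop("no lncRNA passes the expression filter")
  keep
}

#' @describeIn filterExpressed matrix method
#' @export
setMethod("filterExpressed", "matrix", function(x, minNonzeroFrac = 0.9) {
  x[.filterRows(x, minNonzeroFrac), , drop = FALSE]
})

#' @describeIn filterExpressed LncExpression method
#' @export
setMethod("filterExpressed", "LncExpression",
          function(x, minNonzeroFrac = 0.9) {
  keep <- .filterRows(SummarizedExperiment::assay(x, "expr"), minNonzeroFrac)
  x[keep, ]
})

#' Write a per-sample call matrix as TSV
#'
#' Cells hold \code{up}, \code{down} or \code{none}; first column
#' \code{lnc_id}, remaining columns cancer samples.
#'
#' @param calls a \linkS4class{DECalls} or a character call matrix
#' @param path output file
#' @return invisibly, \code{path}
#' @export
writeCalls <- function(calls, path) {
  m <- if (is(calls, "DECalls")) callMatrix(calls) else calls
  df <- data.frame(lnc_id = rownames(m), m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a call matrix written by \code{writeCalls}
#'
#' @param path TSV file
#' @return character matrix with lncRNA row names
#' @export
readCalls <- function(path) {
  df <- .readTable(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  if (!all(m %in% c("up", "down", "none")))
    stop("call matrix cells must be 'up', 'down' or 'none'")
  m
}
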