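#' @include evaluate.R
NULL

#' Discretize copy-number log2 ratios
#'
#' Per-cell states: +1 (amplification) when the ratio strictly exceeds
#' \code{ampCut}, -1 (deletion) when strictly below \code{delCut}, 0
#' otherwise. The default cutoffs are the conventional +/-0.1 applied to
#' segmented log2 ratios.
#'
#' @param ratios numeric matrix of log2 copy ratios (lncRNAs x samples)
#' @param ampCut amplification cutoff (strict), default 0.1
#' @param delCut deletion cutoff (strict), default -0.1
#' @return integer matrix of states in \{-1, 0, +1\}
#' @examples
#' discretizeCNA(matrix(c(0.2, -0.2, 0.1), 1))
#' @export
discretizeCNA <- function(ratios, ampCut = 0.1, delCut = -0.1) {
  if (ampCut <= delCut) stop("'ampCut' must exceed 'delCut'")
  if (anyNA(ratios) || any(!is.finite(ratios)))
    stop("log2 ratios must be finite")
  states <- (ratios > ampCut) - (ratios < delCut)
  storage.mode(states) <- "integer"
  states
}

#' Hypergeometric concordance of DE calls with copy-number states
#'
#' For one lncRNA, tests whether the patients in which it is called DE
#' overlap the patients carrying the direction-matched copy-number
#' alteration (up with gain, down with loss) more than chance. The
#' population is the patients shared by the two matrices; the p-value is
#' the upper-tail hypergeometric probability of at least the observed
#' overlap when |DE patients| are drawn from a population containing
#' |altered patients| successes.
#'
#' @param calls a \linkS4class{DECalls} or character call matrix
#' @param cna integer state matrix from \code{\link{discretizeCNA}}
#' @param lnc lncRNA identifier present in both matrices
#' @return list: direction, nShared, nDE, nAltered, overlap, expected
#'   (chance overlap), p; or NULL (with a message) when the lncRNA has
#'   no DE patients or no altered patients among the shared ones
#' @export
concordanceTest <- function(calls, cna, lnc) {
  m <- .callsMatrix(calls)
  if (!(lnc %in% rownames(m)) || !(lnc %in% rownames(cna)))
    stop("lncRNA '", lnc, "' absent from calls or CNA matrix")
  shared <- intersect(colnames(m), colnames(cna))
  if (!length(shared)) stop("no shared patients")
  cc <- m[lnc, shared]
  direction <- unique(cc[cc != "none"])
  if (length(direction) != 1L) {
    message("skipping ", lnc, ": no single-direction DE patients")
    return(NULL)
  }
  wanted <- if (direction == "up") 1L else -1L
  dePatients <- shared[cc == direction]
  altered <- shared[cna[lnc, shared] == wanted]
  if (!length(altered)) {
    message("skipping ", lnc, ": no patients with matched alteration")
    return(NULL)
  }
  overlap <- length(intersect(dePatients, altered))
  nShared <- length(shared)
  p <- stats::phyper(overlap - 1L, length(altered),
                     nShared - length(altered), length(dePatients),
                     lower.tail = FALSE)
  list(direction = direction, nShared = nShared,
       nDE = length(dePatients), nAltered = length(altered),
       overlap = overlap,
       expected = length(dePatients) * length(altered) / nShared,
       p = p)
}

#' Cohort-wide copy-number/expression concordance
#'
#' Runs \code{\link{concordanceTest}} for every lncRNA present in both
#' matrices (optionally restricted to a whitelist, e.g. lncRNAs inside
#' significantly altered regions) and summarises how many are
#' concordant in direction (overlap above chance expectation) and how
#' many are significant at \code{alpha}.
#'
#' @param calls a \linkS4class{DECalls} or character call matrix
#' @param cna integer state matrix from \code{\link{discretizeCNA}}
#' @param alpha significance level, default 0.05
#' @param whitelist optional lncRNA IDs to restrict the scan
#' @return list: \code{perLnc} (data.frame lnc, direction, nDE,
#'   nAltered, overlap, expected, p), \code{nTested},
#'   \code{nConcordant}, \code{nSignificant}, \code{alpha}
#' @export
cohortConcordance <- function(calls, cna, alpha = 0.05, whitelist = NULL) {
  m <- .callsMatrix(calls)
  ids <- intersect(rownames(m), rownames(cna))
  if (!is.null(whitelist)) ids <- intersect(ids, whitelist)
  if (!length(ids) || !length(intersect(colnames(m), colnames(cna))))
    stop("empty shared lncRNA/patient universe")
  rows <- list()
  for (lnc in ids) {
    r <- suppressMessages(concordanceTest(m, cna, lnc))
    if (is.null(r)) next
    rows[[lnc]] <- data.frame(lnc = lnc, direction = r$direction,
                              nDE = r$nDE, nAltered = r$nAltered,
                              overlap = r$overlap, expected = r$expected,
                              p = r$p, stringsAsFactors = FALSE)
  }
  perLnc <- if (length(rows)) do.call(rbind, rows)
  else data.frame(lnc = character(), direction = character(),
                  nDE = integer(), nAltered = integer(),
                  overlap = integer(), expected = numeric(), p = numeric())
  rownames(perLnc) <- NULL
  list(perLnc = perLnc, nTested = nrow(perLnc),
       nConcordant = sum(perLnc$overlap > perLnc$expected),
       nSignificant = sum(perLnc$p < alpha), alpha = alpha)
}
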