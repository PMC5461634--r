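#' @include pairs.R
NULL

#' Population-level dysregulation direction of a target lncRNA
#'
#' The sign of (mean rank in cancer - mean rank in normal), computed on
#' within-sample rank profiles. Exact equality of the two means leaves
#' the direction undefined and the target is excluded from calling.
#'
#' @param target lncRNA identifier
#' @param rankNormal,rankCancer rank matrices (see
#'   \code{\link{rankTransform}}) sharing the lncRNA universe
#' @return \code{"up"}, \code{"down"} or \code{NA} (tie)
#' @export
populationDirection <- function(target, rankNormal, rankCancer) {
  if (!(target %in% rownames(rankNormal)) ||
      !(target %in% rownames(rankCancer)))
    stop("target '", target, "' absent from a rank matrix")
  delta <- mean(rankCancer[target, ]) - mean(rankNormal[target, ])
  if (delta > 0) "up" else if (delta < 0) "down" else NA_character_
}

#' Reversal partners concordant with a target's direction
#'
#' A reversal pair implies its former-low member is up-regulated and its
#' former-high member down-regulated. Only partners whose flip implies the
#' target's own population direction are kept: an up-regulated target
#' keeps pairs in which it is the low member; a down-regulated target
#' keeps pairs in which it is the high member.
#'
#' @param target lncRNA identifier
#' @param direction the target's population direction, "up" or "down"
#' @param reversalPairs a \linkS4class{ReversalPairSet}
#' @return character vector of partner lncRNA IDs (possibly empty)
#' @export
retainConcordantPartners <- function(target, direction, reversalPairs) {
  direction <- match.arg(direction, c("up", "down"))
  rp <- reversalPairs@pairs
  if (direction == "up") rp$high[rp$low == target]
  else rp$low[rp$high == target]
}

#' Coefficient of variation of a partner's rank
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean of
#' the partner's within-sample ranks, pooled across cancer and normal
#' samples. A low CV marks a partner whose rank barely moves, so a flip
#' of the target-partner order can be attributed to the target.
#'
#' @param rankAll rank matrix over all samples (both groups pooled)
#' @param partner lncRNA identifier
#' @return the CV (0 for constant ranks)
#' @export
partnerCV <- function(rankAll, partner) {
  if (!(partner %in% rownames(rankAll)))
    stop("partner '", partner, "' absent from rank matrix")
  r <- rankAll[partner, ]
  if (length(r) < 2L) stop("CV needs at least 2 samples")
  stats::sd(r) / mean(r)
}

#' Select a target's top reversal partners by rank CV
#'
#' Partners are ordered by increasing CV; if more than \code{k} are
#' available the \code{k} smallest-CV partners are retained, otherwise
#' all of them. CV ties are broken lexicographically by partner ID so the
#' selection is deterministic.
#'
#' @param partners character vector of candidate partner IDs
#' @param cv named numeric vector (or vector aligned with
#'   \code{partners}) of their rank CVs
#' @param k maximum number retained, default 3
#' @return partner IDs, CV-ascending, length <= k
#' @export
selectTopPartners <- function(partners, cv, k = 3) {
  if (!length(partners)) return(character())
  if (!is.null(names(cv))) cv <- cv[partners]
  ord <- order(cv, partners)
  partners[ord][seq_len(min(k, length(partners)))]
}

#' Call a single sample for a single target
#'
#' The target is called differentially expressed in the sample iff the
#' reversed orientation holds for strictly more than half of its selected
#' partner pairs: an up-regulated target must lie strictly above a
#' majority of its partners (it sat below them in normals), a
#' down-regulated target strictly below.
#'
#' @param target lncRNA identifier
#' @param direction "up" or "down" (the target's population direction)
#' @param partners selected partner IDs
#' @param sampleValues named numeric vector of one sample's expression
#'   (or rank) values
#' @return TRUE iff the target is DE in this sample
#' @export
callSample <- function(target, direction, partners, sampleValues) {
  direction <- match.arg(direction, c("up", "down"))
  if (!length(partners)) stop("no selected partner pairs")
  flips <- if (direction == "up")
    sampleValues[target] > sampleValues[partners]
  else
    sampleValues[target] < sampleValues[partners]
  sum(flips) > length(partners) / 2
}

#' @describeIn lncrindiv run on explicit normal and cancer matrices
#' @param stabilityFrac stable-pair support threshold (strict), default 0.95
#' @param fdr reversal-pair BH threshold (strict), default 0.1
#' @param k maximum reversal partners per target, default 3
#' @export
setMethod("lncrindiv", signature("matrix", "matrix"),
function(normal, cancer, stabilityFrac = 0.95, fdr = 0.1, k = 3) {
  if (!identical(rownames(normal), rownames(cancer)))
    stop("normal and cancer matrices must share the same lncRNA rows")
  if (ncol(normal) < 2L || ncol(cancer) < 1L)
    stop("need >= 2 normal and >= 1 cancer samples")
  sp <- findStablePairs(normal, stabilityFrac)
  rp <- suppressWarnings(findReversalPairs(sp, cancer, fdr))
  .callFromPairs(rp, normal, cancer,
                 params = list(stabilityFrac = stabilityFrac,
                               fdr = fdr, k = k))
})

#' @describeIn lncrindiv run on an LncExpression holding both groups
#' @export
setMethod("lncrindiv", signature("LncExpression", "missing"),
function(normal, cancer, stabilityFrac = 0.95, fdr = 0.1, k = 3) {
  lncrindiv(normalMatrix(normal), cancerMatrix(normal),
            stabilityFrac = stabilityFrac, fdr = fdr, k = k)
})

## Steps 2-4 given a reversal pair set: per-target direction filter,
## CV-based partner selection, strict-majority per-sample voting.
.callFromPairs <- function(rp, normal, cancer, params) {
  k <- params$k
  ids <- rownames(normal)
  rankN <- rankTransform(normal)
  rankC <- rankTransform(cancer)
  rankAll <- cbind(rankN, rankC)
  cvAll <- apply(rankAll, 1L, stats::sd) / rowMeans(rankAll)
  meanDelta <- rowMeans(rankC) - rowMeans(rankN)

  calls <- matrix("none", nrow(cancer), ncol(cancer),
                  dimnames = dimnames(cancer))
  tg <- list()
  rpdf <- rp@pairs
  for (target in unique(c(rpdf$low, rpdf$high))) {
    delta <- meanDelta[target]
    if (delta == 0) next                       # undefined direction
    direction <- if (delta > 0) "up" else "down"
    partners <- retainConcordantPartners(target, direction, rp)
    if (!length(partners)) next
    sel <- selectTopPartners(partners, cvAll, k)
    np <- length(sel)
    flips <- matrix(FALSE, np, ncol(cancer))
    for (j in seq_len(np)) {
      flips[j, ] <- if (direction == "up")
        cancer[target, ] > cancer[sel[j], ]
      else
        cancer[target, ] < cancer[sel[j], ]
    }
    de <- colSums(flips) > np / 2
    calls[target, de] <- direction
    tg[[target]] <- data.frame(
      lnc = target, direction = direction, nPartners = np,
      partners = paste(sel, collapse = ","),
      partnerCV = paste(sprintf("%.6g", cvAll[sel]), collapse = ","),
      stringsAsFactors = FALSE)
  }
  targets <- if (length(tg))
    S4Vectors::DataFrame(do.call(rbind, tg), row.names = NULL)
  else
    S4Vectors::DataFrame(lnc = character(), direction = character(),
                         nPartners = integer(), partners = character(),
                         partnerCV = character())
  new("DECalls", calls = calls, targets = targets,
      reversalPairs = rp, params = params)
}
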