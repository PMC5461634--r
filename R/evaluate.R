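#' @include simulate.R
NULL

#' Score individual-level calls against spike-in truth
#'
#' Evaluation is at the (lncRNA, sample)-event level. Sensitivity is the
#' fraction of truth events called DE with the correct direction; a call
#' in the wrong direction does not count as an identification.
#' Specificity is the fraction of non-events (cells of the evaluated
#' universe carrying no spike) left uncalled. The F-score is the harmonic
#' mean 2 (sens x spec) / (sens + spec).
#'
#' The evaluated universe defaults to the spiked lncRNAs crossed with all
#' disease samples: those are the rows with a defined truth status for
#' every cell (a bystander lncRNA crossed by a spiked one has no defined
#' status). Pass \code{universe = rownames(callMatrix(calls))} to score
#' the full matrix instead.
#'
#' @param calls a \linkS4class{DECalls} or a character call matrix
#' @param truth data.frame of spiked events with columns \code{lnc},
#'   \code{sample}, \code{direction}
#' @param universe lncRNA IDs delimiting the evaluated rows; default the
#'   lncRNAs appearing in \code{truth}
#' @return list with \code{sensitivity}, \code{specificity},
#'   \code{fscore} and the event counts (\code{tp}, \code{events},
#'   \code{tn}, \code{nonEvents}). With empty truth, sensitivity and
#'   F-score are NA.
#' @export
scorePerformance <- function(calls, truth, universe = NULL) {
  m <- if (is(calls, "DECalls")) callMatrix(calls) else calls
  if (is.null(universe)) universe <- unique(truth$lnc)
  universe <- intersect(universe, rownames(m))
  if (!length(universe)) stop("empty evaluated universe")
  sub <- m[universe, , drop = FALSE]
  tmat <- matrix("none", nrow(sub), ncol(sub), dimnames = dimnames(sub))
  if (nrow(truth)) {
    keep <- truth$lnc %in% rownames(sub) & truth$sample %in% colnames(sub)
    tk <- truth[keep, , drop = FALSE]
    tmat[cbind(match(tk$lnc, rownames(sub)),
               match(tk$sample, colnames(sub)))] <- tk$direction
  }
  isEvent <- tmat != "none"
  events <- sum(isEvent)
  tp <- sum(isEvent & sub == tmat)
  nonEvents <- sum(!isEvent)
  tn <- sum(!isEvent & sub == "none")
  sens <- if (events > 0) tp / events else NA_real_
  spec <- if (nonEvents > 0) tn / nonEvents else NA_real_
  f <- fScore(sens, spec)
  list(sensitivity = sens, specificity = spec, fscore = f,
       tp = tp, events = events, tn = tn, nonEvents = nonEvents)
}

#' Harmonic mean of sensitivity and specificity
#'
#' @param sensitivity,specificity values in [0, 1]
#' @return 2 (sens x spec) / (sens + spec); NA if either input is NA,
#'   0 if both are 0
#' @examples
#' fScore(0.9694, 0.9995)   # 0.9842
#' @export
fScore <- function(sensitivity, specificity) {
  if (anyNA(c(sensitivity, specificity))) return(NA_real_)
  s <- sensitivity + specificity
  ifelse(s > 0, 2 * sensitivity * specificity / s, 0)
}

#' Per-sample consistency of calls with paired rank changes
#'
#' For sample-paired cancer/normal profiles, the benchmark direction of a
#' lncRNA in a cancer sample is the sign of (rank in the cancer sample -
#' rank in the matched normal sample): larger rank means up-regulated.
#' The consistency score of a sample is the fraction of its DE calls
#' whose direction matches that benchmark (a zero rank change matches
#' neither). Samples with no calls get NA and are excluded from the
#' reported mean.
#'
#' @param calls a \linkS4class{DECalls} or character call matrix whose
#'   columns are the cancer samples, pairing with the normal columns
#'   by position
#' @param rankCancer,rankNormal rank matrices of the paired cancer and
#'   normal profiles (same column order as the pairing)
#' @return list: \code{perSample} (named numeric vector, NA where no
#'   calls) and \code{mean} (over samples with calls)
#' @export
consistencyScore <- function(calls, rankCancer, rankNormal) {
  m <- if (is(calls, "DECalls")) callMatrix(calls) else calls
  if (!identical(dim(rankCancer), dim(rankNormal)))
    stop("paired rank matrices must have identical shape")
  if (ncol(m) != ncol(rankCancer))
    stop("calls and paired matrices must cover the same samples")
  ids <- intersect(rownames(m), rownames(rankCancer))
  scores <- vapply(seq_len(ncol(m)), function(s) {
    called <- ids[m[ids, s] != "none"]
    if (!length(called)) return(NA_real_)
    delta <- rankCancer[called, s] - rankNormal[called, s]
    bench <- ifelse(delta > 0, "up", ifelse(delta < 0, "down", "tie"))
    mean(bench == m[called, s])
  }, numeric(1L))
  names(scores) <- colnames(m)
  list(perSample = scores, mean = mean(scores, na.rm = TRUE))
}
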