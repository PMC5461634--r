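#' @include evaluate.R
#' @importFrom survival Surv coxph survdiff concordance
NULL

.callsMatrix <- function(calls) {
  if (is(calls, "DECalls")) callMatrix(calls) else calls
}

.alignSurvival <- function(m, survival) {
  if (!all(c("sample", "time", "event") %in% colnames(survival)))
    stop("survival table needs columns sample, time, event")
  shared <- intersect(colnames(m), survival$sample)
  if (length(shared) < 4L)
    stop("too few samples shared between calls and survival table")
  sv <- survival[match(shared, survival$sample), , drop = FALSE]
  if (any(sv$time < 0, na.rm = TRUE)) stop("negative survival times")
  list(m = m[, shared, drop = FALSE], sv = sv)
}

#' Harrell's concordance index
#'
#' Over usable sample pairs - the member with the earlier observed time
#' had an event and the two times differ - a pair scores 1 when the
#' earlier-failing member carries the higher risk score, 0.5 on a risk
#' tie, 0 otherwise; C is the mean. 0.5 means no predictive ability, 1
#' perfect ability. Binary group membership is an admissible risk score.
#'
#' @param risk numeric risk score per sample (higher = riskier)
#' @param time observed time per sample
#' @param event 1 = event observed, 0 = censored
#' @return the C-index, or NA (with a warning) when no pair is usable
#' @export
harrellCIndex <- function(risk, time, event) {
  n <- length(risk)
  if (length(time) != n || length(event) != n)
    stop("risk, time and event must have equal length")
  ## usable[i, j]: time_i < time_j and subject i had an event
  usable <- outer(time, time, "<") & (event == 1)
  if (!any(usable)) {
    warning("no usable pairs; C-index undefined")
    return(NA_real_)
  }
  gt <- outer(risk, risk, ">")
  eq <- outer(risk, risk, "==")
  (sum(gt & usable) + 0.5 * sum(eq & usable)) / sum(usable)
}

#' Screen DE lncRNAs for association with overall survival
#'
#' For each lncRNA with DE calls, samples are split into with-DE and
#' without-DE groups; candidates must have log-rank p < 0.05 and
#' univariate Cox proportional-hazards p < 0.05 (uncorrected, as a
#' screening family). The risk direction is the lncRNA's DE direction
#' when the DE group carries HR > 1; lncRNAs whose DE group is
#' protective (HR < 1) cannot be expressed by the union risk rule and
#' are reported with \code{admissible = FALSE}. Splits with fewer than
#' \code{minGroup} samples on either side, or without events, are
#' skipped.
#'
#' @param calls a \linkS4class{DECalls} or character call matrix
#' @param survival data.frame with columns \code{sample}, \code{time},
#'   \code{event}
#' @param alpha screening threshold for both tests, default 0.05
#' @param minGroup minimum samples per split side, default 3
#' @return data.frame of admitted candidates, ordered by decreasing
#'   C-index: lnc, riskDirection, cIndex, logrankP, coxP, hr, hrLo, hrHi,
#'   nDE
#' @export
screenCandidates <- function(calls, survival, alpha = 0.05, minGroup = 3) {
  al <- .alignSurvival(.callsMatrix(calls), survival)
  m <- al$m; sv <- al$sv
  out <- list()
  for (lnc in rownames(m)) {
    deCall <- m[lnc, ]
    de <- deCall != "none"
    nDe <- sum(de)
    if (nDe < minGroup || sum(!de) < minGroup) next
    if (sum(sv$event) < 1L) next
    direction <- unique(deCall[de])
    if (length(direction) != 1L) next    # mixed-direction split untestable
    lr <- tryCatch(
      survival::survdiff(survival::Surv(sv$time, sv$event) ~ de),
      error = function(e) NULL)
    cx <- tryCatch(
      summary(survival::coxph(survival::Surv(sv$time, sv$event) ~ de)),
      error = function(e) NULL)
    if (is.null(lr) || is.null(cx)) next
    logrankP <- stats::pchisq(lr$chisq, df = 1L, lower.tail = FALSE)
    coxP <- cx$coefficients[1L, "Pr(>|z|)"]
    hr <- cx$conf.int[1L, "exp(coef)"]
    if (!(logrankP < alpha && coxP < alpha)) next
    cIdx <- harrellCIndex(as.numeric(de), sv$time, sv$event)
    out[[lnc]] <- data.frame(
      lnc = lnc, riskDirection = direction, cIndex = cIdx,
      logrankP = logrankP, coxP = coxP, hr = hr,
      hrLo = cx$conf.int[1L, "lower .95"],
      hrHi = cx$conf.int[1L, "upper .95"],
      nDE = nDe, admissible = hr > 1,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    warning("no admissible candidates")
    return(data.frame(lnc = character(), riskDirection = character(),
                      cIndex = numeric(), logrankP = numeric(),
                      coxP = numeric(), hr = numeric(), hrLo = numeric(),
                      hrHi = numeric(), nDE = integer(),
                      admissible = logical()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(-res$cIndex, res$lnc), ]
}

## Union risk rule: a sample is high-risk iff any member is called DE in
## its risk direction.
.unionRisk <- function(m, members) {
  hit <- matrix(FALSE, nrow(members), ncol(m))
  for (i in seq_len(nrow(members)))
    hit[i, ] <- m[members$lnc[i], ] == members$riskDirection[i]
  as.numeric(colSums(hit) > 0)
}

#' Forward selection of a prognostic signature by C-index
#'
#' Candidates are ranked by decreasing C-index (ties broken by ID); the
#' maximal-C candidate seeds the signature, then each further candidate
#' is added in turn and kept only when the combined C-index strictly
#' increases. The combined risk score of a member set is the union rule:
#' a sample is high-risk iff any member is called DE in its risk
#' direction.
#'
#' @param candidates data.frame from \code{\link{screenCandidates}}
#'   (rows with \code{admissible = FALSE} are ignored)
#' @param calls a \linkS4class{DECalls} or character call matrix
#' @param survival data.frame with sample, time, event
#' @return a \linkS4class{LncSignature}
#' @export
forwardSelect <- function(candidates, calls, survival) {
  cand <- candidates[candidates$admissible, , drop = FALSE]
  if (nrow(cand) < 1L) stop("no admissible candidates to select from")
  cand <- cand[order(-cand$cIndex, cand$lnc), , drop = FALSE]
  al <- .alignSurvival(.callsMatrix(calls), survival)
  m <- al$m; sv <- al$sv
  members <- cand[1L, , drop = FALSE]
  cIdx <- harrellCIndex(.unionRisk(m, members), sv$time, sv$event)
  path <- data.frame(step = 1L, lnc = members$lnc, action = "seed",
                     cIndex = cIdx, stringsAsFactors = FALSE)
  if (nrow(cand) > 1L) {
    for (i in 2:nrow(cand)) {
      trial <- rbind(members, cand[i, ])
      cTrial <- harrellCIndex(.unionRisk(m, trial), sv$time, sv$event)
      keep <- !is.na(cTrial) && cTrial > cIdx
      if (keep) { members <- trial; cIdx <- cTrial }
      path <- rbind(path, data.frame(
        step = i, lnc = cand$lnc[i],
        action = if (keep) "kept" else "discarded",
        cIndex = cTrial, stringsAsFactors = FALSE))
    }
  }
  new("LncSignature",
      members = S4Vectors::DataFrame(
        members[, c("lnc", "riskDirection", "cIndex", "logrankP",
                    "coxP", "hr")], row.names = NULL),
      cIndex = cIdx,
      path = S4Vectors::DataFrame(path, row.names = NULL))
}

#' Assign high/low risk groups by the union rule
#'
#' High risk iff at least one signature member is called DE in its risk
#' direction; all remaining samples are low risk.
#'
#' @param calls a \linkS4class{DECalls} or character call matrix
#' @param signature a \linkS4class{LncSignature}
#' @return named character vector ("high"/"low") per sample
#' @export
assignRiskGroups <- function(calls, signature) {
  m <- .callsMatrix(calls)
  members <- as.data.frame(signature@members)
  miss <- setdiff(members$lnc, rownames(m))
  if (length(miss))
    stop("signature member(s) absent from call matrix: ",
         paste(miss, collapse = ", "))
  risk <- .unionRisk(m, members)
  stats::setNames(ifelse(risk > 0, "high", "low"), colnames(m))
}

#' Survival association of risk groups
#'
#' Log-rank test plus univariable and (when covariates are given)
#' multivariable Cox proportional-hazards fits of the high- vs low-risk
#' grouping. A degenerate covariate fails only its own term.
#'
#' @param groups character vector ("high"/"low") per sample, named
#' @param time,event survival outcome aligned with \code{groups}
#' @param covariates optional data.frame of named covariate columns
#' @return list: \code{logrankP}, \code{univariate} (data.frame term,
#'   HR, lo, hi, p), \code{multivariable} (same shape; NULL without
#'   covariates)
#' @export
survivalAssociation <- function(groups, time, event, covariates = NULL) {
  g <- factor(groups, levels = c("low", "high"))
  ss <- survival::Surv(time, event)
  lr <- survival::survdiff(ss ~ g)
  logrankP <- stats::pchisq(lr$chisq, df = 1L, lower.tail = FALSE)
  term_table <- function(fit) {
    s <- summary(fit)
    data.frame(term = rownames(s$conf.int),
               HR = s$conf.int[, "exp(coef)"],
               lo = s$conf.int[, "lower .95"],
               hi = s$conf.int[, "upper .95"],
               p = s$coefficients[, "Pr(>|z|)"],
               row.names = NULL, stringsAsFactors = FALSE)
  }
  uni <- term_table(survival::coxph(ss ~ g))
  multi <- NULL
  if (!is.null(covariates) && ncol(covariates)) {
    df <- data.frame(g = g, covariates)
    multi <- tryCatch(
      term_table(survival::coxph(ss ~ ., data = df)),
      error = function(e) {
        warning("multivariable fit failed: ", conditionMessage(e))
        NULL
      })
  }
  list(logrankP = logrankP, univariate = uni, multivariable = multi)
}

#' Export threshold-free pairwise decision rules for a signature
#'
#' Each signature member contributes its selected reversal partners as
#' pairwise expression comparisons: a member whose risk direction is
#' \code{down} flags a patient when its expression is \emph{lower} than a
#' strict majority of its partners; an \code{up} member when it is
#' \emph{higher}. The rules classify a single sample with no thresholds
#' or normalisation.
#'
#' @param signature a \linkS4class{LncSignature}
#' @param calls the \linkS4class{DECalls} the signature was built from
#'   (source of the selected partners)
#' @return data.frame with one row per (member, partner) comparison:
#'   member, direction, partner, relation ("higher"/"lower"),
#'   nPartners, majority (votes required)
#' @export
exportRules <- function(signature, calls) {
  if (!is(calls, "DECalls"))
    stop("'calls' must be the DECalls object the signature was built from")
  audit <- targetAudit(calls)
  members <- as.data.frame(signature@members)
  rows <- list()
  for (i in seq_len(nrow(members))) {
    lnc <- members$lnc[i]
    j <- match(lnc, audit$lnc)
    if (is.na(j))
      stop("signature member '", lnc, "' has no selected partners")
    partners <- strsplit(audit$partners[j], ",", fixed = TRUE)[[1L]]
    np <- length(partners)
    rows[[i]] <- data.frame(
      member = lnc, direction = members$riskDirection[i],
      partner = partners,
      relation = if (members$riskDirection[i] == "up") "higher" else "lower",
      nPartners = np, majority = floor(np / 2) + 1L,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Apply exported rules to raw expression values
#'
#' Classifies samples into high/low risk straight from an expression
#' matrix using the pairwise comparisons of \code{\link{exportRules}}:
#' a member fires in a sample when its relation to at least
#' \code{majority} of its partners holds; a sample is high-risk iff any
#' member fires. Reproduces \code{\link{assignRiskGroups}} on the
#' training data exactly.
#'
#' @param rules data.frame from \code{\link{exportRules}}
#' @param values numeric expression matrix (lncRNAs x samples) covering
#'   all members and partners
#' @return named character vector ("high"/"low") per sample
#' @export
applyRules <- function(rules, values) {
  need <- unique(c(rules$member, rules$partner))
  miss <- setdiff(need, rownames(values))
  if (length(miss))
    stop("lncRNA(s) absent from expression matrix: ",
         paste(miss, collapse = ", "))
  fired <- matrix(FALSE, 0L, ncol(values))
  for (lnc in unique(rules$member)) {
    rr <- rules[rules$member == lnc, , drop = FALSE]
    cmp <- sapply(seq_len(nrow(rr)), function(i) {
      if (rr$relation[i] == "higher")
        values[lnc, ] > values[rr$partner[i], ]
      else
        values[lnc, ] < values[rr$partner[i], ]
    })
    if (is.null(dim(cmp))) cmp <- matrix(cmp, nrow = 1L)
    else cmp <- t(cmp)
    fired <- rbind(fired, colSums(cmp) >= rr$majority[1L])
  }
  stats::setNames(ifelse(colSums(fired) > 0, "high", "low"),
                  colnames(values))
}
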