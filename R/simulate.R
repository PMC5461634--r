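#' @include indiv.R
NULL

#' Generate a synthetic normal-tissue lncRNA expression matrix
#'
#' Emulates the features of real normal-tissue lncRNA profiles that the
#' rank machinery is sensitive to: a right-skewed abundance distribution
#' (most lncRNAs crowded near the expression floor, a long tail of highly
#' expressed ones; truncated-exponential baselines on the log2 scale) and
#' heteroscedastic between-sample variability (a quiet, tightly
#' rank-stable subpopulation and a noisy one, each with lognormal spread
#' of per-lncRNA SDs). With the defaults and ~200 normal samples roughly
#' 25-30\% of all lncRNA pairs are stable at the 95\% criterion, the
#' density observed in real cohorts.
#'
#' @param nLnc number of lncRNAs (>= 2)
#' @param nSamples number of samples (>= 2)
#' @param baselineLow,baselineHigh log2 dynamic range of baselines,
#'   default [4, 12]
#' @param baselineScale scale (log2 units) of the truncated-exponential
#'   baseline distribution; smaller = more crowding at the floor
#' @param noiseSd median per-lncRNA SD of the quiet subpopulation
#' @param noisySd median per-lncRNA SD of the noisy subpopulation
#' @param quietFrac fraction of lncRNAs in the quiet subpopulation
#' @param noiseSdLog lognormal spread (sdlog) of per-lncRNA SDs
#' @param seed integer seed; fixed seed gives an identical matrix
#' @return an \linkS4class{LncExpression} with all samples labelled
#'   \code{"normal"}
#' @export
synthNormalMatrix <- function(nLnc, nSamples,
                              baselineLow = 4, baselineHigh = 12,
                              baselineScale = 0.9,
                              noiseSd = 0.125, noisySd = 1.8,
                              quietFrac = 0.6, noiseSdLog = 0.4,
                              seed = 1) {
  if (nLnc < 2L || nSamples < 2L)
    stop("need at least 2 lncRNAs and 2 samples")
  if (baselineHigh <= baselineLow)
    stop("'baselineHigh' must exceed 'baselineLow'")
  if (noiseSd < 0 || noisySd < 0 || baselineScale <= 0)
    stop("scales and SDs must be nonnegative")
  if (quietFrac < 0 || quietFrac > 1)
    stop("'quietFrac' must lie in [0, 1]")
  set.seed(seed)
  span <- baselineHigh - baselineLow
  base <- baselineLow +
    stats::qexp(stats::runif(nLnc) * stats::pexp(span, 1 / baselineScale),
                1 / baselineScale)
  quiet <- stats::runif(nLnc) < quietFrac
  sds <- ifelse(quiet, noiseSd, noisySd) *
    exp(stats::rnorm(nLnc, 0, noiseSdLog))
  m <- base + sweep(matrix(stats::rnorm(nLnc * nSamples), nLnc, nSamples),
                    1L, sds, "*")
  dimnames(m) <- list(sprintf("lnc%04d", seq_len(nLnc)),
                      sprintf("N%04d", seq_len(nSamples)))
  LncExpression(m, rep("normal", nSamples))
}

#' Spike differential expression into a paired disease cohort
#'
#' The disease matrix starts as a sample-paired copy of the normal
#' matrix. \code{nUp} up- and \code{nDown} down-regulated lncRNAs are
#' drawn from the callable pool (by default: lncRNAs in the lower
#' \code{eligibleRankSdQuantile} of per-lncRNA rank SD across normals
#' that possess at least \code{minStablePartners} stable pairs in the
#' concordant orientation - partners above for an up-spike, below for a
#' down-spike - mirroring the fact that spike-in panels are drawn from
#' lncRNAs identified as dysregulated, not from all lncRNAs). Each spiked
#' lncRNA receives \code{+/- log2fc} in a random sample subset whose size
#' is a binomial draw with expectation \code{meanDeSamples} (minimum 1).
#'
#' @param normal an \linkS4class{LncExpression} of normal samples (or a
#'   numeric matrix)
#' @param nUp,nDown numbers of up-/down-regulated spike-ins (default 50/50)
#' @param log2fc spike magnitude in log2 units (nonzero)
#' @param meanDeSamples expected number of DE samples per spiked lncRNA
#' @param seed integer seed
#' @param eligible optional character vector overriding the callable pool
#' @param eligibleRankSdQuantile rank-SD quantile bounding the pool
#' @param minStablePartners required concordant-orientation stable pairs
#' @param stabilityFrac stability threshold used for the eligibility scan
#' @return list with \code{disease} (an \linkS4class{LncExpression} of
#'   cancer samples, sample-paired with \code{normal}) and \code{truth}
#'   (data.frame of spiked events: \code{lnc}, \code{sample},
#'   \code{direction}, \code{log2fc})
#' @export
spikeInDE <- function(normal, nUp = 50, nDown = 50, log2fc,
                      meanDeSamples = 10, seed = 1,
                      eligible = NULL,
                      eligibleRankSdQuantile = 0.5,
                      minStablePartners = 3,
                      stabilityFrac = 0.95) {
  m <- if (is(normal, "LncExpression")) normalMatrix(normal)
       else as.matrix(normal)
  if (log2fc == 0) stop("'log2fc' must be nonzero")
  if (nUp + nDown > nrow(m))
    stop("more spike-ins requested than lncRNAs available")
  if (meanDeSamples > ncol(m))
    stop("'meanDeSamples' cannot exceed the sample count")
  set.seed(seed)
  ids <- rownames(m)
  if (nUp + nDown > 0L) {
    if (is.null(eligible)) {
      sp <- pairTable(findStablePairs(m, stabilityFrac))
      nAbove <- table(factor(sp$low, levels = ids))   # partners above
      nBelow <- table(factor(sp$high, levels = ids))  # partners below
      rsd <- apply(rankTransform(m), 1L, stats::sd)
      stable <- rsd <= stats::quantile(rsd, eligibleRankSdQuantile)
      eligUp <- ids[stable & nAbove >= minStablePartners]
      eligDown <- ids[stable & nBelow >= minStablePartners]
    } else {
      eligUp <- eligDown <- intersect(eligible, ids)
    }
    if (length(eligUp) < nUp)
      stop("only ", length(eligUp), " lncRNAs eligible for up-spikes")
    upT <- sample(eligUp, nUp)
    eligDown <- setdiff(eligDown, upT)
    if (length(eligDown) < nDown)
      stop("only ", length(eligDown), " lncRNAs eligible for down-spikes")
    downT <- sample(eligDown, nDown)
  } else {
    upT <- downT <- character()
  }
  spiked <- c(upT, downT)
  dirs <- rep(c("up", "down"), c(nUp, nDown))
  disease <- m
  colnames(disease) <- sub("^N", "C", colnames(m))
  truth <- vector("list", length(spiked))
  for (i in seq_along(spiked)) {
    nDe <- max(1L, stats::rbinom(1L, ncol(m), meanDeSamples / ncol(m)))
    ss <- sample(ncol(m), nDe)
    shift <- if (dirs[i] == "up") abs(log2fc) else -abs(log2fc)
    disease[spiked[i], ss] <- disease[spiked[i], ss] + shift
    truth[[i]] <- data.frame(lnc = spiked[i],
                             sample = colnames(disease)[ss],
                             direction = dirs[i],
                             log2fc = shift,
                             stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth)
  else data.frame(lnc = character(), sample = character(),
                  direction = character(), log2fc = numeric())
  list(disease = LncExpression(disease, rep("cancer", ncol(disease))),
       truth = truth)
}

#' Simulate a survival cohort driven by one informative lncRNA
#'
#' Builds a per-sample DE call matrix for \code{1 + nNull} lncRNAs in
#' which exactly one lncRNA's DE status multiplies the exponential hazard
#' by \code{hr}; the null lncRNAs' DE statuses are independent of
#' survival. Censoring is administrative at \code{followUp} plus uniform
#' random early dropout.
#'
#' @param nSamples cohort size, default 300
#' @param nNull number of uninformative lncRNAs, default 19
#' @param hr hazard ratio carried by the informative lncRNA, default 3
#' @param prevalence per-lncRNA probability a sample is DE, default 0.3
#' @param baseHazard exponential baseline hazard (events per unit time)
#' @param followUp administrative censoring horizon (time units)
#' @param seed integer seed
#' @return list: \code{calls} (character matrix lnc x sample),
#'   \code{survival} (data.frame sample, time, event),
#'   \code{informative} (the informative lncRNA's ID, always
#'   \code{"lncS0001"} with risk direction \code{"up"})
#' @export
synthSurvivalCohort <- function(nSamples = 300, nNull = 19, hr = 3,
                                prevalence = 0.3, baseHazard = 0.03,
                                followUp = 60, seed = 1) {
  set.seed(seed)
  nLnc <- nNull + 1L
  ids <- sprintf("lncS%04d", seq_len(nLnc))
  samples <- sprintf("P%04d", seq_len(nSamples))
  de <- matrix(stats::runif(nLnc * nSamples) < prevalence, nLnc, nSamples,
               dimnames = list(ids, samples))
  dirs <- rep(c("up", "down"), length.out = nLnc)
  calls <- matrix("none", nLnc, nSamples, dimnames = list(ids, samples))
  for (i in seq_len(nLnc)) calls[i, de[i, ]] <- dirs[i]
  hazard <- baseHazard * ifelse(de[1L, ], hr, 1)
  tEvent <- stats::rexp(nSamples, hazard)
  tCens <- pmin(followUp, stats::runif(nSamples, 0, 3 * followUp))
  time <- pmin(tEvent, tCens)
  event <- as.integer(tEvent <= tCens)
  list(calls = calls,
       survival = data.frame(sample = samples, time = time, event = event,
                             stringsAsFactors = FALSE),
       informative = ids[1L])
}

#' Run the simulation benchmark grid
#'
#' For each scenario (normal/disease cohort sizes) and each log2
#' fold-change magnitude: generate a synthetic normal cohort, spike DE
#' into a paired disease cohort, run the full calling pipeline and score
#' it against the spike-in truth. Cohorts smaller than the generated pool
#' are taken as random sample subsets (normals and disease drawn
#' independently), the pool being \code{nPool} samples.
#'
#' @param log2fc vector of spike magnitudes, default c(1, 1.5, 2)
#' @param scenarios list of c(normal, disease) cohort sizes, default
#'   210 vs 210 and 60 vs 60
#' @param seeds integer vector of replicate seeds, default 1:10
#' @param nLnc lncRNA panel size, default 300
#' @param nPool generated sample pool per seed, default 210
#' @param nUp,nDown spike-in counts, default 50 each
#' @param meanDeSamples expected DE samples per spiked lncRNA (scaled
#'   down proportionally for subsampled scenarios), default 10
#' @param ... generator overrides passed to \code{synthNormalMatrix}
#' @return data.frame with one row per scenario x log2fc x seed plus the
#'   per-cell means: sensitivity, specificity, fscore
#' @export
runSimulationProtocol <- function(log2fc = c(1, 1.5, 2),
                                  scenarios = list(c(210, 210), c(60, 60)),
                                  seeds = 1:10, nLnc = 300, nPool = 210,
                                  nUp = 50, nDown = 50,
                                  meanDeSamples = 10, ...) {
  rows <- list()
  for (seed in seeds) {
    pool <- synthNormalMatrix(nLnc, nPool, seed = seed, ...)
    poolM <- normalMatrix(pool)
    for (fc in log2fc) {
      sp <- spikeInDE(pool, nUp = nUp, nDown = nDown, log2fc = fc,
                      meanDeSamples = meanDeSamples, seed = seed + 1000L)
      disM <- cancerMatrix(sp$disease)
      for (sc in scenarios) {
        nN <- sc[1L]; nC <- sc[2L]
        if (nN > nPool || nC > nPool)
          stop("scenario larger than the generated pool")
        set.seed(seed + 2000L)
        normM <- poolM[, sample(nPool, nN), drop = FALSE]
        canM <- disM[, sample(nPool, nC), drop = FALSE]
        truth <- sp$truth[sp$truth$sample %in% colnames(canM), ]
        calls <- lncrindiv(normM, canM)
        perf <- scorePerformance(calls, truth)
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = paste0(nN, "v", nC), log2fc = fc, seed = seed,
          nStablePairs = calls@reversalPairs@nTested,
          sensitivity = perf$sensitivity,
          specificity = perf$specificity,
          fscore = perf$fscore)
      }
    }
  }
  do.call(rbind, rows)
}
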