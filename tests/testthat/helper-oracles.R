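# Brute-force reference implementations used as independent oracles.
# These deliberately favour clarity over speed and share no code with
# the package internals.

# all ordered stable pairs by explicit double loop over pairs and samples
bruteStablePairs <- function(m, frac = 0.95) {
  ids <- rownames(m)
  out <- list()
  for (i in seq_len(nrow(m))) for (j in seq_len(nrow(m))) {
    if (i == j) next
    a <- 0L; b <- 0L
    for (s in seq_len(ncol(m))) {
      if (m[i, s] < m[j, s]) a <- a + 1L
      else if (m[i, s] > m[j, s]) b <- b + 1L
    }
    if (a + b > 0 && a / (a + b) > frac)
      out[[length(out) + 1L]] <- data.frame(low = ids[i], high = ids[j],
                                            a = a, b = b)
  }
  if (!length(out)) return(data.frame(low = character(), high = character(),
                                      a = integer(), b = integer()))
  df <- do.call(rbind, out)
  df[order(df$low, df$high), , drop = FALSE]
}

# one-sided reversal p by summing the probabilities of all same-margin
# tables at least as extreme in d
enumFisherReversal <- function(a, b, c, d) {
  mrev <- b + d        # total reversed-orientation samples
  mfwd <- a + c
  k <- c + d           # cancer draws
  xs <- max(0L, k - mfwd):min(mrev, k)
  num <- vapply(xs, function(x) choose(mrev, x) * choose(mfwd, k - x),
                numeric(1))
  sum(num[xs >= d]) / sum(num)
}

# upper-tail hypergeometric overlap p by enumeration
enumHyperOverlap <- function(overlap, nAltered, nShared, nDE) {
  xs <- max(0L, nDE - (nShared - nAltered)):min(nAltered, nDE)
  num <- vapply(xs, function(x)
    choose(nAltered, x) * choose(nShared - nAltered, nDE - x), numeric(1))
  sum(num[xs >= overlap]) / sum(num)
}

# naive BH step-up
naiveBH <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (r in n:1) {
    prev <- min(prev, p[o[r]] * n / r)
    q[o[r]] <- prev
  }
  q
}

# Harrell C by explicit pair enumeration
bruteCIndex <- function(risk, time, event) {
  num <- 0; den <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  num / den
}

# event-by-event performance tallies
brutePerformance <- function(callM, truth, universe) {
  tp <- ev <- tn <- ne <- 0L
  for (lnc in universe) for (s in colnames(callM)) {
    hit <- truth$lnc == lnc & truth$sample == s
    if (any(hit)) {
      ev <- ev + 1L
      if (callM[lnc, s] == truth$direction[hit]) tp <- tp + 1L
    } else {
      ne <- ne + 1L
      if (callM[lnc, s] == "none") tn <- tn + 1L
    }
  }
  list(sensitivity = tp / ev, specificity = tn / ne)
}

# small paired synthetic dataset used by several tests
makeSpikedData <- function(seed = 1, nLnc = 120, nSamples = 80,
                           log2fc = 2, nUp = 8, nDown = 8,
                           meanDeSamples = 8, ...) {
  nm <- synthNormalMatrix(nLnc, nSamples, seed = seed, ...)
  sp <- spikeInDE(nm, nUp = nUp, nDown = nDown, log2fc = log2fc,
                  meanDeSamples = meanDeSamples, seed = seed + 500)
  list(normal = normalMatrix(nm), cancer = cancerMatrix(sp$disease),
       truth = sp$truth)
}
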