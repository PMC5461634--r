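test_that("rank transform ranks within sample with average ties", {
  m <- cbind(s1 = c(2, 5, 3), s2 = c(1, 1, 2))
  rownames(m) <- c("a", "b", "c")
  r <- rankTransform(m)
  expect_equal(unname(r[, "s1"]), c(1, 3, 2))
  expect_equal(unname(r[, "s2"]), c(1.5, 1.5, 3))
  expect_equal(colSums(r), c(s1 = 6, s2 = 6))   # G(G+1)/2 per sample
})

test_that("rank transform is invariant to strictly increasing transforms", {
  set.seed(7)
  for (i in 1:5) {
    m <- matrix(rnorm(60, 8), 10, 6,
                dimnames = list(paste0("l", 1:10), paste0("s", 1:6)))
    expect_equal(rankTransform(2^m + 1), rankTransform(m))
    # sort-based oracle: rank = position in the sorted sample
    oracle <- apply(m, 2, function(v) match(seq_along(v), order(v)))
    dimnames(oracle) <- dimnames(m)
    expect_equal(rankTransform(m), oracle)
  }
})

test_that("stability threshold is strict: 95/100 support is not stable", {
  low <- c(rep(1, 95), rep(3, 5))
  high <- rep(2, 100)
  m95 <- rbind(a = low, b = high)
  colnames(m95) <- paste0("n", 1:100)
  expect_identical(length(findStablePairs(m95)), 0L)
  m96 <- m95; m96["a", 96] <- 1   # 96/100 support
  expect_identical(nrow(pairTable(findStablePairs(m96))), 1L)
  expect_identical(pairTable(findStablePairs(m96))$a, 96L)
  expect_error(findStablePairs(m95, stabilityFrac = 0.4), "0.5")
  expect_error(findStablePairs(m95[, 1, drop = FALSE]), "2 normal")
})

test_that("stable pair detection equals an exhaustive double loop", {
  set.seed(11)
  m <- matrix(rnorm(12 * 30, 8, 2), 12, 30,
              dimnames = list(paste0("l", 1:12), paste0("n", 1:30)))
  m <- m + runif(12)            # spread baselines a little
  got <- pairTable(findStablePairs(m, 0.8))
  got <- got[order(got$low, got$high), ]
  rownames(got) <- NULL
  want <- bruteStablePairs(m, 0.8)
  rownames(want) <- NULL
  expect_identical(got[, c("low", "high")], want[, c("low", "high")])
  expect_identical(got$a, want$a)
  expect_identical(got$b, want$b)
})

test_that("exact ties contribute to neither orientation of a pair", {
  m <- rbind(a = c(1, 1, 1, 1, 2), b = c(2, 2, 2, 1, 1))
  colnames(m) <- paste0("n", 1:5)
  tab <- pairTable(findStablePairs(m, 0.7))
  expect_identical(tab$low, "a")
  expect_identical(tab$a, 3L)        # one tied sample dropped
  expect_identical(tab$nUsed, 4L)
})

test_that("binomial stability p-value is the exact upper tail", {
  expect_equal(binomialStabilityPvalue(10, 10), 2^-10)
  expect_equal(binomialStabilityPvalue(0, 10), 1)
  # brute-force tail summation oracle
  for (k in c(3, 7, 9)) {
    oracle <- sum(choose(10, k:10)) / 2^10
    expect_equal(binomialStabilityPvalue(k, 10), oracle)
  }
  expect_error(binomialStabilityPvalue(11, 10), "kMin")
})

test_that("reversal p-value matches enumeration and fisher.test", {
  expect_equal(fisherReversalPvalue(10, 0, 0, 10), 1 / choose(20, 10))
  expect_equal(fisherReversalPvalue(10, 0, 10, 0), 1)
  set.seed(3)
  for (i in 1:20) {
    tb <- rmultinom(1, 25, c(0.45, 0.05, 0.3, 0.2))
    a <- tb[1]; b <- tb[2]; cc <- tb[3]; d <- tb[4]
    p <- fisherReversalPvalue(a, b, cc, d)
    expect_equal(p, enumFisherReversal(a, b, cc, d))
    ft <- fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                      alternative = "greater")$p.value
    expect_equal(p, ft, tolerance = 1e-10)
  }
  expect_error(fisherReversalPvalue(0, 0, 0, 0), "all-zero")
})

test_that("BH adjustment matches the step-up procedure", {
  expect_equal(bhAdjust(0.01), 0.01)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(5)
  for (i in 1:10) {
    p <- runif(17)
    q <- bhAdjust(p)
    expect_equal(q, naiveBH(p))
    expect_true(all(q >= p - 1e-12))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("a constructed single flipped pair is the only reversal pair", {
  base <- c(a = 1, b = 2, c = 3, d = 4, e = 5)
  normal <- matrix(rep(base, 20), 5, dimnames = list(names(base), paste0("n", 1:20)))
  cancer <- normal
  cancer["a", ] <- 2.5               # flips (a, b) only
  colnames(cancer) <- paste0("c", 1:20)
  sp <- findStablePairs(normal)
  expect_equal(length(sp), choose(5, 2))
  rp <- findReversalPairs(sp, cancer)
  tab <- pairTable(rp)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$low, "a")
  expect_identical(tab$high, "b")
  expect_identical(tab$upMember, "a")
  expect_identical(tab$downMember, "b")
})

test_that("cancer identical to normal yields no reversal pairs", {
  set.seed(9)
  m <- matrix(rnorm(200, 8), 10, 20,
              dimnames = list(paste0("l", 1:10), paste0("n", 1:20)))
  m <- m + 2 * (1:10)            # separated baselines: stable pairs exist
  sp <- findStablePairs(m, 0.8)
  rp <- findReversalPairs(sp, m)
  expect_identical(length(rp), 0L)
})

test_that("reversal detection equals the composition of its parts", {
  set.seed(13)
  d <- makeSpikedData(seed = 13, nLnc = 60, nSamples = 40, log2fc = 2,
                      nUp = 4, nDown = 4, meanDeSamples = 10)
  sp <- findStablePairs(d$normal)
  rp <- findReversalPairs(sp, d$cancer, fdr = 0.1)
  # recompute by hand from the stable table and raw counts
  st <- pairTable(sp)
  cc <- dd <- integer(nrow(st))
  for (i in seq_len(nrow(st))) {
    lo <- d$cancer[st$low[i], ]; hi <- d$cancer[st$high[i], ]
    cc[i] <- sum(lo < hi); dd[i] <- sum(lo > hi)
  }
  q <- bhAdjust(fisherReversalPvalue(st$a, st$b, cc, dd))
  keep <- which(q < 0.1)
  got <- pairTable(rp)
  expect_identical(nrow(got), length(keep))
  expect_identical(got$low, st$low[keep])
  expect_identical(got$d, dd[keep])
  expect_equal(got$q, q[keep])
  # reversed orientation must be enriched in cancer for every kept pair
  expect_true(all(got$d / (got$c + got$d) > got$b / (got$a + got$b)))
  # and never more reversal pairs than stable pairs
  expect_lte(nrow(got), nrow(st))
})

test_that("pair detection is invariant to monotone per-sample transforms", {
  d <- makeSpikedData(seed = 21, nLnc = 40, nSamples = 30, log2fc = 1.5,
                      nUp = 3, nDown = 3, meanDeSamples = 8)
  warp <- function(m) {   # different strictly increasing map per sample
    for (s in seq_len(ncol(m))) m[, s] <- exp(m[, s] / (4 + s %% 3))
    m
  }
  sp1 <- pairTable(findStablePairs(d$normal))
  sp2 <- pairTable(findStablePairs(warp(d$normal)))
  expect_identical(sp1[, c("low", "high", "a", "b")],
                   sp2[, c("low", "high", "a", "b")])
  rp1 <- pairTable(findReversalPairs(findStablePairs(d$normal), d$cancer))
  rp2 <- pairTable(findReversalPairs(findStablePairs(warp(d$normal)),
                                     warp(d$cancer)))
  expect_equal(rp1, rp2)
})

test_that("an empty stable set warns and returns an empty reversal set", {
  m <- rbind(a = c(1, 2), b = c(2, 1))   # no stable order in 2 samples
  colnames(m) <- c("n1", "n2")
  sp <- findStablePairs(m)
  expect_identical(length(sp), 0L)
  expect_warning(rp <- findReversalPairs(sp, m), "empty")
  expect_identical(length(rp), 0L)
})
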