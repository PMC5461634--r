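test_that("Harrell's C-index scores pairs as the definition says", {
  # perfect ordering of event times by risk
  expect_equal(harrellCIndex(risk = 8:1, time = 1:8, event = rep(1, 8)), 1)
  # a constant risk score is exactly uninformative
  expect_equal(harrellCIndex(rep(2, 8), time = 1:8, event = rep(1, 8)), 0.5)
  # 8-sample censored fixture vs O(n^2) enumeration and survival::concordance
  set.seed(19)
  risk <- c(0.2, 0.9, 0.4, 0.9, 0.1, 0.7, 0.3, 0.5)
  time <- c(5, 1, 8, 2, 10, 3, 7, 4)
  event <- c(1, 1, 0, 1, 0, 1, 1, 0)
  c1 <- harrellCIndex(risk, time, event)
  expect_equal(c1, bruteCIndex(risk, time, event))
  cref <- survival::concordance(survival::Surv(time, event) ~ risk,
                                reverse = TRUE)$concordance
  expect_equal(c1, cref)
  # antisymmetry on tie-free data
  risk2 <- c(0.2, 0.9, 0.4, 0.85, 0.1, 0.7, 0.3, 0.5)
  expect_equal(harrellCIndex(risk2, time, event) +
               harrellCIndex(-risk2, time, event), 1)
  expect_warning(expect_true(is.na(harrellCIndex(1:3, c(2, 2, 2), c(0, 0, 0)))),
                 "no usable")
})

test_that("screening admits hazard-raising DE lncRNAs and skips degenerate splits", {
  co <- synthSurvivalCohort(nSamples = 300, nNull = 19, hr = 3, seed = 7)
  cand <- screenCandidates(co$calls, co$survival)
  expect_true(co$informative %in% cand$lnc)
  top <- cand[cand$lnc == co$informative, ]
  expect_gt(top$hr, 1)
  expect_true(top$admissible)
  expect_lt(top$logrankP, 0.05)
  # identical survival in both groups: not admitted
  n <- 60
  calls <- matrix("none", 1, n,
                  dimnames = list("lncA", paste0("P", 1:n)))
  calls[1, 1:30] <- "up"
  tt <- rep(c(3, 6, 9, 12, 18, 24), 5)
  sv <- data.frame(sample = paste0("P", 1:n), time = c(tt, tt),
                   event = rep(1, n))
  expect_warning(c0 <- screenCandidates(calls, sv), "no admissible")
  expect_identical(nrow(c0), 0L)
  # DE in a single sample: below the minimum split size, skipped
  calls1 <- calls; calls1[1, ] <- "none"; calls1[1, 1] <- "up"
  expect_warning(c1 <- screenCandidates(calls1, sv), "no admissible")
  expect_identical(nrow(c1), 0L)
})

test_that("forward selection follows the ranked strict-improvement procedure", {
  co <- synthSurvivalCohort(nSamples = 250, nNull = 7, hr = 2.5, seed = 11)
  cand <- screenCandidates(co$calls, co$survival)
  sig <- forwardSelect(cand, co$calls, co$survival)
  # combined C-index never below the best single candidate
  expect_gte(combinedCIndex(sig), max(cand$cIndex[cand$admissible]))
  # manual replay of the procedure with public pieces
  adm <- cand[cand$admissible, ]
  adm <- adm[order(-adm$cIndex, adm$lnc), ]
  m <- co$calls[, co$survival$sample]
  unionRisk <- function(members) {
    as.numeric(colSums(m[members$lnc, , drop = FALSE] ==
                       members$riskDirection) > 0)
  }
  members <- adm[1, ]
  cBest <- harrellCIndex(unionRisk(members), co$survival$time,
                         co$survival$event)
  for (i in seq_len(nrow(adm))[-1]) {
    trial <- rbind(members, adm[i, ])
    cTrial <- harrellCIndex(unionRisk(trial), co$survival$time,
                            co$survival$event)
    if (!is.na(cTrial) && cTrial > cBest) { members <- trial; cBest <- cTrial }
  }
  expect_identical(signatureMembers(sig)$lnc, members$lnc)
  expect_equal(combinedCIndex(sig), cBest)
  # single-candidate seeding
  one <- cand[cand$lnc == co$informative, ]
  sig1 <- forwardSelect(one, co$calls, co$survival)
  expect_identical(signatureMembers(sig1)$lnc, co$informative)
  expect_equal(combinedCIndex(sig1), one$cIndex)
})

.mkSignature <- function(lnc, dir) {
  new("LncSignature",
      members = S4Vectors::DataFrame(lnc = lnc, riskDirection = dir,
                                     cIndex = rep(0.6, length(lnc)),
                                     logrankP = rep(0.01, length(lnc)),
                                     coxP = rep(0.01, length(lnc)),
                                     hr = rep(2, length(lnc))),
      cIndex = 0.65,
      path = S4Vectors::DataFrame(step = 1L, lnc = lnc[1],
                                  action = "seed", cIndex = 0.6))
}

test_that("risk groups follow the direction-qualified union rule", {
  calls <- rbind(A = c("down", "none", "up", "none"),
                 B = c("none", "up", "none", "none"))
  colnames(calls) <- paste0("P", 1:4)
  sig <- .mkSignature(c("A", "B"), c("down", "up"))
  rg <- assignRiskGroups(calls, sig)
  # P1: A down (risk) -> high; P2: B up (risk) -> high
  # P3: A up but A's risk direction is down -> low; P4: nothing -> low
  expect_identical(unname(rg), c("high", "high", "low", "low"))
  expect_error(assignRiskGroups(calls[1, , drop = FALSE], sig), "B")
})

test_that("survival association recovers simulated hazards and ignores noise covariates", {
  # identical groups: HR ~ 1, log-rank p ~ 1
  tt <- rep(c(2, 5, 8, 11, 14, 20), 4)
  g <- rep(c("low", "high"), each = 12)
  sa0 <- survivalAssociation(g, tt, rep(1, 24))
  expect_equal(sa0$univariate$HR, 1, tolerance = 1e-6)
  expect_gt(sa0$logrankP, 0.9)
  # CI coverage of a true HR 2.5 at n = 300
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    grp <- rep(c(0, 1), 150)
    tEvent <- rexp(300, 0.04 * 2.5^grp)
    cens <- runif(300, 0, 40)
    sa <- survivalAssociation(ifelse(grp == 1, "high", "low"),
                              pmin(tEvent, cens),
                              as.integer(tEvent <= cens))
    if (sa$univariate$lo <= 2.5 && sa$univariate$hi >= 2.5) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
  # an independent noise covariate barely moves the group HR
  set.seed(202)
  grp <- rep(c(0, 1), 150)
  tEvent <- rexp(300, 0.04 * 2.5^grp)
  cens <- runif(300, 0, 40)
  gchr <- ifelse(grp == 1, "high", "low")
  time <- pmin(tEvent, cens); event <- as.integer(tEvent <= cens)
  plain <- survivalAssociation(gchr, time, event)
  noisy <- survivalAssociation(gchr, time, event,
                               covariates = data.frame(z = rnorm(300)))
  hrG <- noisy$multivariable$HR[noisy$multivariable$term == "ghigh"]
  expect_lt(abs(log(hrG) - log(plain$univariate$HR)), 0.15)
})

test_that("exported rules reproduce risk assignments from raw expression", {
  # build calls from expression, attach survival driven by one target
  d <- makeSpikedData(seed = 61, nLnc = 100, nSamples = 90, log2fc = 2,
                      nUp = 6, nDown = 6, meanDeSamples = 25)
  calls <- lncrindiv(d$normal, d$cancer)
  audit <- targetAudit(calls)
  cm <- callMatrix(calls)
  # pick spiked targets with plenty of calls as the survival drivers
  nCalls <- rowSums(cm != "none")[audit$lnc]
  drivers <- audit$lnc[order(-nCalls)][1:2]
  set.seed(61)
  de <- colSums(cm[drivers, , drop = FALSE] != "none") > 0
  tEvent <- rexp(ncol(cm), 0.03 * ifelse(de, 3.5, 1))
  cens <- runif(ncol(cm), 0, 45)
  sv <- data.frame(sample = colnames(cm), time = pmin(tEvent, cens),
                   event = as.integer(tEvent <= cens))
  cand <- screenCandidates(calls, sv)
  expect_gt(nrow(cand), 0)
  sig <- forwardSelect(cand, calls, sv)
  rules <- exportRules(sig, calls)
  members <- signatureMembers(sig)
  expect_identical(sort(unique(rules$member)), sort(members$lnc))
  expect_true(all(rules$majority == floor(rules$nPartners / 2) + 1))
  expect_true(all(rules$relation[rules$direction == "down"] == "lower"))
  # round trip: rules applied to raw expression == union rule on calls
  fromRules <- applyRules(rules, d$cancer)
  fromCalls <- assignRiskGroups(calls, sig)
  expect_identical(fromRules, fromCalls)
})
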