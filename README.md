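# LncRIndiv

Individual-level differential expression of lncRNAs from reversed
within-sample expression orderings.

## The problem

Standard differential-expression tools (t-tests, edgeR/DESeq-style
models) report which lncRNAs are dysregulated *on average* across a
cancer cohort. They say nothing about *which patients* carry the
dysregulation, and lncRNA expression is highly heterogeneous between
patients. LncRIndiv calls up- or down-regulated lncRNAs **per
individual cancer sample**, using only the ordering of expression
values *within* each sample. Because within-sample orderings are
invariant to any monotone normalisation, the calls are robust to batch
effects and platform differences — samples profiled in different
laboratories can be classified directly, and a patient can be
classified alone, with no cohort-level threshold.

## The method

Write G_a(s) < G_b(s) when lncRNA *a* has lower expression than *b* in
sample *s* (within-sample rank order; the smallest value has rank 1).

1. **Stable pairs.** An ordered pair (a, b) is *stable* when
   a < b holds in strictly more than 95% of normal samples:
   a/(a+b) > 0.95 in the 2×2 notation below. Under a fair-coin null
   this is astronomically unlikely (for 95 of 100 samples, one-sided
   binomial P = 6.26 × 10⁻²³).
2. **Reversal pairs.** For each stable pair, count the four
   orientation frequencies — *a*, *b* (normal: low<high, low>high) and
   *c*, *d* (cancer likewise) — and test enrichment of the reversed
   orientation *d* in cancer with a one-sided Fisher exact test;
   adjust across all stable pairs by Benjamini–Hochberg and keep pairs
   with FDR < 0.1. A flip implies the former-low member is
   up-regulated or the former-high member down-regulated.
3. **Partner curation.** For a target lncRNA, keep only reversal
   partners whose flip implies the target's own population-level
   direction (sign of its mean rank change), then rank partners by the
   coefficient of variation (CV) of their ranks across all samples and
   keep the (up to) 3 lowest-CV partners — partners whose own rank
   barely moves, so a flip can be attributed to the target.
4. **Per-sample call.** The target is called DE in a cancer sample iff
   the reversed orientation holds there for a strict majority of its
   selected pairs (≥2 of 3).

On top of the calls the package provides

* a **simulation benchmark** (synthetic normal cohorts, paired
  spike-in disease cohorts at log2FC ±1.0/±1.5/±2.0, sensitivity /
  specificity / F-score = harmonic mean of the two, and a
  paired-sample **consistency score**),
* a **prognostic-signature** workflow: log-rank + univariate Cox
  screening of DE lncRNAs (P < 0.05), forward selection maximising
  Harrell's C-index under the union risk rule (high risk iff any
  member is DE in its risk direction), and export of threshold-free
  pairwise **decision rules** ("expression of X lower than P1, P2,
  P3") that classify a single patient from raw values,
* a **copy-number concordance** test: per lncRNA, a hypergeometric
  test of the overlap between DE patients and patients with the
  direction-matched copy-number alteration (gain↔up, loss↔down;
  log2-ratio cutoffs ±0.1).

## Worked example

```r
library(LncRIndiv)

nm    <- synthNormalMatrix(nLnc = 300, nSamples = 210, seed = 1)
sp    <- spikeInDE(nm, nUp = 50, nDown = 50, log2fc = 1.5, seed = 42)
calls <- lncrindiv(normalMatrix(nm), cancerMatrix(sp$disease))
calls
#> DECalls: 300 lncRNAs x 210 cancer samples; 476 up and 514 down calls
#> across 178 callable targets

perf <- scorePerformance(calls, sp$truth)
sprintf("sensitivity %.4f  specificity %.4f  F-score %.4f",
        perf$sensitivity, perf$specificity, perf$fscore)
#> "sensitivity 0.9186  specificity 0.9983  F-score 0.9568"

cs <- consistencyScore(calls, rankTransform(cancerMatrix(sp$disease)),
                       rankTransform(normalMatrix(nm)))
cs$mean
#> 0.966

head(targetAudit(calls), 3)
#>       lnc direction nPartners                partners                     partnerCV
#> 1 lnc0002        up         3 lnc0070,lnc0076,lnc0099 0.0741928,0.0801964,0.0894407
#> 2 lnc0003        up         3 lnc0004,lnc0061,lnc0070 0.0617339,0.0683438,0.0741928
#> 3 lnc0005        up         3 lnc0141,lnc0096,lnc0037    0.105409,0.105654,0.107702
```

The synthetic cohort spikes 100 of 300 lncRNAs into a paired disease
cohort in ~10 samples each; at log2FC 1.5 the pipeline recovers ~92%
of the spiked (lncRNA, sample) events with ~99.8% specificity, and
~97% of its calls agree with the sign of the paired rank change. The
audit table shows, per callable target, the direction and the selected
low-CV reference partners behind each call.

A command-line front end with the same functionality is installed as
`exec/lncrindiv` (subcommands `stable-pairs`, `reversal-pairs`,
`call`, `simulate`, `evaluate`, `consistency`, `signature`,
`cna-concordance`; all I/O is header-rowed TSV).

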