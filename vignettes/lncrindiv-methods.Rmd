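---
title: "Individual-level DE calling from reversed expression orderings: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual-level DE calling from reversed expression orderings: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LncRIndiv)
```

## The model

The package rests on one empirical regularity: the *relative ordering*
of two genes' expression values within a sample is remarkably stable
across normal tissue of one type, and widely disturbed in tumours.
Orderings are invariant under any strictly monotone transformation of
a sample's values, so every statistic in this package — stable pairs,
reversal pairs, per-sample calls, the exported clinical rules — is
unchanged by normalisation choices, platform differences and batch
effects. That is the point of the design: a single patient profiled on
a different array than the reference cohort can still be classified.

Formally, for lncRNAs $a, b$ and sample $s$, let $a <_s b$ denote
$x_{as} < x_{bs}$. Exactly tied values support neither orientation and
are dropped from that pair's tally for that sample (continuous
expression rarely ties; no tie rule is imposed beyond this).

**Stable pairs.** Over $n$ normal samples with per-pair orientation
counts $a$ (low $<$ high) and $b$ (low $>$ high), the ordered pair is
stable when $a/(a+b) > 0.95$ — a strict inequality, so 95 of 100
exactly does *not* qualify. The strictness matters at cohort sizes
divisible by 20 and is covered by tests. The binomial illustration
$P(X \ge 95 \mid n = 100, p = 1/2) = 6.26\times10^{-23}$
(`binomialStabilityPvalue`) was verified against brute-force tail
summation; $n = 100$ reproduces the cited magnitude.

**Reversal pairs.** Against cancer counts $c, d$, the one-sided Fisher
exact test asks whether the reversed orientation $d$ is enriched in
cancer. One-sided is deliberate: the hypothesis is directional (the
stable order *reverses*), and a two-sided test would also reward
pairs that become *more* concordant. The p-value is computed as a
vectorised hypergeometric upper tail; tests check it against
`fisher.test` and an exhaustive same-margin enumeration.
Benjamini–Hochberg correction is applied across the family of *all*
stable pairs tested in the run — that is the set on which p-values
are produced — and pairs with $q < 0.1$ (strict) are retained.

**Per-target curation and calling.** A reversal of (low, high) can
mean the low member rose or the high member fell. The target's
population direction disambiguates: the sign of (mean within-sample
rank in cancer − mean rank in normal). The mean-rank estimator is a
design choice — the reference description asserts a direction exists
but not its estimator — chosen because it stays on the rank scale and
is robust; exact equality of means excludes the target from calling.
Partners whose flip contradicts the target's direction are removed.
Remaining partners are ranked by the coefficient of variation of
their ranks pooled over *both* groups (sample SD with the $n-1$
denominator; ties broken lexicographically by partner ID so selection
is deterministic) and the 3 smallest-CV partners are kept, or all of
them if fewer. A low-CV partner is a fixed landmark: if the pair
flips, it is the target that moved. Finally, a target is called DE in
a cancer sample iff the reversed orientation holds there for a
*strict majority* of selected pairs — ≥2 of 3, 2 of 2, 1 of 1 — which
prevents single-pair false calls at $k = 2$.

Whether partners may simultaneously be DE targets themselves is left
unconstrained; nothing in the procedure requires exclusivity, and in
dense panels a spiked lncRNA routinely serves as another target's
partner.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `stabilityFrac` | 0.95 | strict support threshold for stable pairs |
| `fdr` | 0.1 | strict BH threshold for reversal pairs |
| `k` | 3 | maximum reversal partners per target |
| `minNonzeroFrac` | 0.9 | inclusive expression filter (fraction of samples with non-zero values) |
| `ampCut`, `delCut` | +0.1, −0.1 | strict log2-ratio cutoffs for copy-number states |

Probe-level matrices are aggregated to lncRNAs by the arithmetic mean
of probe values *on the scale provided*; the package does not decide
whether that scale is log-transformed (aggregation before vs. after
log transform is a user choice the rank machinery is indifferent to
only when it is applied consistently to both groups).

## The synthetic-data generator

All testing is self-contained: `synthNormalMatrix` plays the role of
a real normal-tissue cohort. It emulates the two features of real
lncRNA profiles that the rank machinery is actually sensitive to:

1. **A right-skewed abundance distribution.** Baselines are
   truncated-exponential on [4, 12] log2 units (scale 0.9): most
   lncRNAs crowd near the expression floor with a long tail of highly
   expressed ones. Crowding produces many small between-lncRNA gaps,
   hence many unstable pairs.
2. **Heteroscedastic rank stability.** Per-lncRNA noise SDs come from
   a two-component lognormal: a *quiet* subpopulation (60%, median SD
   0.125 log2 units) and a *noisy* one (40%, median SD 1.8), each
   with sdlog 0.4. Real cohorts contain both tightly rank-stable
   transcripts and erratic ones; a single homoscedastic noise level
   cannot reproduce that. In particular, under homoscedastic noise
   the stable-pair density and spike detectability are mutually
   exclusive: noise large enough to leave only ~27% of pairs stable
   forces every stable pair's gap beyond the reach of a 1.5 log2FC
   spike, and noise small enough to detect spikes leaves ~70% of
   pairs stable. The two-component design resolves this exactly the
   way real data does — close, quiet pairs are both stable and
   flippable.

With these defaults and 210 normal samples, 25–30% of all pairs are
stable at the 95% criterion, matching the density reported for real
cohorts (~237k stable pairs among ~1310 lncRNAs is 28%). The quiet-SD
median was fixed at 0.125 so that flips at the smallest benchmark
effect size (log2FC 1.0–1.5) remain stochastic rather than saturated,
preserving the qualitative effect-size gradient of the benchmark;
0.10 already saturates detection at 1.5.

`spikeInDE` builds the disease cohort as a *sample-paired copy* of
the normal matrix and adds ±log2FC to each spiked lncRNA in a random
subset of samples (binomial with expectation `meanDeSamples = 10`,
floor 1 — only an *average* spike prevalence is specified, so a
binomial draw is the natural reading). Spiked lncRNAs are drawn from
the *callable* pool: lncRNAs in the lower half of rank SD across
normals possessing ≥3 stable pairs in the concordant orientation
(partners above for an up-spike, below for a down-spike). This
mirrors how spike-in panels are constructed in practice — from
lncRNAs already identified as dysregulated — and it is observable
from the normal data alone. Without the orientation condition,
down-spikes land on floor-dwelling lncRNAs with nothing below them
and sensitivity collapses for reasons that have nothing to do with
the method.

**What the generator does not emulate:** gene–gene correlation
structure, intensity-dependent (mean–variance) noise coupling,
outlier samples, missingness, and annotation error. Passing the
benchmark therefore demonstrates internal correctness of the pipeline
under a realistic rank-stability regime, not performance on any
particular clinical dataset.

## Evaluation

Evaluation is at the (lncRNA, sample)-*event* level: sensitivity is
the fraction of spiked events called with the correct direction
(direction-aware — a wrong-direction call is not an identification);
specificity the fraction of non-events left uncalled; the F-score the
harmonic mean of the two. The evaluated universe defaults to the
spiked lncRNAs × all disease samples: those rows have a defined truth
status in every cell, whereas a bystander lncRNA that a spiked one
jumps over suffers a real rank displacement with no defined truth.
The ~0.999 specificity magnitudes of the reference benchmark are
arithmetically consistent only with this universe. The full-matrix
universe is available via the `universe` argument.

The consistency score needs no simulation truth: on sample-paired
cancer/normal profiles, a call is consistent when its direction
matches the sign of (rank in cancer sample − rank in matched normal);
a zero rank change matches neither. Samples with no calls are
excluded from the mean rather than imputed.

Benchmark problem sizes: 300 lncRNAs (100 spiked), 210 + 210 samples,
ten replicate seeds per operating point, with a 60 vs 60 subsampled
scenario drawn from the same pools. These sizes keep the full grid in
the minutes range while leaving all per-pair statistics in the same
regime (BH family ~12k pairs) as larger panels.

One detectability constraint is worth stating because it is a
property of the method, not of any implementation: with a BH family
of $m$ stable pairs, a spiked lncRNA is discoverable only when its
spiked-sample count $k$ makes the best attainable per-pair p-value
$\approx 2^{-k}$ survive $q = p\,m/\mathrm{rank} < 0.1$. At $m
\approx 3\times10^3$–$10^4$ this needs $k \gtrsim 7$; a lncRNA spiked
in 4–5 samples is invisible at FDR 0.1 *regardless of noise level*.
Binomial spike counts therefore put a ceiling just under 1 on
attainable sensitivity, which is visible in the benchmark numbers.

## Prognostic signature

DE lncRNAs are screened by splitting patients into with/without-DE
groups (minimum 3 per side; smaller splits are degenerate) and
requiring log-rank *and* univariate Cox p < 0.05. The two screening
p-values are deliberately uncorrected — screening at a nominal level
is the convention this procedure follows, and the forward selection
provides the actual model choice. The risk direction is the lncRNA's
DE direction when the DE group carries HR > 1. Candidates whose DE
group is *protective* (HR < 1) are reported but marked inadmissible:
the union risk rule ("high risk iff any member is DE in its risk
direction") has no way to express "risky when *not* DE", and the
union rule is the only combination the published 2-lncRNA signature
exhibits. For the same reason the combined score during selection is
the union rule itself — the reference procedure never states how
multi-lncRNA candidates are scored mid-selection, and using the rule
that defines the final classifier keeps selection and deployment
consistent. This is the package's single largest interpretive choice
and is flagged here prominently.

Forward selection ranks admissible candidates by decreasing
univariate C-index (ties lexicographic), seeds with the best one, and
iterates through the remainder in order, keeping an addition only
when the combined Harrell C-index *strictly* increases (an equal
C-index discards the addition). The procedure iterates the full
ranked list rather than stopping at the first non-improvement; the
published wording ("repeat until not increased") is ambiguous between
the two, and trying every candidate is the more faithful reading of
"add … once at a time based on the decreasing C-index value".
Harrell's C is computed over usable pairs (earlier time has an event,
times unequal; risk ties score 0.5) and is validated against both an
$O(n^2)$ enumeration and `survival::concordance`.

`exportRules` turns a signature into the deployable artifact: per
member, up to three pairwise comparisons ("expression of X lower than
P") plus the strict-majority vote, applicable to a single patient's
raw values with no thresholds. `applyRules` re-derives the risk
groups from an expression matrix and reproduces `assignRiskGroups`
exactly on the training data; the round trip is tested.

## Copy-number concordance

Per lncRNA, DE patients are intersected with patients carrying the
direction-matched discrete alteration (+1 gain for up, −1 loss for
down; states from strict ±0.1 log2-ratio cutoffs). The p-value is the
hypergeometric upper tail with the *shared* patients of the two
matrices as population — cohorts overlap imperfectly and no
imputation rule is defensible, so patients absent from either matrix
are simply outside the experiment. Region-level significance
filtering (e.g. GISTIC q-value thresholds) is upstream metadata;
`cohortConcordance` accepts a whitelist instead of re-deriving it.

## Numerical and degenerate-input choices

* Exact expression ties within a sample: dropped from the pair's
  count (both in stability and reversal tallies); in per-sample
  voting a tie is *not* a flip.
* Rank ties: average rank (`rank(..., ties.method = "average")`).
* Missing values: rejected at construction — the rank machinery has
  no NA semantics and silent imputation would be worse.
* Empty stable set: reversal detection warns and returns an empty
  set; downstream calling produces an all-`none` matrix.
* A target with no concordant partners, or with an exactly tied mean
  rank, yields an all-`none` row and is absent from the audit table.
* `fisherReversalPvalue` rejects an all-zero table; zero margins
  otherwise give p = 1 as the tail convention dictates.
* Degenerate survival covariates fail their own term with a warning;
  the run continues.
* Expression TSVs are written with 10 significant digits; round trips
  are value-exact for data at or below that precision.

## Limitations

* Sensitivity is bounded by the FDR-family detectability constraint
  above: lncRNAs dysregulated in very few patients cannot be
  discovered, only *called* once discovered through other patients.
* The generator's independence assumptions (no co-expression) make
  the simulated BH family slightly better behaved than a real one;
  correlated pairs would share flips and the effective family would
  be smaller than the nominal count.
* The prognostic workflow inherits the union rule's asymmetry:
  protective DE lncRNAs are excluded from signatures by construction.
* Consistency scoring requires genuinely paired samples; applying it
  to unpaired cohorts answers a different question.
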