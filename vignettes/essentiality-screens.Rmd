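---
title: "Classifying essential genes in pooled dropout screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying essential genes in pooled dropout screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfscreen)
```

## The problem and the model

A pooled loss-of-function screen measures, for every reagent in a library,
the log2 fold-change of its abundance as the cell population grows. Reagents
targeting genes the cells require drop out; everything else drifts around
zero. The unit of measurement is the reagent, but the unit of interest is
the gene, and the two are separated by pervasive noise: reagents differ in
efficacy, some silence unintended targets, and whole screens differ in
quality.

`bfscreen` treats gene classification as a supervised two-class problem.
Given training sets of known essential and known nonessential genes, the
fold-changes of their reagents provide empirical likelihoods
Pr(fold-change | essential) and Pr(fold-change | nonessential), estimated by
Gaussian kernel density estimation separately for every screen and
timepoint (replicates pooled). A gene's log2 Bayes Factor is the sum of
per-observation log2 likelihood ratios across its reagents, replicates, and
timepoints. Summation assumes observations are independent given the class
— false for a reagent measured at two timepoints, but the bias it introduces
(overconfident magnitudes) does not disturb the ranking that all downstream
calls use.

The classifier is deliberately screen-local: a density pair is trained and
applied within one screen and timepoint, so systematic differences between
screens (depth of dropout, noise level) are absorbed into the likelihoods
rather than requiring cross-screen normalization.

### Truncation

Log2 fold-changes are clipped into [−4, +0.5] at training and scoring time.
Beyond these bounds the nonessential likelihood becomes vanishingly small
and a single outlying observation would dominate a gene's score, while
carrying no real additional evidence — a reagent 16-fold depleted is not
more convincingly essential than one 15-fold depleted. Clipping also makes
the score invariant to the exact magnitude of extreme values, which is
asserted as a test invariant.

### Priors

A Bayes Factor becomes a posterior log odds (LOD) by adding the log2 prior
odds. Two priors are provided:

* **Uniform** (`uniform_prior(0.1)`): every gene gets the same
  log2(0.1) ≈ −3.32, encoding a background expectation that about 10% of
  assayed genes are essential. It shifts, but never reorders, the ranking.
* **Expression-based** (`fit_expression_prior()`): genes are ranked by
  expression, binned (500 genes per bin by default), and the log2 fraction
  of training essentials per bin (+0.001 pseudocount against empty bins) is
  regressed on the bin's mean expression. The fit uses only bins with mean
  log2 FPKM > 1: below that the relation flattens into the pseudocount
  floor and would drag the line down. Emitted priors are clamped into
  [log2(0.001), 0] — a prior probability can exceed neither 1 nor,
  by construction, the pseudocount floor.

### Reference sets and cross-validation

Training labels come from the data themselves. Seed essentials are found by
singular value decomposition of a reagent-by-sample fold-change matrix: the
first left singular vector (U1) captures consistent dropout, and genes whose
reagents are enriched in its right tail — upper-tail hypergeometric test on
the count of a gene's reagents at or above the gene's median projection,
Benjamini–Hochberg adjusted, FDR < 0.25 — are seeds. They are then filtered
to constitutively, invariantly expressed genes (mean log2 FPKM > 0 and
per-gene SD below the across-gene mean SD, in every RNA-seq panel supplied).
Reference nonessentials are genes with FPKM < 0.1 in all but one sample of
every panel, intersected with the assayed library.

Both sets are split in half (seeded shuffle, alternate assignment, train
takes the odd gene): densities are trained on one half and every evaluation
uses only the withheld half, with `swap_split()` supplying the mirrored fold
so training genes are never scored against densities they helped fit.

## Evaluation and essential-set calling

Each screen's genes are ranked by BF (or LOD); precision and recall against
the withheld test sets give a PR curve, and the F-measure is read at the
point where the score crosses zero. Screens with F ≥ 0.75 are "performing".
Core essentials are genes hit in at least half the performing screens
(inclusive boundary: `ceiling(majority × n)`); total essentials are genes
hit in ≥ 3 of the top 12 screens ranked by F-measure. The binwise FDR of the
observation histogram is estimated by treating hits exclusive to later,
disjoint screen sets as false positives; the expected false positives per
bin is the *mean* of the later sets' exclusive counts — each later set is an
independent model of the false-positive distribution, and averaging (rather
than summing) keeps the estimate on the scale of one set. Genes with trace
expression (mean log2 FPKM < −2) cannot be essential, so the fraction of
them called as hits estimates a screen's background error rate.

## The saturation model

How many essential genes would this compendium find if screening continued
forever? The model: each screen reports a fixed number of hits
(`hits_per_screen`), of which a fixed fraction `fdr` are false; true hits
are drawn uniformly without replacement from an essential population of
size E, false hits from the remaining G − E genes. Fixed (rounded) counts
rather than binomial draws are used because the observed quantity being
mimicked — genes reported per screen — is itself fixed per screen at its
mean. The cumulative unique-hit curve then has the exact expectation

E[C_k] = E·(1 − (1 − t/E)^k) + (G − E)·(1 − (1 − f/(G − E))^k),

with t and f the true/false hits per screen. This closed form is both the
default model curve in the grid fit (it is the infinite-replicate limit of
the Monte-Carlo mean, at no simulation cost) and the independent oracle
against which the simulation is tested. The fit minimizes unweighted RMSD
over all screen ranks, and reports the region of grid points with RMSD
below 1.5× the minimum; the argmin is always a member of the region, which
matters only in the degenerate self-fit case where the minimum is exactly 0.

The RMSD landscape has a diagonal ridge — a larger essential population with
a lower FDR produces a similar curve — so a single observed curve localizes
the parameter pair much better along the ridge's normal than along it. The
default grid (E from 500 to 2,000 by 25; FDR from 0 to 0.30 by 0.005)
brackets the plausible range for genome-scale human screens at ~15,700 genes
and ~600 hits per screen; grid cells infeasible under the model's
constraints (more true hits than essentials) are assigned infinite RMSD
rather than rejected, so one grid can span feasibility boundaries.

## What the synthetic generator emulates — and what it does not

`simulate_compendium()` generates the world the classifier assumes, plus
the failure modes it must tolerate:

* **Dropout kinetics.** An effective reagent of an essential gene draws from
  Normal(shift × quality × j/T, noise_sd) at timepoint j of T — later
  timepoints deplete further, as dropout deepens with cell doublings, giving
  per-timepoint densities distinct shapes as in real screens.
* **Reagent efficacy.** Only a fraction (default 0.8) of an essential gene's
  reagents are effective; the rest behave like nonessential reagents.
* **Off-targets.** Each nonessential gene's reagent behaves as essential
  with probability `offtarget_rate` (default 0.01), assigned *per reagent*
  and kept consistent across screens — seed-sequence artifacts follow the
  reagent, not the experiment. These produce the reproducible false
  positives that core/total calling must contend with.
* **Screen quality.** A per-screen multiplier on the dropout shift.
* **Expression.** `generate_expression()` allocates expression values so the
  probability a value belongs to an essential gene is proportional to
  2^(slope × expression) (calibrated so probabilities sum to the essential
  count, capped at 1) — making the binned log2(fraction essential) relation
  linear with a known slope. Base values are drawn from a normal truncated
  at log2 FPKM = −1, and trace expression (FPKM 0) is injected only into
  nonessential genes, so trace genes are nonessential by construction.

Defaults (1,200 genes, 10% essential, 5 reagents per gene, 3 replicates,
2 timepoints, shift −2, noise SD 0.5) are a downscaled but
proportion-faithful rendering of a genome-scale shRNA compendium; the 10%
essential fraction matches the uniform prior's background expectation.

The generator does **not** emulate: correlated noise between reagents of a
gene, context-specific (subtype) essentiality, copy-number-driven dropout,
reagent abundance effects, or count-level sequencing noise. A green
end-to-end test therefore establishes that the pipeline recovers truth under
the model's own assumptions — it does not certify performance on real
compendia, where those unmodelled effects set the error floor.

## Numerical choices

* **KDE bandwidth**: Scott-type rule of thumb (`bw.nrd`) on the truncated
  training sample, with a scalar `bw_adjust` multiplier; a degenerate sample
  (zero variance) falls back to 0.01, one grid step.
* **Density evaluation**: each density is evaluated once on a fixed grid of
  step 0.01 spanning half a unit beyond the truncation bounds; scoring
  interpolates linearly. This bounds cost at (grid length) density
  evaluations regardless of compendium size.
* **Density floor**: 10⁻⁶ of each density's grid maximum, applied after
  fitting, so log-ratios are always finite; a score at the floor contributes
  a large but bounded term.
* **Median for even reagent counts**: the lower median, so the median
  reagent itself always counts among the "at or above" set and k ≥ ⌈n/2⌉
  holds by construction.
* **Hypergeometric observed count**: the test statistic is the number of a
  gene's reagents at or above its median projection (not the median's rank,
  which does not type-check as a hypergeometric draw), with the marked
  population defined by the same cutoff.
* **SVD sign**: inherently arbitrary; fixed by requiring the sum of
  first right-singular-vector entries to be negative (dropout samples
  project negatively), so depleted reagents project positively. Exact zero
  sum falls back to making the first nonzero U1 entry positive. Missing
  cells are imputed as 0 — the neutral fold-change — for the decomposition
  only; they never contribute terms to a Bayes Factor.
* **Quantile-normalization ties**: tied values receive the mean of the
  reference values across their tied ranks, which makes the transform well
  defined and idempotent (limma's interpolation at the average rank differs
  for ties of three or more; the two agree on tie-free data, which a test
  asserts).
* **Ranking ties**: PR curves break score ties lexicographically by gene id;
  screen rankings break F-measure ties by screen id. Determinism over
  statistical elegance.
* **F at threshold**: evaluated at the last ranked gene with score at or
  above the threshold; 0 when no gene qualifies or P + R = 0.

## Known limitations

* Bayes Factor magnitudes are not calibrated probabilities: replicate and
  timepoint observations of one reagent are correlated, so 30 summed terms
  overstate the evidence. Thresholds (0, 5, 10, 20) should be read as
  ranking cutpoints validated against reference sets, not as posterior odds.
* The saturation model assumes screens are exchangeable draws from one
  essential population; genuinely context-specific essentials inflate the
  imputed false-positive rate, biasing the fitted FDR upward.
* With a single observed curve the saturation argmin remains uncertain along
  the RMSD ridge even when the confidence region is tight across it; the
  region, not the argmin, is the honest summary at small screen counts or
  low hit counts.
* `fit_densities()` requires ≥ 30 training observations per class per
  timepoint by default; tiny reference sets should lower `min_obs`
  deliberately rather than silently.
* The expression-based prior assumes log-linearity above 2-fold FPKM; it
  extrapolates (clamped) outside the fitted range.

## Session info

```{r}
sessionInfo()
```
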