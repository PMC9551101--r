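---
title: "Methods: miRNA target-set crossover enrichment and cross-disorder convergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA target-set crossover enrichment and cross-disorder convergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircross)
```

## The analysis in one paragraph

Inhibiting a repressive histone methyltransferase (for example EHMT with
UNC0638) de-represses a set of miRNAs. Several of those miRNAs are
predicted to target the mRNA of the neuronal master repressor NRSF/REST,
and the same miRNAs keep appearing in gene lists for intellectual
disability (ID) and schizophrenia (SCZ). The pipeline in this package makes
that chain of observations quantitative in three stages: (1) which miRNAs
are upregulated after treatment (a fold-change/FDR filter on a small-RNA
count matrix), (2) which of those miRNAs have predicted target sets that
overlap a disease gene list more than chance ("crossover probability",
one test per miRNA), and (3) whether the miRNAs sharing a common target —
the REST-targeting ones — are over-represented inside each
disorder-associated miRNA set (a second-level set test, summarised by a
three-disorder Venn diagram and its core set).

## Stage 1: the upregulation filter

Counts are FPKM-normalised,
`FPKM = count / ((length/1000) * (library_size/1e6))`, with the library
size taken as the sample's column sum; the mature-miRNA length is in
nucleotides. The reported fold change is
`(mean FPKM treated + eps) / (mean FPKM control + eps)` with `eps = 0.25`
FPKM, so all-zero control groups stay finite. A miRNA survives when
`fold_change >= 2.5` *and* the BH-adjusted p-value is `< 0.05`; the
boundary at exactly 2.5 is included, and only the upregulated direction is
screened.

The p-value comes from a self-contained negative-binomial Wald-type test
on median-of-ratios size-factor-normalised counts (`test = "nb_wald"`):

* **Dispersion.** Per-miRNA method-of-moments estimates
  `(s^2 - m)/m^2`, pooled across the two conditions and floored at
  `1e-8`, are moderated toward the 10%-trimmed mean of all per-miRNA
  estimates with a prior weight of 20 degrees of freedom. With two or
  three replicates per group the raw estimate is far too noisy to use
  alone; shrinking toward the panel-wide centre is the standard
  empirical-Bayes remedy in this field.
* **Statistic.** The log ratio of group means of normalised counts (a
  0.5-count pseudocount keeps it finite), with a delta-method standard
  error from the NB variance function `mu + disp * mu^2`.
* **Empirical null.** Even with a stabilised dispersion, the Wald z of an
  NB log-ratio at n = 3 per group is slightly over-dispersed relative to
  N(0, 1) (its null spread is about 1.05 in our simulations). The z
  vector is therefore rescaled by its own MAD-based null-spread estimate
  before two-sided normal p-values are taken. The scale factor is floored
  at 1 — the correction can only widen, never narrow — and is skipped for
  panels under 50 miRNAs, where a MAD is itself unstable. Because the MAD
  is robust to a minority of genuinely changed miRNAs, real signal
  inflates it only marginally (making the test slightly conservative, the
  safe direction).

Under simulated nulls (2000 miRNAs, 3 vs 3, dispersion 0.05) the raw
p < 0.05 rate sits within the binomial 99% band of 0.05, and miRNAs
planted at fold changes of 20.6, 7.95, 6.70 and 4.62 — the magnitudes a
qPCR validation of such an experiment reports — survive the full filter in
over 95% of simulation replicates. Both properties are asserted in the
test suite at exactly those sizes.

Two alternative engines are kept behind the `test` argument:
`"log_fpkm_welch"` (Welch t on `log2(FPKM + 0.25)`) as a distribution-free
sanity check, and `"fc_only"` for designs without replication, which
reports fold changes with no p-values.

## Stage 2: crossover probability

For each surviving miRNA the urn is: `N` genes in the universe, `K` of
them on the disease list, the miRNA's `n` predicted targets are the draw,
and `k` is the observed overlap. The reported p-value is the upper tail
`P(X >= k)` — an enrichment question, so one-sided by design — of
**Fisher's noncentral hypergeometric distribution** with odds parameter
`omega`. A miRNA is disorder-associated when `p < 0.01` (raw; the screen
deliberately applies no multiple-testing correction at this stage, though
`adjust = TRUE` is available).

Fisher's variant (each success item carries an odds multiplier, the total
draw size conditioned on) was chosen over Wallenius' because no
sequential-sampling story is implied by prediction-score weighting;
Fisher's is the conditional-independence construction and reduces exactly
to the central distribution at `omega = 1`. Wallenius' numerics are out of
scope.

**The odds parameter.** Prediction scores (miRDB convention, 50–100) enter
through a two-colour reduction:
`omega = mean(score of targets on the disease list) / mean(score of
targets off it)`, with `omega = 1` whenever either group is empty. This
reduction is deterministic, reduces to the central test under uniform
scores, and is monotone in the score advantage of disease-listed targets —
the three properties we consider essential. It is one defensible mapping
among several (the underlying methods literature does not pin one down);
a generative Monte-Carlo alternative (`crossover_mc`: draws weighted by
`score/100` for targets, 0.5 baseline otherwise) is included as a
sensitivity check, not as the screen's engine.

**The universe.** By default all genes appearing in the target table; an
explicit background gene set can be supplied. Disease-list and target
identifiers outside the universe are reported, never silently dropped. A
miRNA with no universe targets is kept in the output with `p = 1` and
flagged untestable.

## Stage 3: convergence and the Venn core

For each disorder the second-level test asks whether the REST-targeting
miRNAs concentrate inside the disorder-associated set: with `M` miRNAs in
the universe, `D` disorder-associated, `R` REST-targeting and `x` in the
overlap, `p = P(X >= x)` for `Hypergeometric(N = M, K = D, n = R)`,
significant at `p < 0.05`. The universe defaults to the upregulated
survivor set — the population both memberships were defined on — and can
be switched to all expressed miRNAs (`universe = "all"`); the choice is
genuinely open, and with the survivor-set default the three published
significance calls (ID and SCZ enriched, ASD not: tails 0.039, 0.021 and
0.121 against 0.05) are reproduced from the printed counts alone.

`venn_decompose` partitions any miRNA collection into the 7 regions of
three sets (plus the outside region; counts always sum to the collection
size), and `core_set` returns the triple intersection — run on the
REST-targeting collection this is the core miRNA set shared by all three
disorders.

## Numerical choices

* Noncentral masses are accumulated in log space
  (`lchoose + k*log(omega)`, log-sum-exp), stable for gene universes of
  at least 25,000.
* `pmf` outside the support returns 0 and `sf` at or below the support
  minimum returns 1, so tail sums are total functions; `omega = Inf` puts
  all mass on the support maximum.
* Central tails go through `stats::phyper`/`dhyper`; BH adjustment through
  `stats::p.adjust`. The package's own noncentral code is cross-checked in
  the tests against a direct enumeration oracle (relative error 1e-9 for
  N up to 200), against `stats::fisher.test` evaluated at a null odds
  ratio, and against a conditioned-Bernoulli Monte-Carlo oracle.
* Size factors are median-of-ratios with all-zero rows excluded, scaled to
  geometric mean 1.

## The qPCR formulas

`ddct` implements 2^-ddCt relative quantification with amplification
efficiency fixed at 2: per replicate `dCt = Ct_target - Ct_reference`,
`ddCt` subtracts the mean calibrator dCt, and the per-condition point
estimate `2^-mean(ddCt)` makes the calibrator exactly 1. The SEM is
computed across replicates on the rq scale (matching mean±SEM bar plots);
`log_scale = TRUE` reports it in cycles instead. With two reference genes,
pass the mean of their Ct values as `ct_reference` — the geometric-mean
normalisation on the concentration scale. `chip_enrichment` implements
percent-of-input with dilution adjustment,
`100 * 2^((Ct_input - log2(1/input_fraction)) - Ct_IP)`; this is the
standard ChIP-qPCR convention, stated here as such.

## The synthetic-data generators

`simulate_counts` emulates a two-condition small-RNA experiment:
log-normal baseline abundances, log-normal library sizes centred on 5e6
reads (a desk-scale stand-in for production sequencing depth), NB counts
with dispersion 0.05, and planted miRNAs whose treated-condition mean is
multiplied by a true fold change; planted miRNAs get a fixed baseline mean
of 200 counts, since miRNAs worth validating are rarely near the detection
floor. `simulate_targets` draws each miRNA's predicted targets from a
synthetic 1000-gene universe — 100 targets per miRNA, keeping miRDB-like
proportions at this universe size — with disease genes oversampled
5-fold for planted disorder-miRNAs and scores uniform on [50, 100]. Every
generator is a pure function of its seed.

What the generators deliberately do **not** emulate: mean–dispersion
trends, GC or length biases, miRNA families with correlated counts,
overlapping disease lists curated with different criteria, or the
heavy-tailed target-set sizes of real prediction databases. Passing tests
on this synthetic material therefore demonstrate the statistical
machinery's correctness and calibration under its stated model, not
robustness to every artefact of production data.

`reference_fixture` is different in kind: a deterministic input bundle
constructed so the full pipeline, run at its standard thresholds,
reproduces a known published pattern of set cardinalities exactly — 56
survivors; disorder sets of 43/34/15 with the 15 inside the 43 and 13 of
them shared with the 34; 11 shared-target miRNAs overlapping 11/10/5; a
five-member core set (miR-26a, miR-26b, miR-153, miR-181a, miR-548). Only
those cardinalities and five names are anchored externally; every other
identifier is synthetic (`mirSIM-*`, `mirNULL-*`), and the fixture's 444
unchanged miRNAs keep the composition effect of library-size normalisation
small enough that the planted 6-fold signal clears the 2.5-fold cut.
Construction fails loudly if any cardinality constraint breaks.

## Worked example

```{r example}
fx <- reference_fixture()
report <- run_all(fx, verbose = FALSE)
report
report$venn$counts
```

## Problem sizes used by the test suite

Distribution properties are checked over randomised urns up to N = 200
(enumeration oracle) and N = 25,000 (stability); Monte-Carlo agreement at
1e5 accepted samples; DE calibration on 2000 null miRNAs and power on 200
simulation seeds of 200 miRNAs each. These sizes give the binomial bands
quoted above while keeping a full test run under a minute of CPU.

## Known limitations

* The score-to-odds mapping is a modelling choice, not an estimate; other
  monotone reductions would give different (correlated) p-values.
* The crossover screen treats target predictions as fixed truth; the
  noncentral test weights but does not propagate prediction uncertainty.
* The NB test assumes a common dispersion scale across conditions and
  uses plug-in group means in the variance; with fewer than two
  replicates per group only `fc_only` is honest.
* Identifier harmonisation across databases (species prefixes, arm
  suffixes) is out of scope: sets are matched by exact string identity.
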