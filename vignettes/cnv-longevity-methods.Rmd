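---
title: "Methods: CNV-gene-longevity causality network inference"
author: "cnvLongevity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNV-gene-longevity causality network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In an aging cohort with whole-genome copy-number calls, brain expression
profiles and clinical follow-up to death, we want to know which rare copy
number variants (CNVs) influence how long patients live, and whether that
influence runs *through* gene expression (CNV &rarr; gene &rarr; age of
death) or is merely reflected in expression because aging itself alters
transcription (CNV &rarr; age of death &rarr; gene). `cnvLongevity`
implements that full analysis as a reusable, tested pipeline over three
tables: an integer dosage matrix (CNVs &times; samples, diploid baseline
2), a log2 expression matrix (genes &times; samples), and a phenotype
table carrying age of death (AOD, capped at 90 years), sex and three
Alzheimer's pathology severity scores (clinical consensus diagnosis
`cogdx` 1&ndash;5, Braak stage `braaksc` 0&ndash;6, CERAD plaque score
`ceradsc` on the recoded 1&ndash;4 scale).

Because the real cohort is controlled-access, the package ships a
synthetic cohort generator with known mediation ground truth; every
stage of the pipeline is validated against it.

## The screening model

Three association screens feed the causal test, all at Benjamini-Hochberg
(BH) FDR < 0.05 — BH is the package-wide meaning of "FDR":

1. **CNV&ndash;AOD** (`cnvAodScan`): per CNV, ordinary least squares of

   AOD = &beta;&middot;dosage + &alpha;&middot;sex +
   &gamma;&middot;trait + &epsilon;

   with dosage as a numeric copy number (0&ndash;4; a single slope per
   CNV, matching how per-CNV effects are conventionally reported) and
   the disease-status covariate being one pathology trait as a numeric
   severity score, not a binary diagnosis flag. CNVs with zero dosage
   standard deviation are excluded (no contrast to test). The scan is
   run under each of the three traits and the **consensus** is the
   intersection of the three significant sets, so that a CNV's call
   does not hinge on one operationalization of disease severity. FDR
   is computed across the CNVs tested within a trait.

2. **CNV&ndash;gene eQTL** (`cnvGeneScan`): gene expression regressed
   on dosage + sex + trait, on the samples shared by all three inputs,
   for every (consensus CNV, gene) pair, with one BH adjustment across
   all pairs jointly. This is exactly the linear model a matrix-eQTL
   engine fits; no link function is involved.

3. **Gene&ndash;AOD** (`geneAodSpearman`): before screening, expression
   is residualized per gene on intercept + trait (`residualize`), so
   disease severity cannot masquerade as a longevity signal. The screen
   is the tie-corrected Spearman rank correlation between residualized
   expression and capped AOD, with a two-sided t-approximation p-value
   and genome-wide BH adjustment. Residuals of an ordinary linear model
   are orthogonal to the trait by construction; the "subtract
   &alpha;&times;trait" shorthand is implemented as full linear-model
   residuals (intercept included), since removing the slope but not the
   intercept would only shift every value by a constant and change no
   downstream correlation.

A **triplet** is a (CNV, gene) pair significant in screen 2 whose CNV
passed screen 1 and whose gene passed screen 3 (`assembleTriplets`).
Duplicate (CNV, gene) keys — which can arise when an upstream table
repeats a row — are collapsed before causal testing.

## The Causal Inference Test

For each triplet the package runs a from-scratch Causal Inference Test
(CIT) in both directions (`citComponents`, `scenarioSelect`). Writing L
for dosage, G for the mediator and T for the outcome, the four
component conditions are

* p1 — L and T associated: partial F-test of L in `T ~ L (+ covariates)`;
* p2 — L and G associated given T: F-test of L in `G ~ T + L`;
* p3 — G and T associated given L: F-test of G in `T ~ L + G`;
* p4 — T independent of L given G: a permutation *equivalence* test.
  Fit `G ~ L`, form surrogate mediators `G*_b = fitted + permuted
  residuals` for b = 1..`n_perm`, compute the F statistic of L in
  `T ~ G*_b + L` for each surrogate, and set
  `p4 = (1 + #{F*_b <= F_obs}) / (n_perm + 1)` where `F_obs` is the L
  statistic in `T ~ G + L`. Each surrogate preserves G's dependence on
  L but destroys its residual link to T, so the surrogate F's describe
  what the residual L&rarr;T signal looks like under *complete*
  mediation; a small p4 says the observed residual signal is at least
  that small. The add-one correction keeps p4 away from zero.

The omnibus p-value is the intersection&ndash;union combination
`max(p1, p2, p3, p4)` — small only when *all four* conditions hold,
which also makes the omnibus conservative under the null (the
calibration test in the suite confirms the empirical size is below
nominal).

Scenario 1 tests the chain CNV &rarr; gene &rarr; AOD; scenario 2 swaps
the roles of G and T (aging drives expression). Omnibus p-values are
BH-adjusted *within each scenario across triplets*, and the more
significant scenario wins: `causal` if the scenario-1 FDR is smaller
and below `alpha` (default 0.05), `reactive` for scenario 2, `ambiguous`
on an exact tie below `alpha` (never silently causal), `none` otherwise.
Covariates (sex + trait) enter every component regression by default;
`adjust_covariates = FALSE` disables that, which is the right setting
for raw simulated chains with no confounding.

Numerical details: all component F's are computed from residual sums of
squares of QR-based least-squares fits, so p4 is invariant to affine
rescaling of G and T; the permutation stream is driven by a seed derived
per triplet and per scenario from the configured seed, making reports
reproducible and independent of how many triplets accompany a given
test. `n_perm` defaults to 1,000 (resolution 1/1001 &asymp; 0.001);
at least a few hundred is advisable for reported results.

## Supporting computations

* **Frequencies** (`summarizeFrequencies`): per CNV, deletion alleles
  are counted as `max(0, 2 - dosage)` and duplication alleles as
  `max(0, dosage - 2)` per sample; the allele number is twice the
  sample count; a *carrier* is any sample with dosage &ne; 2, in either
  direction. This reproduces published allele-count arithmetic exactly
  (e.g. 2 alleles / 2,254 &rarr; AF 0.0887%; 28 carriers of 1,127
  &rarr; 2.48%).
* **Group comparison** (`groupFrequencyTest`): per CNV, the 2&times;2
  carrier &times; diagnosis-group table with a plain Pearson chi-square
  (no continuity correction by default; a flag restores Yates).
* **External validation** (`validateAgainstDb`): a query CNV is
  validated when the best type-compatible database record reciprocally
  overlaps it *strictly* above 50% in both directions ("more than 50%"
  read literally: 0.5 exactly fails). Coordinates are 1-based fully
  closed intervals (length = end &minus; start + 1). An mCNV query is
  type-compatible with any database type by default — a mixed locus
  carries both allele classes — and `mcnv_matches_any = FALSE` demands
  exact matches. When several records partially cover one query, the
  single best match (largest minimal reciprocal overlap) is reported.
* **Survival** (`kmLogrank`): one Kaplan-Meier curve per distinct
  dosage value, all subjects treated as observed deaths (censoring
  support exists but defaults off), K-group log-rank test with K-1
  degrees of freedom; dosage groups with fewer than two samples are
  merged into the nearest dosage value with a warning.
* **Enrichment** (`fisherEnrichment`): one-sided Fisher's exact
  (hypergeometric upper tail) per gene set against a user-supplied
  universe, fold enrichment defined as
  `(overlap / input size) / (term size / universe size)`, BH across
  terms. Terms are intersected with the universe before testing and
  input genes must be a subset of the universe.
* **Export** (`exportNetwork`): SIF plus node/edge attribute TSVs
  loadable by Cytoscape; correlation mode emits undirected signed
  edges for every triplet, causality mode only the directed chains of
  triplets called causal or reactive.

## The synthetic cohort generator

`generateCohort` draws, per CNV, deviant-allele counts from
binomial(2, AF) with AF uniform over `allele_freq_range`; deletion loci
lose copies, duplication loci gain, and mixed (mCNV) loci split each
deviant allele between the two directions, so type labels stay
meaningful for overlap validation. Sex is Bernoulli(1/2). The three
pathology scores are noisy monotone transforms of one latent severity,
so they are correlated but not interchangeable — mirroring their role
as alternative covariates (the `cogdx` cut reproduces roughly a
one-third normal-cognition fraction). Expression is a gene baseline +
severity loading + Gaussian noise; mediator genes add
`beta_cg * (dosage - 2)`. AOD is `aod_mean` plus, per causal edge,
`beta_ga` times the mediator's dosage-driven and intrinsic-noise
components, plus direct effects of reactive CNVs, sex and severity
effects, Gaussian noise with SD `sd_aod`, and finally the cap at
`aod_cap` (default 90). Reactive genes respond to the *capped* realized
AOD with slope `beta_ag`. Identical config + seed gives bit-identical
output; a single seed set once drives every draw.

Two structural choices deserve explanation:

* **The severity component of a mediator is not forwarded into AOD.**
  Mediation forwards the mediator's dosage signal and intrinsic noise;
  forwarding its severity loading as well would give each cohort a
  random, `beta_ga`-amplified severity&rarr;AOD coefficient, making
  cohort behavior swing wildly between seeds. Severity still affects
  both expression and AOD (through its own terms), so it remains a
  genuine confounder that the covariate adjustment has to handle.
* **One mediator gene per causal CNV by default.** With k equally
  loaded mediators, conditioning on one leaves the other paths' signal
  in T, so the CIT's conditional-independence component *correctly*
  refuses complete mediation per edge — per-edge causal calls are
  structurally suppressed, which is a property of multi-path mediation,
  not an error. The single-mediator cohort is the clean baseline;
  `genes_per_causal_cnv > 1` remains available to study exactly that
  suppression.

Default parameters (all overridable): 1,100 samples, 200 CNVs, 2,000
genes; AF range 0.4&ndash;1.25% (the upper region of the published
rare-CNV band — about 9&ndash;27 expected carriers at n = 1,100, which
is the regime where effects of the published magnitude are detectable);
3 causal and 2 reactive CNVs (matching the scale of the published
3-CNV causal network); `beta_cg` = 1.5 log2 units/copy, `beta_ga` = 8
years per log2 unit (total mediated effect 12 years/copy, inside the
published 4&ndash;13 year per-copy band), `beta_direct` = 8 years/copy,
`beta_ag` = 0.1 log2 units/year; expression noise SD 0.5, AOD noise SD
8 years, mean AOD 83. The number of mediated loci is kept small on
purpose: every mediator's intrinsic noise propagates into AOD
(`beta_ga` &times; 0.5 = 4 years each), so many mediated loci would
inflate AOD variance and mask each individual CNV.

What the generator does **not** emulate: linkage disequilibrium,
genome-wide CNV landscapes, batch effects, censoring, non-Gaussian
expression noise, and multi-tissue structure. Passing tests on this
generator therefore certify the *statistical machinery* — calibration,
directionality, effect recovery, determinism — not performance on any
particular real cohort.

## Numerical choices and degenerate inputs

* The AOD cap is applied at load time (`readPhenotypes`, default 90)
  and at generation time. A capped phenotype attenuates regression
  slopes when carriers are pushed into the cap; recovery simulations
  in the test suite therefore measure estimators on uncapped draws,
  while capping itself is asserted separately.
* Constant predictors error (`linearAssoc`, CIT's L and G); constant
  genes are skipped with a warning in the Spearman screen (rho is
  undefined); rank-deficient designs error naming the collinear
  columns.
* Genes with numerically zero residual variance in the differential
  expression screen get p = 1 when the group difference is also zero
  (no evidence), by convention.
* Spearman ties take average ranks; the statistic is Pearson on ranks,
  which is the tie-corrected form.
* TSV writers emit 17 significant digits, so write &rarr; read
  round-trips reproduce doubles exactly and pipeline artifacts are
  byte-stable under re-runs.
* The differential-expression screen reports the classical pooled
  t-statistic by default. Residuals are identical with or without
  empirical-Bayes variance moderation (moderation rescales standard
  errors, not coefficients), which is why `residualize` needs no
  moderation at all; `moderated = TRUE` switches the DEG test to the
  moderated t.

## Problem sizes used by the shipped validation

The test suite exercises: the published-table arithmetic at n = 1,127;
CIT directionality on 100 causal and 100 reactive chains (n = 500,
standardized effects 0.5, 500 permutations); CIT calibration on 500
null triplets; effect recovery over 200 cohorts of 1,100; and full
two-run byte-identity of the pipeline at the default cohort size.
These sizes were chosen so the whole suite completes in a few minutes
on one CPU while keeping Monte Carlo error well inside the asserted
margins.

## Known limitations

* The pipeline tests marginal mediation per (CNV, gene) edge; it does
  not fit joint multi-mediator models, mixed models, or kinship
  corrections.
* BH is applied within well-defined families (per scan, per scenario);
  no permutation-based eQTL FDR is offered.
* The CIT here addresses continuous outcomes only; survival-outcome
  CIT variants are out of scope (survival enters through the separate
  Kaplan-Meier/log-rank module).
* Enrichment requires the user to supply gene sets (GMT); no pathway
  database ships with the package.
* With AOD capped at 90, effects among the longest-lived individuals
  are intrinsically attenuated; consensus counts and recall on
  synthetic cohorts should be read with that in mind.
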