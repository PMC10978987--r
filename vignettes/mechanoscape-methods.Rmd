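---
title: "Models and methods behind mechanoscape"
author: "mechanoscape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mechanoscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechanoscape)
```

# Scope

`mechanoscape` packages the statistical machinery used in pan-cancer
studies of mechanosensitive adapter genes — the kindlin family
(*FERMT1/2/3*) being the motivating case — into a tested, reusable
pipeline. Four analysis surfaces are covered: the mutant
stability/flexibility landscape, co-alteration statistics,
RPPA-style pathway activity calls, and shared cohort statistics
(paired differentials, group splits, survival). A synthetic cohort
generator with planted, recorded ground truth ties them together so that
every significance procedure in the package can be checked for
calibration and every estimator for parameter recovery.

The package consumes *derived* inputs: per-mutant stability
(\(\Delta\Delta G\), kJ/mol) and vibrational-entropy (\(\Delta\Delta S\),
unitless) changes as produced by elastic-network normal-mode analysis,
alteration matrices, expression/methylation/phospho matrices and
survival tables. It does not compute normal modes, parse structures,
call CNVs or fit differential-expression models beyond simple paired
tests; those belong to upstream tools.

# The stability landscape

## Sign conventions

For a mutant, \(\Delta\Delta G = \Delta G_{WT} - \Delta G_{mut}\):
positive values indicate stabilization. The identical contract holds for
\(\Delta\Delta S\) (positive = increased flexibility). Oligomerization
affinity shifts are mutant-minus-wild-type,
\(\Delta BA = \Delta BA_{mut} - \Delta BA_{WT}\) (kcal/mol), so positive
values are *unfavorable* for dimer/trimer formation. The
\(\Delta\Delta G\)–\(\Delta\Delta S\) plane is divided into quadrants
Q1 (both up), Q2 (stability up, flexibility down), Q3 (both down) and
Q4 (stability down, flexibility up); any exact zero is labelled
`boundary` rather than forced into a quadrant, because the quadrant
populations are defined by strict signs only.

## Recurrence weighting and percentile regions

Each mutant's \(\Delta\Delta G\) is replicated by its recurrence (the
mutation's frequency across tumors) before ranking, so a hotspot mutation
influences the thresholds in proportion to its prevalence. Percentiles
use the strictly-below nearest-rank form \(P = 100\,n/N\) (\(n\) = values
strictly below, ties share a percentile); the same convention is reused
for quartile group splits so the package has exactly one percentile
definition. Regions are half-open — P1 \([0,25)\), P2 \([25,75)\),
P3 \([75,100]\) — so every percentile maps to exactly one region.

## The five-category scheme

Within the stabilizing cohort P1/P2/P3 map to low/moderate/high; within
the destabilizing cohort the mapping reverses (the most negative values
are the most severe). Two thresholds refine the ends:

\[
\mathrm{Avg(low)} = \tfrac12\left(|\mathrm{med}(P1)_{stab}| +
|\mathrm{med}(P3)_{destab}|\right),\qquad
\mathrm{Avg(high)} = \tfrac12\left(|\mathrm{med}(P3)_{stab}| +
|\mathrm{med}(P1)_{destab}|\right)
\]

Low-region mutants with \(|\Delta\Delta G| < \mathrm{Avg(low)}\) are
reassigned `slight`; high-region mutants with
\(|\Delta\Delta G| \ge \mathrm{Avg(high)}\) become `very_high`. The
`slight` rule is standard in this analysis tradition; the `very_high`
rule is its symmetric completion, which we adopt as a design decision —
it is the only refinement consistent with treating the two tails alike,
and it preserves monotonicity of severity in \(|\Delta\Delta G|\) within
each sign cohort (property-tested). Exact zeros are excluded and
counted. Degenerate ties (a side whose values are all equal) collapse
into one region; an empty region's median falls back to the side median
so the thresholds remain defined.

Whether recurrence expansion happens before or after the
stabilizing/destabilizing split is immaterial under these conventions
(copies of a mutant share its value, hence its percentile); the
implementation computes per-mutant percentiles against the expanded
multiset, which the tests confirm equals expansion-first classification.

The high-impact screen retains mutants with
\(\Delta\Delta G \ge +1.24\) or \(\le -1.24\) kJ/mol (inclusive), the
conventional cut separating highly stabilizing/destabilizing mutants
from the bulk. Deleteriousness calls threshold a SIFT-type score
strictly at 0.05 (`loss_of_function` below, `neutral` at or above,
`unclassified` when missing).

# Co-alteration statistics

For an anchor gene, samples partition into anchor-altered and
anchor-unaltered cohorts. Per partner gene, A% and U% are the partner's
alteration percentages in the two cohorts, and the mean co-alteration
dynamics of a gene set of size \(N\) is

\[ X = \frac{\sum A\% - \sum U\%}{N}. \]

\(X\) is linear over disjoint unions (size-weighted mean), zero when
A% = U% elementwise, and collapses to zero under anchor-label
permutation — all three properties are tested, and a permutation test is
provided as a diagnostic.

Pairwise dependence is summarized by the 2x2 odds ratio
\(\mathrm{OR} = (n_{11} n_{00})/(n_{10} n_{01})\), with the Haldane
+0.5 correction applied only when a zero cell occurs, and a two-sided
Fisher exact test (exact at the small strata partner analyses produce;
the test suite verifies it against the hypergeometric tail closed form by
full enumeration). The package reports `exclusive` for log2 OR < 0 at
q <= 0.05 and `co-occurrent` for log2 OR > 0 — the conventional sign.
Published analyses sometimes pair the word "mutually exclusive" with
positive log2 odds ratios; we do not guess at such intent and always
report the signed value alongside the call. Percentages are cohort-wide
by default; per-cancer-type stratification is available by subsetting
the alteration matrix. Multiple testing uses Benjamini–Hochberg
throughout.

# Pathway activity

RPPA-like component matrices are normalized per component by median
centering and SD scaling across samples (idempotent, and invariant to
per-component affine rescaling). The pathway activity score of a sample
is the sum of normalized positive-regulator components minus the sum of
negative-regulator components. For a gene of interest, samples split at
the gene's median expression (ties to the low group, deterministic);
pathway scores of the two groups are compared with a two-sided Welch
t-test — the median split yields generically unequal group variances, so
the unequal-variance form is the safer default; the variant is recorded
in the run manifest. p-values are BH-adjusted across all (gene, pathway)
pairs submitted in one batch: the FDR family is the batch, a logged,
configurable choice. Calls are `activate` when the high group's mean
score exceeds the low group's at FDR <= 0.05, `inhibit` for the reverse,
`none` otherwise. The global percentage of a call for a (gene, pathway)
is \(100 \times\) (cancer types with that call) / (cancer types).

# Cohort statistics

Paired tumor/normal differentials average the per-pair difference on the
log scale (log2 of the tumor/normal ratio for ratio-scale inputs) and
test it with a paired Student t-test; features with fewer than 10
complete pairs (configurable) are excluded and counted, and zero-variance
differences yield p = 1 by convention — deterministic and conservative.
Expression z-scores are computed against the unaltered cohort's
mean/SD, flagged at ±1.96 (inclusive). Median splits send ties to the
low group; quartile splits use the shared strictly-below percentile
convention with inclusive boundaries (>= 75 high, <= 25 low).

Survival uses the product-limit estimator with Greenwood variance and
log-log 95% intervals, the standard log-rank chi-square, and a
single-covariate Cox model with Breslow tie handling (the simplest
documented default; noted in output metadata). A positive Cox
coefficient flags the indicator group as having worse survival. The
log-rank p is verified against a label-permutation oracle at small n.
Kruskal–Wallis serves rank comparisons; the pairwise mode applies the
two-group test to each named pair (which equals the rank-sum normal
approximation), and the mode used is logged.

# The synthetic cohort generator

The generator is first-class, tested code: its defaults define the
package's reference study conditions, and its truth record is the only
ground-truth source the tests consult.

* **Alterations.** A latent Gaussian vector is thresholded at
  \(\Phi^{-1}(1-p_g)\) per gene, preserving each marginal exactly.
  Planted pairwise odds ratios are induced by calibrating the latent
  pairwise correlation with bisection against the bivariate-normal
  orthant probability (integration tolerance 1e-10, odds-ratio
  tolerance 1e-9 on the log scale). Structures whose calibrated latent
  matrix is not positive definite are rejected with a clear error.
* **Reference conditions.** 1000 samples, 60 genes (FERMT1/2/3 plus
  named mechanochemical interactors), 10 cancer types; kindlin baseline
  alteration probabilities 0.29/0.27/0.20 and 0.15 elsewhere, matching
  the altered-cohort fractions reported for large pan-cancer kindlin
  cohorts. Mutual exclusivity is planted across all three kindlin pairs.
  A fully pairwise-exclusive triangle is mathematically bounded under
  the Gaussian copula at these marginals: the published-scale magnitudes
  (log2 OR −3/−2.77/−1.93) produce a non-positive-definite latent
  matrix, so the defaults plant the strongest uniformly scaled version
  that is comfortably realisable, log2 OR −2.40/−2.22/−1.54 (80%),
  plus one co-occurrent partner pair (OR 3).
* **Expression.** Paired tumor/normal values on the log2(TPM+1) scale;
  per-gene baselines are uniform on [2, 8] with unit Gaussian noise, and
  planted log2 shifts (+1 for the kindlins by default) apply to altered
  tumor samples only.
* **Survival.** Exponential event times with baseline rate 0.1 per time
  unit scaled by the planted hazard ratio of each group (default:
  high/low with HR 1.9, the magnitude reported for high-risk kindlin
  expression cohorts); censoring is independent uniform on
  \([0, T_{max}]\) with \(T_{max}\) calibrated by root-finding so the
  expected censoring fraction is the requested 30%. The closed-form
  planted HR makes recovery tests exact.
* **Mutants.** \((\Delta\Delta G, \Delta\Delta S)\) bivariate normal
  with planted correlation −0.75 (the magnitude reported for kindlin
  mutant landscapes); the \(\Delta\Delta G\) scale defaults to
  \(1.24/\Phi^{-1}(0.95) \approx 0.754\) kJ/mol, placing 10% of mutants
  beyond the ±1.24 high-impact screen. Recurrence counts follow a power
  law \(P(k) \propto k^{-2}\) truncated at 50 — a realistic heavy tail
  for mutation recurrence — and 5% of records are frameshifts lacking
  \(\Delta\Delta S\), exercising the missing-data paths.
* **RPPA.** Components are standard normal; each planted
  (gene, pathway, shift) effect adds the shift (in SD units) to the
  pathway's positive-regulator components within the gene's
  expression-high half. Null pathways and extra null components carry no
  dependence on any gene.
* **Seeding.** All draws flow from one root seed through named
  substreams (one per table), so adding or resizing one table never
  perturbs the others, and identical spec + seed reproduces identical
  bundles (tested).

What the generator deliberately does **not** emulate: mutational
signatures, copy-number segments, read-level data, methylation-array
chemistry, batch effects, or the correlation structure of real
transcriptomes. Passing recovery tests therefore demonstrates that the
estimators are correct and calibrated under the stated models — not that
real cohorts satisfy those models.

# Numerical choices and test problem sizes

Calibration and recovery checks run at sizes chosen to make Monte-Carlo
error small relative to each tolerance: marginal and tail-mass checks at
n = 5000 (3 binomial SE), odds-ratio recovery at n = 5000 over 20 seeds
(tolerance ±0.5 log2 units ≈ 4 SE), hazard-ratio recovery at n = 2000
over 20 seeds, null calibration of pathway calls over 1000 generator
replicates at n = 50 (binomial SE ≈ 0.7 percentage points at the 5%
level) and power at n = 1000 over 100 replicates, correlation recovery
at n = 5000 mutants. The survival-recovery band [1.8, 2.2] spans about
±1.9 standard errors of the Cox estimate at n = 2000 with 30% censoring,
so roughly one seed in twenty is expected to fall outside it even for an
exact implementation; the suite reports the observed count honestly
rather than widening the band.

# Known limitations

* The Gaussian copula bounds jointly plantable odds-ratio structures;
  strongly exclusive cliques may be rejected as non-realisable even
  though other joint laws could realize them.
* Planted pathway effects shift positive-regulator components only;
  effects that act through negative regulators can be emulated by sign
  reversal but are not a separate dial.
* The Cox step fits a single group indicator; multivariate models with
  clinical covariates are out of scope.
* `classifyMagnitude` requires at least 4 recurrence-expanded values per
  sign cohort; smaller cohorts are a hard error rather than a guess.
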