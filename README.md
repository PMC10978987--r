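# mechanoscape

Pan-cancer mechanochemical alteration landscape analysis for
mechanosensitive adapter genes — the kindlin family (*FERMT1*, *FERMT2*,
*FERMT3*) being the motivating case. The package is aimed at
computational cancer biologists who have *derived* inputs in hand
(normal-mode-analysis stability predictions, alteration matrices,
omics feature matrices, survival tables) and need the downstream
statistics as tested, reusable building blocks.

## What it computes

**Mutant stability landscape.** From per-mutant
ΔΔG = ΔG<sub>WT</sub> − ΔG<sub>mut</sub> (kJ/mol, positive =
stabilizing) and ΔΔS (unitless, positive = increased flexibility):
quadrant labels of the ΔΔG–ΔΔS plane; recurrence-weighted five-category
magnitude classification built on strict percentiles
P = 100·n/N and the thresholds

&nbsp;&nbsp;Avg(low) = (|med(P1)<sub>stab</sub>| + |med(P3)<sub>destab</sub>|)/2,&nbsp;&nbsp;
Avg(high) = (|med(P3)<sub>stab</sub>| + |med(P1)<sub>destab</sub>|)/2;

the ±1.24 kJ/mol high-impact screen; oligomerization affinity shifts
ΔBA = ΔBA<sub>mut</sub> − ΔBA<sub>WT</sub> (kcal/mol, positive =
unfavorable); SIFT-threshold loss-of-function calls; and the
stability–flexibility regression trend with 95% confidence band.

**Co-alteration statistics.** Partner alteration percentages A%/U% in
anchor-altered versus unaltered cohorts, the mean co-alteration dynamics
of a gene set X = (ΣA% − ΣU%)/N, and pairwise mutual-exclusivity odds
ratios (Haldane-corrected at zero cells) with two-sided Fisher exact
tests and Benjamini–Hochberg FDR.

**Pathway activity.** Median-center/SD normalization of RPPA-style
components, pathway activity scores (Σ positive − Σ negative
regulators), median-split Welch-t activation/inhibition calls at
FDR ≤ 0.05, and global percentages across cancer types.

**Cohort statistics.** Paired tumor/normal differentials with a
minimum-pairs filter, ±1.96 z-score flags, median/quartile splits,
Kaplan–Meier curves with log-log 95% CIs, log-rank tests, Cox hazard
ratios with the coefficient-sign worse-survival rule, Kruskal–Wallis
rank comparisons and Pearson/Spearman correlation reports.

**Synthetic cohorts.** A seeded generator that plants known pairwise
odds ratios (latent Gaussian copula calibrated by bisection, marginals
preserved exactly), expression shifts, hazard ratios (exponential
baseline, uniform censoring) and a ΔΔG–ΔΔS correlation of −0.75, with a
serialized truth record — the substrate for every calibration and
recovery test in the suite.

## Worked example

```r
library(mechanoscape)

spec <- CohortSpec(seed = 7)      # reference conditions: 1000 samples, 60 genes
bundle <- generateCohort(spec)
bundle
#> CohortBundle (seed 7 )
#>   alterations: 60 genes x 1000 samples
#>   expression: 60 genes x 2000 columns (paired tumor/normal)
#>   survival: 1000 samples, groups: low/high
#>   rppa: 60 components x 1000 samples
#>   mutants: 500 records

# mutual exclusivity of the kindlin pair (planted log2 OR: -2.40)
mutualExclusivity(alterations(bundle), "FERMT1", "FERMT2")
#>   both a_only b_only neither log2_odds_ratio p
#> 1   23    262    248     467         -2.5968 0
```

The estimated log2 odds ratio of −2.60 recovers the planted exclusivity
(−2.40) within sampling error; 23 of 1000 samples carry both
alterations where ~80 would be expected under independence.

```r
# survival by the planted high/low groups (planted hazard ratio: 1.9)
cox <- coxHazardRatio(survivalData(bundle))
#> HR 2.09 [1.79, 2.44], worse group: high; logrank p = 1.09e-21

# five-category magnitude classification of the mutant table
res <- classifyMagnitude(mutantTable(bundle))
res$thresholds
#> MagnitudeThresholds: Average(low) = 0.1675467 | Average(high) = 1.062849 kJ/mol
table(as.character(res$categories$category), res$categories$sign)
#>             destabilizing stabilizing
#>   high                 37          37
#>   low                  27           5
#>   moderate            124         112
#>   slight               34          41
#>   very_high            44          39

stabilityFlexibilityTrend(mutantTable(bundle))$r
#> ddG-ddS Pearson r = -0.756 (p = 4.81e-87)   # planted: -0.75
```

Every quantity above is a recovery of a value the generator planted and
recorded in `cohortTruth(bundle)`.

A command-line pipeline over the same functions lives in
`inst/cli/mechanoscape.R` with subcommands `simulate`, `stability`,
`coalter`, `pas` and `survive`; each step writes TSV outputs and appends
seed/test-variant provenance to a `run-manifest.txt`.

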