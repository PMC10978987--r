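Package: mechanoscape
Title: Pan-Cancer Mechanochemical Alteration Landscape Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistical toolkit for pan-cancer analysis of mechanosensitive
    adapter genes such as the kindlins (FERMT1/2/3). Provides classification
    of mutant stability/flexibility landscapes from normal-mode-analysis
    derived free-energy and vibrational-entropy changes (quadrant scheme,
    recurrence-weighted percentile magnitude categories, high-impact
    screening, oligomerization affinity shifts), co-alteration frequency and
    mean co-alteration dynamics statistics with mutual-exclusivity odds
    ratios, RPPA-style pathway activity scoring with median-split
    activation/inhibition calls, shared cohort statistics (paired
    differentials, Kaplan-Meier/log-rank/Cox survival, quartile and median
    splits, rank and correlation tests), and a seeded synthetic cohort
    generator that plants known co-alteration odds ratios, expression
    shifts, hazard ratios and stability-flexibility correlations for
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival,
    fgsea,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: Software, StatisticalMethod, Survival, Pathways, SomaticMutation
RoxygenNote: 7.3.3
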