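# Synthetic cohort generator: determinism, planted-parameter fidelity and
# degenerate-input contracts.

test_that("identical spec and seed reproduce identical bundles", {
  spec <- CohortSpec(nSamples = 150, nMutants = 60, seed = 7)
  b1 <- generateCohort(spec)
  b2 <- generateCohort(spec)
  expect_identical(alteredStatus(alterations(b1)),
                   alteredStatus(alterations(b2)))
  expect_identical(featureValues(expressionData(b1)),
                   featureValues(expressionData(b2)))
  expect_identical(as.data.frame(survivalData(b1)),
                   as.data.frame(survivalData(b2)))
  expect_identical(featureValues(rppaData(b1)), featureValues(rppaData(b2)))
  expect_identical(as.data.frame(mutantTable(b1)),
                   as.data.frame(mutantTable(b2)))
  expect_identical(cohortTruth(b1), cohortTruth(b2))
})

test_that("named substreams isolate tables: resizing the mutant table never perturbs the others", {
  b1 <- generateCohort(CohortSpec(nSamples = 120, nMutants = 40, seed = 5))
  b2 <- generateCohort(CohortSpec(nSamples = 120, nMutants = 90, seed = 5))
  expect_identical(alteredStatus(alterations(b1)),
                   alteredStatus(alterations(b2)))
  expect_identical(as.data.frame(survivalData(b1)),
                   as.data.frame(survivalData(b2)))
  expect_identical(featureValues(expressionData(b1)),
                   featureValues(expressionData(b2)))
})

test_that("null cohort marginals match the planted baseline within 3 binomial SE and pairwise log2 OR is centered on 0", {
  # the log2 OR of one null draw at n = 5000 has SD ~0.10, so a |.| < 0.2
  # check is only a 2-sigma bound per draw; averaging over seeds tests the
  # same centering with sound joint coverage.
  log2ors <- c()
  for (seed in 1:5) {
    spec <- CohortSpec(
      nSamples = 5000, nCancerTypes = 2L,
      geneNames = paste0("G", 1:6), baselineProb = 0.3,
      plantedOR = data.frame(gene_a = character(), gene_b = character(),
                             odds_ratio = numeric()),
      plantedShift = setNames(numeric(0), character(0)),
      plantedHR = c(all = 1), censoringFraction = 0, nMutants = 5L,
      pathways = list(PathwayDefinition("pw", "c1")),
      pathwayEffects = data.frame(gene = character(),
                                  pathway = character(),
                                  shift = numeric()),
      seed = seed)
    am <- alterations(generateCohort(spec))
    if (seed == 1) {
      st <- alteredStatus(am)
      se3 <- 3 * sqrt(0.3 * 0.7 / 5000)
      expect_true(all(abs(rowMeans(st) - 0.3) < se3))
    }
    for (pair in list(c("G1", "G2"), c("G3", "G4"), c("G5", "G6"))) {
      me <- mutualExclusivity(am, pair[1], pair[2])
      log2ors <- c(log2ors, me$log2_odds_ratio)
      expect_lt(abs(me$log2_odds_ratio), 0.45)  # ~4.5 sigma per draw
    }
  }
  expect_lt(abs(mean(log2ors)), 0.1)  # SE of the mean ~0.026
})

test_that("a planted exclusivity odds ratio of 0.2 is recovered by the co-alteration module", {
  b <- generateCohort(pairSpec(seed = 9, or = 0.2))
  me <- mutualExclusivity(alterations(b), "G1", "G2")
  expect_lt(abs(me$log2_odds_ratio - log2(0.2)), 0.5)
  expect_lte(me$q, 0.05)
  expect_identical(me$call, "exclusive")
})

test_that("expression shifts are applied to altered tumor samples only", {
  spec <- CohortSpec(nSamples = 2000, nCancerTypes = 2L,
                     geneNames = c("G1", "G2"), baselineProb = 0.3,
                     plantedOR = data.frame(gene_a = character(),
                                            gene_b = character(),
                                            odds_ratio = numeric()),
                     plantedShift = c(G1 = 1.5),
                     plantedHR = c(all = 1), censoringFraction = 0,
                     nMutants = 5L,
                     pathways = list(PathwayDefinition("pw", "c1")),
                     pathwayEffects = data.frame(gene = character(),
                                                 pathway = character(),
                                                 shift = numeric()),
                     seed = 3)
  b <- generateCohort(spec)
  expr <- featureValues(expressionData(b))
  tumor <- expr[, tissueType(expressionData(b)) == "tumor"]
  colnames(tumor) <- pairId(expressionData(b))[
    tissueType(expressionData(b)) == "tumor"]
  alt <- alteredStatus(alterations(b))["G1", colnames(tumor)]
  gap <- mean(tumor["G1", alt]) - mean(tumor["G1", !alt])
  expect_lt(abs(gap - 1.5), 0.2)
  gap2 <- mean(tumor["G2", alt]) - mean(tumor["G2", !alt])
  expect_lt(abs(gap2), 0.2)
})

test_that("mutant table obeys its planted law: correlation, recurrence support and high-impact tail mass", {
  spec <- CohortSpec(nSamples = 100, nMutants = 5000, seed = 21)
  mt <- generateMutantTable(spec)
  expect_true(all(mt$recurrence >= 1L))
  expect_true(all(mt$recurrence <= 50L))
  ok <- is.finite(mt$ddS)
  expect_lt(abs(cor(mt$ddG[ok], mt$ddS[ok]) - (-0.75)), 0.05)
  truth <- cohortTruth(generateCohort(CohortSpec(nSamples = 10,
                                                 nMutants = 10, seed = 21)))
  tail <- truth$high_impact_tail_mass
  expect_equal(tail, 0.10, tolerance = 1e-12)
  frac <- mean(abs(mt$ddG) >= 1.24)
  expect_lt(abs(frac - tail), 3 * sqrt(tail * (1 - tail) / 5000))
})

test_that("survival times respect the planted censoring fraction and group structure", {
  b <- generateCohort(pairSpec(seed = 13, n = 4000, or = NULL))
  sv <- survivalData(b)
  expect_true(all(sv$time >= 0))
  expect_true(all(sv$event %in% c(0L, 1L)))
  expect_lt(abs(mean(sv$event == 0) - 0.3), 0.03)
  expect_equal(sort(unique(sv$group)), c("high", "low"))
})

test_that("rppa matrix has the contracted shape and planted effects shift only positive components of the target pathway", {
  b <- generateCohort(pasSpec(seed = 5, n = 1000, shift = 1))
  rp <- featureValues(rppaData(b))
  expect_identical(dim(rp), c(5L, 1000L))
  expr <- featureValues(expressionData(b))
  tumor <- expr[, tissueType(expressionData(b)) == "tumor"]
  colnames(tumor) <- pairId(expressionData(b))[
    tissueType(expressionData(b)) == "tumor"]
  high <- tumor["G1", colnames(rp)] > median(tumor["G1", colnames(rp)])
  gapPos <- mean(rp["c1", high]) - mean(rp["c1", !high])
  gapNeg <- mean(rp["n1", high]) - mean(rp["n1", !high])
  expect_lt(abs(gapPos - 1), 0.25)
  expect_lt(abs(gapNeg), 0.25)
})

test_that("truth record carries every planted parameter", {
  b <- generateCohort(CohortSpec(nSamples = 100, nMutants = 20, seed = 1))
  truth <- cohortTruth(b)
  expect_true(all(c("seed", "baseline_prob", "planted_or", "latent_rho",
                    "planted_shift", "planted_hr", "censoring_fraction",
                    "censoring_horizon", "ddg_dds_correlation", "ddg_scale",
                    "high_impact_tail_mass", "recurrence_exponent",
                    "pathway_effects") %in% names(truth)))
  expect_identical(truth$planted_hr, c(low = 1, high = 1.9))
})

test_that("degenerate or inconsistent specs are rejected", {
  expect_error(CohortSpec(nSamples = 3, plantedHR = c(a = 1, b = 2)),
               "degenerate")
  expect_error(CohortSpec(nSamples = 100,
                          plantedOR = data.frame(gene_a = "NOPE",
                                                 gene_b = "FERMT1",
                                                 odds_ratio = 0.5)),
               "unknown gene")
  expect_error(CohortSpec(nSamples = 100, censoringFraction = 1),
               "censoringFraction")
  expect_error(CohortSpec(nSamples = 100, baselineProb = 1.2),
               "probabilities")
  expect_error(generateMutantTable(CohortSpec(nSamples = 100,
                                              nMutants = 0)),
               "empty table")
})
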