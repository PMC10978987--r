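# Shared fixture builders. All fixtures are generated in code.

DataFrame <- S4Vectors::DataFrame

# Minimal two-gene cohort spec for planted-effect recovery runs.
pairSpec <- function(seed, n = 5000, or = 0.2, hr = c(low = 1, high = 2),
                     censoring = 0.3, baseline = 0.3) {
  CohortSpec(
    nSamples = n,
    nCancerTypes = 2L,
    geneNames = c("G1", "G2"),
    baselineProb = baseline,
    plantedOR = if (is.null(or)) {
      data.frame(gene_a = character(), gene_b = character(),
                 odds_ratio = numeric())
    } else {
      data.frame(gene_a = "G1", gene_b = "G2", odds_ratio = or)
    },
    plantedShift = setNames(numeric(0), character(0)),
    plantedHR = hr,
    censoringFraction = censoring,
    nMutants = 5L,
    pathways = list(PathwayDefinition("pw", paste0("c", 1:3),
                                      paste0("n", 1:2))),
    pathwayEffects = data.frame(gene = character(), pathway = character(),
                                shift = numeric()),
    nNullComponents = 0L,
    seed = seed)
}

# Tiny cohort for pathway-activity calibration runs: one gene driving one
# five-component pathway, optionally with a planted activation shift.
pasSpec <- function(seed, n = 100, shift = NULL) {
  CohortSpec(
    nSamples = n,
    nCancerTypes = 1L,
    geneNames = c("G1", "G2"),
    baselineProb = 0.3,
    plantedOR = data.frame(gene_a = character(), gene_b = character(),
                           odds_ratio = numeric()),
    plantedShift = setNames(numeric(0), character(0)),
    plantedHR = c(all = 1),
    censoringFraction = 0,
    nMutants = 5L,
    pathways = list(pw = PathwayDefinition("pw", paste0("c", 1:3),
                                           paste0("n", 1:2))),
    pathwayEffects = if (is.null(shift)) {
      data.frame(gene = character(), pathway = character(),
                 shift = numeric())
    } else {
      data.frame(gene = "G1", pathway = "pw", shift = shift)
    },
    nNullComponents = 0L,
    seed = seed)
}

# Build an AlterationMatrix realizing exact 2x2 counts for two genes.
alterationFromCounts <- function(both, aOnly, bOnly, neither,
                                 genes = c("A", "B")) {
  n <- both + aOnly + bOnly + neither
  a <- c(rep(TRUE, both + aOnly), rep(FALSE, bOnly + neither))
  b <- c(rep(TRUE, both), rep(FALSE, aOnly), rep(TRUE, bOnly),
         rep(FALSE, neither))
  m <- rbind(a, b)
  dimnames(m) <- list(genes, sprintf("s%03d", seq_len(n)))
  AlterationMatrix(m)
}

# Independent oracle: two-sided Fisher p as the hypergeometric tail closed
# form, summing all tables (conditional on margins) whose probability does
# not exceed the observed one (standard 1 + 1e-7 relative tolerance).
hyperExactP <- function(both, aOnly, bOnly, neither) {
  r <- both + aOnly      # margin of gene A
  cc <- both + bOnly     # margin of gene B
  n <- both + aOnly + bOnly + neither
  lo <- max(0L, r + cc - n)
  hi <- min(r, cc)
  probs <- dhyper(lo:hi, r, n - r, cc)
  sum(probs[probs <= probs[both - lo + 1L] * (1 + 1e-7)])
}

# Independent product-limit oracle: hand computation of the KM estimate at
# each event time (no Greenwood CI).
kmHand <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  times <- unique(time)
  surv <- numeric(length(times))
  s <- 1
  for (i in seq_along(times)) {
    atRisk <- sum(time >= times[i])
    d <- sum(time == times[i] & event == 1)
    s <- s * (1 - d / atRisk)
    surv[i] <- s
  }
  data.frame(time = times, surv = surv)
}

# Random mutant table with both sign cohorts guaranteed non-degenerate.
randomMutantTable <- function(seed, n = 300) {
  set.seed(seed)
  data.frame(
    protein_id = sample(c("FERMT1", "FERMT2", "FERMT3"), n, replace = TRUE),
    substitution = paste0("A", seq_len(n), "T"),
    ddG = c(runif(4, 0.5, 2), runif(4, -2, -0.5),
            rnorm(n - 8, sd = 1.2)),
    ddS = rnorm(n),
    recurrence = sample(1:6, n, replace = TRUE))
}
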