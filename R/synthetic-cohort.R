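# Synthetic cohort generator. Every table draws from a named substream of
# the root seed, so identical spec + seed reproduces identical bundles and
# adding a table never perturbs existing ones.

#' Default ten cancer-related pathway definitions
#'
#' Ten synthetic signed pathway definitions patterned on the major
#' cancer-associated RPPA pathway panels (apoptosis, cell cycle
#' progression, DNA damage response, EMT, hormone ER/AR, TSC/mTOR, RTK,
#' RAS/MAPK, PI3K/AKT). Component names are synthetic
#' (\code{<pathway>.p1..p3} positive, \code{<pathway>.n1..n2} negative).
#'
#' @return a named list of \code{\link{PathwayDefinition}} objects.
#' @export
defaultPathways <- function() {
  nm <- c("Apoptosis", "CellCycle", "DDR", "EMT", "HormoneER", "HormoneAR",
          "TSC_mTOR", "RTK", "RAS_MAPK", "PI3K_AKT")
  setNames(lapply(nm, function(p) {
    PathwayDefinition(p,
                      positive = paste0(p, ".p", 1:3),
                      negative = paste0(p, ".n", 1:2))
  }), nm)
}

#' Specify a synthetic pan-cancer cohort
#'
#' A \code{CohortSpec} records every planted parameter of a synthetic
#' cohort: per-gene baseline alteration probabilities, pairwise
#' co-alteration odds ratios (induced through a latent Gaussian copula
#' calibrated by bisection so marginals are preserved exactly), expression
#' shifts applied to altered tumor samples, survival hazard ratios over an
#' exponential baseline with uniform censoring, the bivariate
#' \eqn{\Delta\Delta G}/\eqn{\Delta\Delta S} law for the mutant table and a
#' truncated power-law recurrence distribution. The seed fully determines
#' all outputs.
#'
#' The defaults describe the package's reference study conditions: 1000
#' samples, 60 genes (the three kindlins plus mechanochemical interactors),
#' 10 cancer types, kindlin baseline alteration probabilities of
#' 0.29/0.27/0.20 (0.15 elsewhere), mutual exclusivity planted between the
#' kindlin pairs at log2 odds ratios of -2.40, -2.22 and -1.54, a +1 log2
#' expression shift in kindlin-altered tumors, a high/low survival split
#' with hazard ratio 1.9, 30\% censoring, a -0.75
#' \eqn{\Delta\Delta G}-\eqn{\Delta\Delta S} correlation and a
#' \eqn{\Delta\Delta G} scale placing 10\% of mutants beyond the
#' high-impact screen at \eqn{\pm}1.24 kJ/mol.
#'
#' @param nSamples number of tumor samples.
#' @param nCancerTypes number of cancer-type labels.
#' @param geneNames unique gene identifiers.
#' @param baselineProb per-gene baseline alteration probability in (0,1);
#'   recycled and named after \code{geneNames} if unnamed.
#' @param plantedOR data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{odds_ratio} (> 0; 1 = independence).
#' @param plantedShift named numeric of log2 expression shifts applied to
#'   altered tumor samples.
#' @param plantedHR named numeric of hazard ratios, one per survival group;
#'   samples are assigned to groups in equal blocks.
#' @param censoringFraction target fraction of censored samples in [0,1);
#'   censoring is independent uniform on [0, T_max] with T_max calibrated
#'   to this fraction.
#' @param baselineHazard exponential baseline event rate per time unit.
#' @param ddgDdsCorrelation planted correlation of the bivariate normal
#'   (\code{ddG}, \code{ddS}) law, in [-1, 1].
#' @param ddgScale standard deviation of \code{ddG} in kJ/mol.
#' @param recurrenceExponent power-law exponent of the recurrence law
#'   (probability of count k proportional to k^-exponent).
#' @param recurrenceMax truncation point of the recurrence law.
#' @param nMutants number of mutant records.
#' @param frameshiftFraction fraction of mutant records flagged as
#'   frameshifts (these lack \code{ddS}).
#' @param expressionNoiseSd Gaussian noise SD of expression values.
#' @param pathways list of \code{\link{PathwayDefinition}}s for the RPPA
#'   table.
#' @param pathwayEffects data.frame with columns \code{gene},
#'   \code{pathway}, \code{shift}: positive-regulator components of
#'   \code{pathway} are shifted by \code{shift} (in component SD units) in
#'   the gene-expression-high sample group.
#' @param nNullComponents extra RPPA components with no planted dependence.
#' @param seed integer root seed.
#'
#' @return a validated \code{CohortSpec}.
#' @seealso \code{\link{generateCohort}}
#' @examples
#' spec <- CohortSpec(nSamples = 200, seed = 7)
#' spec
#' @export
CohortSpec <- function(nSamples = 1000L,
                       nCancerTypes = 10L,
                       geneNames = defaultGeneNames(),
                       baselineProb = defaultBaselineProb(geneNames),
                       plantedOR = defaultPlantedOR(),
                       plantedShift = c(FERMT1 = 1, FERMT2 = 1, FERMT3 = 1),
                       plantedHR = c(low = 1, high = 1.9),
                       censoringFraction = 0.3,
                       baselineHazard = 0.1,
                       ddgDdsCorrelation = -0.75,
                       ddgScale = 1.24 / qnorm(0.95),
                       recurrenceExponent = 2,
                       recurrenceMax = 50L,
                       nMutants = 500L,
                       frameshiftFraction = 0.05,
                       expressionNoiseSd = 1,
                       pathways = defaultPathways(),
                       pathwayEffects = defaultPathwayEffects(),
                       nNullComponents = 10L,
                       seed = 1L) {
  if (is.null(names(baselineProb))) {
    baselineProb <- setNames(rep_len(baselineProb, length(geneNames)),
                             geneNames)
  }
  new("CohortSpec",
      nSamples = as.integer(nSamples),
      nCancerTypes = as.integer(nCancerTypes),
      geneNames = as.character(geneNames),
      baselineProb = baselineProb[geneNames],
      plantedOR = as.data.frame(plantedOR),
      plantedShift = plantedShift,
      plantedHR = plantedHR,
      censoringFraction = censoringFraction,
      baselineHazard = baselineHazard,
      ddgDdsCorrelation = ddgDdsCorrelation,
      ddgScale = ddgScale,
      recurrenceExponent = recurrenceExponent,
      recurrenceMax = as.integer(recurrenceMax),
      nMutants = as.integer(nMutants),
      frameshiftFraction = frameshiftFraction,
      expressionNoiseSd = expressionNoiseSd,
      pathways = pathways,
      pathwayEffects = as.data.frame(pathwayEffects),
      nNullComponents = as.integer(nNullComponents),
      seed = as.integer(seed))
}

#' @rdname CohortSpec
#' @export
defaultGeneNames <- function() {
  interactors <- c("SKIC3", "SKIC2", "CTNNB1", "PFKM", "EXOSC10", "ILK",
                   "ACTN1", "RAC1", "DNMT1", "TP53", "TMX4", "ITGB1",
                   "YAP1", "SRC", "MYC", "AKT1", "EZR", "HK1", "NOTCH1",
                   "STAT3", "GSK3B", "FOXO3", "BCL2", "EP300", "DNMT3A",
                   "CEBPA", "LATS1", "PIK3CA", "CREBBP", "TLN1", "VCL",
                   "PXN", "FAK1", "RHOA", "CDC42", "MAPK1", "EGFR",
                   "TGFB1", "VEGFA", "SNAI1", "ZEB1", "CDH1", "VIM")
  c("FERMT1", "FERMT2", "FERMT3", interactors,
    sprintf("MCP%02d", seq_len(60L - 3L - length(interactors))))
}

#' @rdname CohortSpec
#' @export
defaultBaselineProb <- function(geneNames = defaultGeneNames()) {
  p <- setNames(rep(0.15, length(geneNames)), geneNames)
  p[intersect(c("FERMT1", "FERMT2", "FERMT3"), geneNames)] <-
    c(FERMT1 = 0.29, FERMT2 = 0.27,
      FERMT3 = 0.20)[intersect(c("FERMT1", "FERMT2", "FERMT3"), geneNames)]
  p
}

#' @rdname CohortSpec
#' @export
defaultPlantedOR <- function() {
  # Mutual exclusivity across all three kindlin pairs plus one partner
  # co-occurrence. A fully pairwise-exclusive triangle is bounded by joint
  # realisability of the latent Gaussian copula at these marginals; the
  # planted magnitudes are the strongest uniform scaling of the
  # log2 odds ratios -3/-2.77/-1.93 that remains jointly realisable with
  # comfortable margin (80%).
  data.frame(
    gene_a = c("FERMT1", "FERMT2", "FERMT1", "FERMT2"),
    gene_b = c("FERMT2", "FERMT3", "FERMT3", "CTNNB1"),
    odds_ratio = c(2^-2.40, 2^-2.22, 2^-1.54, 3))
}

#' @rdname CohortSpec
#' @export
defaultPathwayEffects <- function() {
  data.frame(gene = c("FERMT2", "FERMT3", "FERMT1"),
             pathway = c("EMT", "Apoptosis", "DDR"),
             shift = c(1, 1, -1))
}

## ---------------------------------------------------------------------------
## Latent Gaussian copula calibration
## ---------------------------------------------------------------------------

# P(X1 > z1, X2 > z2) for standard bivariate normal with correlation rho.
.orthantProb <- function(z1, z2, rho) {
  if (abs(rho) < 1e-12) {
    return(pnorm(z1, lower.tail = FALSE) * pnorm(z2, lower.tail = FALSE))
  }
  s <- sqrt(1 - rho^2)
  f <- function(x) dnorm(x) * pnorm((z2 - rho * x) / s, lower.tail = FALSE)
  integrate(f, z1, Inf, rel.tol = 1e-10, abs.tol = 1e-12)$value
}

# Odds ratio of the thresholded pair given marginals p1, p2 and latent rho.
.orFromRho <- function(p1, p2, rho) {
  z1 <- qnorm(1 - p1); z2 <- qnorm(1 - p2)
  p11 <- .orthantProb(z1, z2, rho)
  p10 <- p1 - p11; p01 <- p2 - p11; p00 <- 1 - p1 - p2 + p11
  (p11 * p00) / (p10 * p01)
}

# Bisection for the latent correlation that yields the target odds ratio.
# OR is monotone increasing in rho, so plain bisection suffices.
.latentRho <- function(p1, p2, targetOR, tol = 1e-9) {
  if (abs(log(targetOR)) < 1e-12) return(0)
  lo <- -0.9999; hi <- 0.9999
  target <- log(targetOR)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    val <- log(.orFromRho(p1, p2, mid))
    if (abs(val - target) < tol) return(mid)
    if (val < target) lo <- mid else hi <- mid
  }
  mid
}

## ---------------------------------------------------------------------------
## Table generators
## ---------------------------------------------------------------------------

.generateAlterations <- function(spec) {
  set.seed(.substreamSeed(spec@seed, "alterations"))
  n <- spec@nSamples
  genes <- spec@geneNames
  p <- spec@baselineProb
  G <- length(genes)
  R <- diag(G)
  dimnames(R) <- list(genes, genes)
  latent <- numeric(0)
  if (nrow(spec@plantedOR)) {
    for (i in seq_len(nrow(spec@plantedOR))) {
      a <- spec@plantedOR$gene_a[i]; b <- spec@plantedOR$gene_b[i]
      rho <- .latentRho(p[[a]], p[[b]], spec@plantedOR$odds_ratio[i])
      R[a, b] <- R[b, a] <- rho
      latent[paste(a, b, sep = ":")] <- rho
    }
  }
  L <- tryCatch(chol(R), error = function(e) {
    stop("planted odds-ratio structure is not jointly realisable ",
         "(latent correlation matrix is not positive definite)",
         call. = FALSE)
  })
  Z <- matrix(rnorm(n * G), n, G) %*% L
  thr <- qnorm(1 - p)
  altered <- t(sweep(Z, 2, thr, ">"))
  rownames(altered) <- genes
  colnames(altered) <- sprintf("S%04d", seq_len(n))
  ct <- sample(sprintf("CT%02d", seq_len(spec@nCancerTypes)), n,
               replace = TRUE)
  list(table = AlterationMatrix(altered, cancerType = ct),
       latentRho = latent)
}

.generateExpression <- function(spec, alterations) {
  set.seed(.substreamSeed(spec@seed, "expression"))
  genes <- spec@geneNames
  n <- spec@nSamples
  samples <- colnames(alterations)
  base <- setNames(runif(length(genes), 2, 8), genes)
  noise <- spec@expressionNoiseSd
  normal <- matrix(rnorm(length(genes) * n, mean = base, sd = noise),
                   length(genes), n, dimnames = list(genes, NULL))
  shift <- setNames(numeric(length(genes)), genes)
  shift[names(spec@plantedShift)] <- spec@plantedShift
  st <- alteredStatus(alterations)
  tumor <- matrix(rnorm(length(genes) * n, mean = base, sd = noise),
                  length(genes), n, dimnames = list(genes, NULL)) +
    shift * st
  values <- cbind(tumor, normal)
  colnames(values) <- c(paste0(samples, "_T"), paste0(samples, "_N"))
  FeatureMatrix(values,
                pairId = c(samples, samples),
                tissue = rep(c("tumor", "normal"), each = n),
                valueScale = "log2(TPM+1)")
}

# Horizon of the uniform censoring law giving the target expected
# censoring fraction under exponential event times with the given rates.
.censoringHorizon <- function(rates, fraction) {
  if (fraction <= 0) return(Inf)
  f <- function(Tm) mean((1 - exp(-rates * Tm)) / (rates * Tm)) - fraction
  uniroot(f, lower = 1e-8, upper = 1e8, tol = 1e-10)$root
}

.generateSurvival <- function(spec) {
  set.seed(.substreamSeed(spec@seed, "survival"))
  n <- spec@nSamples
  groups <- rep_len(names(spec@plantedHR), n)
  rate <- spec@baselineHazard * spec@plantedHR[groups]
  x <- rexp(n, rate)
  horizon <- .censoringHorizon(rate, spec@censoringFraction)
  if (is.finite(horizon)) {
    cens <- runif(n, 0, horizon)
    time <- pmin(x, cens)
    event <- as.integer(x <= cens)
  } else {
    time <- x
    event <- rep(1L, n)
  }
  list(table = SurvivalData(sprintf("S%04d", seq_len(n)), time, event,
                            groups),
       horizon = horizon)
}

#' Generate a synthetic mutant stability table
#'
#' Draws (\code{ddG}, \code{ddS}) from a bivariate normal with the planted
#' correlation (\code{ddG} SD = \code{ddgScale} kJ/mol, \code{ddS} SD = 1),
#' recurrence counts from a power law truncated at
#' \code{recurrenceMax}, uniform SIFT scores, and synthetic
#' dimer/trimer binding-affinity inputs. A fraction of records are flagged
#' as frameshifts and lack \code{ddS}. The theoretical tail mass beyond
#' \eqn{|\Delta\Delta G| \ge 1.24} kJ/mol is recorded alongside.
#'
#' @param spec a \code{\link{CohortSpec}}.
#' @return a \code{\link{MutantTable}}.
#' @examples
#' mt <- generateMutantTable(CohortSpec(nSamples = 100, nMutants = 50,
#'                                      seed = 3))
#' head(as.data.frame(mt))
#' @export
generateMutantTable <- function(spec) {
  validObject(spec)
  if (spec@nMutants < 1L) {
    stop("empty table: at least one mutant must be requested", call. = FALSE)
  }
  set.seed(.substreamSeed(spec@seed, "mutants"))
  n <- spec@nMutants
  rho <- spec@ddgDdsCorrelation
  s <- spec@ddgScale
  z1 <- rnorm(n); z2 <- rnorm(n)
  ddG <- s * z1
  ddS <- rho * z1 + sqrt(1 - rho^2) * z2
  k <- seq_len(spec@recurrenceMax)
  recurrence <- sample(k, n, replace = TRUE,
                       prob = k^(-spec@recurrenceExponent))
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  pos <- sample(5:650, n, replace = TRUE)
  fs <- runif(n) < spec@frameshiftFraction
  substitution <- ifelse(
    fs,
    paste0(sample(aa, n, replace = TRUE), pos, "fs"),
    paste0(sample(aa, n, replace = TRUE), pos, sample(aa, n, replace = TRUE)))
  ddS[fs] <- NA_real_
  proteins <- intersect(c("FERMT1", "FERMT2", "FERMT3"), spec@geneNames)
  if (!length(proteins)) proteins <- spec@geneNames[1]
  baDimerWT <- rnorm(n, -10, 2)
  baTrimerWT <- rnorm(n, -12, 2)
  MutantTable(data.frame(
    protein_id = sample(proteins, n, replace = TRUE),
    substitution = substitution,
    ddG = ddG,
    ddS = ddS,
    recurrence = as.integer(recurrence),
    sift_score = runif(n),
    ba_dimer_wt = baDimerWT,
    ba_dimer_mut = baDimerWT + rnorm(n, 0, 1),
    ba_trimer_wt = baTrimerWT,
    ba_trimer_mut = baTrimerWT + rnorm(n, 0, 1),
    cancer_type = sample(sprintf("CT%02d", seq_len(spec@nCancerTypes)), n,
                         replace = TRUE),
    stringsAsFactors = FALSE))
}

#' Generate a synthetic RPPA component matrix
#'
#' Components are standard normal per sample. For each planted
#' (gene, pathway, shift) effect, the positive-regulator components of the
#' pathway are shifted by \code{shift} component-SD units in the
#' gene-expression-high sample group (tumor expression above the median).
#' Null pathways and the extra null components carry no dependence on any
#' gene.
#'
#' @param spec a \code{\link{CohortSpec}}.
#' @param expression the cohort's paired expression \code{FeatureMatrix}
#'   (only tumor columns are used for the high/low split).
#' @return a \code{\link{FeatureMatrix}} of components x samples with
#'   value scale \code{"rppa"}.
#' @export
generateRPPA <- function(spec, expression) {
  validObject(spec)
  set.seed(.substreamSeed(spec@seed, "rppa"))
  comps <- unique(unlist(lapply(spec@pathways, function(p) {
    c(positiveComponents(p), negativeComponents(p))
  })))
  if (spec@nNullComponents > 0L) {
    comps <- c(comps, sprintf("null.c%02d", seq_len(spec@nNullComponents)))
  }
  tumorCols <- which(tissueType(expression) == "tumor")
  samples <- pairId(expression)[tumorCols]
  n <- length(samples)
  values <- matrix(rnorm(length(comps) * n), length(comps), n,
                   dimnames = list(comps, samples))
  expr <- featureValues(expression)[, tumorCols, drop = FALSE]
  colnames(expr) <- samples
  pe <- spec@pathwayEffects
  pwNames <- pathwayNames(spec@pathways)
  for (i in seq_len(nrow(pe))) {
    pw <- spec@pathways[[match(pe$pathway[i], pwNames)]]
    target <- positiveComponents(pw)
    if (!all(target %in% comps)) {
      stop("unknown component: pathway '", pe$pathway[i],
           "' references components missing from the matrix", call. = FALSE)
    }
    g <- expr[pe$gene[i], ]
    high <- g > median(g)
    values[target, high] <- values[target, high] + pe$shift[i]
  }
  FeatureMatrix(values, valueScale = "rppa")
}

#' Generate a full synthetic cohort
#'
#' Produces every table of a \code{\link{CohortBundle}} from one
#' \code{\link{CohortSpec}}: the alteration matrix (latent Gaussian copula
#' thresholded to the per-gene marginals, latent correlations calibrated to
#' the planted odds ratios by bisection), paired tumor/normal expression
#' with planted log2 shifts in altered tumors, exponential survival scaled
#' by the planted hazard ratios with independent uniform censoring, the
#' mutant stability table and the RPPA component matrix. All planted
#' parameters (including derived quantities such as the latent
#' correlations, censoring horizon and high-impact tail mass) are recorded
#' in the truth slot.
#'
#' @param spec a \code{\link{CohortSpec}}; identical spec and seed
#'   reproduce identical bundles.
#' @return a \code{\link{CohortBundle}}.
#' @examples
#' bundle <- generateCohort(CohortSpec(nSamples = 100, nMutants = 50,
#'                                     seed = 7))
#' bundle
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  alt <- .generateAlterations(spec)
  expr <- .generateExpression(spec, alt$table)
  surv <- .generateSurvival(spec)
  mutants <- generateMutantTable(spec)
  rppa <- generateRPPA(spec, expr)
  truth <- list(
    seed = spec@seed,
    n_samples = spec@nSamples,
    n_cancer_types = spec@nCancerTypes,
    baseline_prob = spec@baselineProb,
    planted_or = spec@plantedOR,
    latent_rho = alt$latentRho,
    planted_shift = spec@plantedShift,
    planted_hr = spec@plantedHR,
    baseline_hazard = spec@baselineHazard,
    censoring_fraction = spec@censoringFraction,
    censoring_horizon = surv$horizon,
    ddg_dds_correlation = spec@ddgDdsCorrelation,
    ddg_scale = spec@ddgScale,
    high_impact_tail_mass = 2 * pnorm(-1.24 / spec@ddgScale),
    recurrence_exponent = spec@recurrenceExponent,
    recurrence_max = spec@recurrenceMax,
    frameshift_fraction = spec@frameshiftFraction,
    pathway_effects = spec@pathwayEffects)
  new("CohortBundle", alterations = alt$table, expression = expr,
      survival = surv$table, rppa = rppa, mutants = mutants,
      truth = truth, spec = spec)
}
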