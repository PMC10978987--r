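# End-to-end pipeline steps. Each step reads/writes plain TSV and appends
# provenance (seed, test variants, FDR family) to a run manifest in the
# output directory. The command-line interface in inst/cli wraps these.

.appendManifest <- function(dir, step, fields) {
  lines <- c(sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                     step),
             sprintf("  %s = %s", names(fields),
                     vapply(fields, function(f) paste(format(f),
                                                      collapse = ","),
                            character(1))))
  cat(lines, file = file.path(dir, "run-manifest.txt"), sep = "\n",
      append = TRUE)
  cat("\n", file = file.path(dir, "run-manifest.txt"), append = TRUE)
  invisible(NULL)
}

#' Pipeline step: simulate a synthetic cohort
#'
#' Generates a cohort from a spec (or YAML config) and writes every table
#' plus the truth record and run manifest to \code{outDir}.
#'
#' @param outDir output directory.
#' @param spec a \code{\link{CohortSpec}}; defaults to the reference study
#'   conditions.
#' @param config optional YAML config path (overrides \code{spec}).
#' @param seed optional root-seed override.
#' @return the generated \code{\link{CohortBundle}}, invisibly.
#' @export
runSimulate <- function(outDir, spec = CohortSpec(), config = NULL,
                        seed = NULL) {
  if (!is.null(config)) spec <- readCohortSpec(config)
  if (!is.null(seed)) spec@seed <- as.integer(seed)
  bundle <- generateCohort(spec)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeCohort(bundle, outDir)
  .appendManifest(outDir, "simulate",
                  list(seed = spec@seed, n_samples = spec@nSamples,
                       n_genes = length(spec@geneNames),
                       n_cancer_types = spec@nCancerTypes))
  invisible(bundle)
}

#' Pipeline step: mutant stability landscape classification
#'
#' Reads a mutant table, assigns quadrants, five-category magnitudes, the
#' high-impact screen and deleteriousness calls, fits the
#' stability-flexibility trend and writes a classification TSV plus trend
#' report.
#'
#' @param mutants a \code{\link{MutantTable}} or path to a mutant TSV.
#' @param outDir output directory.
#' @param cutoff high-impact screen threshold (kJ/mol).
#' @return list with \code{classification}, \code{thresholds} and
#'   \code{trend}, invisibly.
#' @export
runStability <- function(mutants, outDir, cutoff = 1.24) {
  mt <- if (is.character(mutants)) readMutantTable(mutants) else
    .asMutantTable(mutants)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  mag <- classifyMagnitude(mt)
  key <- paste(mt$protein_id, mt$substitution, mt$ddG)
  magKey <- paste(mag$categories$protein_id, mag$categories$substitution,
                  mag$categories$ddG)
  out <- as.data.frame(mt)
  out$quadrant <- as.character(assignQuadrant(mt$ddG, mt$ddS))
  out$category <- as.character(mag$categories$category[match(key, magKey)])
  out$sign <- as.character(mag$categories$sign[match(key, magKey)])
  out$high_impact <- !is.na(mt$ddG) & abs(mt$ddG) >= cutoff
  out$function_call <- if ("sift_score" %in% colnames(mt)) {
    as.character(classifyFunction(mt$sift_score))
  } else {
    "unclassified"
  }
  trend <- stabilityFlexibilityTrend(mt)
  .writeTsv(out, file.path(outDir, "stability_classification.tsv"))
  .writeTsv(data.frame(r = trend$r, p = trend$p, slope = trend$slope,
                       intercept = trend$intercept, n = trend$n),
            file.path(outDir, "stability_trend.tsv"))
  .appendManifest(outDir, "stability",
                  list(cutoff = cutoff,
                       average_low = mag$thresholds@averageLow,
                       average_high = mag$thresholds@averageHigh,
                       n_zero_excluded = mag$nZeroExcluded))
  invisible(list(classification = out, thresholds = mag$thresholds,
                 trend = trend))
}

#' Pipeline step: co-alteration analysis
#'
#' Computes partner co-alteration frequencies around an anchor gene, mean
#' co-alteration dynamics (per GMT gene set when given, otherwise over all
#' partners), and mutual-exclusivity odds ratios of the anchor against
#' each partner.
#'
#' @param alterations an \code{\link{AlterationMatrix}} or path to a
#'   binary-matrix TSV.
#' @param anchor anchor gene.
#' @param outDir output directory.
#' @param genesets optional path to a GMT file of gene sets.
#' @return list with \code{frequencies}, \code{dynamics} and
#'   \code{exclusivity}, invisibly.
#' @export
runCoalter <- function(alterations, anchor, outDir, genesets = NULL) {
  am <- if (is.character(alterations)) readAlterationMatrix(alterations)
        else alterations
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  freqs <- coalterationFrequencies(am, anchor)
  sets <- if (is.null(genesets)) {
    list(all_partners = freqs$partner)
  } else {
    readGeneSets(genesets)
  }
  dyn <- do.call(rbind, lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], freqs$partner)
    if (!length(members)) return(NULL)
    meanCoalterationDynamics(freqs[freqs$partner %in% members, ], nm)
  }))
  excl <- mutualExclusivityAll(am, c(anchor, freqs$partner))
  excl <- excl[excl$gene_a == anchor | excl$gene_b == anchor, ]
  excl$q <- .bh(excl$p)
  excl$call <- .exclusivityCall(excl$log2_odds_ratio, excl$q)
  .writeTsv(freqs, file.path(outDir, "coalteration_frequencies.tsv"))
  .writeTsv(dyn, file.path(outDir, "coalteration_dynamics.tsv"))
  .writeTsv(excl, file.path(outDir, "mutual_exclusivity.tsv"))
  .appendManifest(outDir, "coalter",
                  list(anchor = anchor, test = "fisher_exact_two_sided",
                       fdr = "BH", n_partners = nrow(freqs)))
  invisible(list(frequencies = freqs, dynamics = dyn, exclusivity = excl))
}

#' Pipeline step: pathway activity calls
#'
#' Normalizes RPPA components, scores every pathway, tests each
#' (gene, pathway) median-split association per cancer type and summarizes
#' global activation/inhibition percentages.
#'
#' @param rppa a \code{\link{FeatureMatrix}} or path to a component TSV.
#' @param pathways list of \code{\link{PathwayDefinition}}s or path to a
#'   signed-membership TSV.
#' @param expression a \code{\link{FeatureMatrix}} or path to an
#'   expression TSV.
#' @param genes genes driving the median splits.
#' @param outDir output directory.
#' @param cancerType optional named per-sample cancer-type labels; when
#'   supplied, calls are per cancer type and Eq-8-style global percentages
#'   are written.
#' @return list with \code{pas}, \code{calls} and (when stratified)
#'   \code{global}, invisibly.
#' @export
runPas <- function(rppa, pathways, expression, genes, outDir,
                   cancerType = NULL) {
  if (is.character(rppa)) rppa <- readFeatureMatrix(rppa)
  if (is.character(pathways)) pathways <- readPathwayDefinitions(pathways)
  if (is.character(expression)) expression <- readFeatureMatrix(expression)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  norm <- normalizeComponents(rppa)
  pas <- pathwayScores(norm, pathways)
  calls <- pathwayAssociation(pas, expression, genes,
                              cancerType = cancerType)
  .writeTsv(data.frame(sample_id = rownames(pas), pas,
                       check.names = FALSE),
            file.path(outDir, "pas_scores.tsv"))
  .writeTsv(calls, file.path(outDir, "pathway_calls.tsv"))
  global <- NULL
  if (!is.null(cancerType)) {
    global <- globalPercentage(calls, length(unique(cancerType)))
    .writeTsv(global, file.path(outDir, "pathway_global_percentage.tsv"))
  }
  .appendManifest(outDir, "pas",
                  list(t_test = "welch_two_sided", fdr = "BH",
                       split = "median_ties_low",
                       n_pathways = length(pathways),
                       n_genes = length(genes)))
  invisible(list(pas = pas, calls = calls, global = global))
}

#' Pipeline step: survival analysis
#'
#' Splits samples into high/low groups on a feature (median or quartile
#' scheme) or uses the table's own groups, then computes Kaplan-Meier
#' curves with 95\% confidence intervals, the log-rank test and the Cox
#' hazard ratio.
#'
#' @param survival a \code{\link{SurvivalData}} or path to a survival TSV.
#' @param outDir output directory.
#' @param expression optional \code{\link{FeatureMatrix}} or TSV path; with
#'   \code{feature}, drives the group split.
#' @param feature feature to split on.
#' @param scheme \code{"median"} or \code{"quartile"}.
#' @return list with \code{km}, \code{logrank} and \code{cox}, invisibly.
#' @export
runSurvive <- function(survival, outDir, expression = NULL, feature = NULL,
                       scheme = "quartile") {
  if (is.character(survival)) survival <- readSurvivalTable(survival)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  groups <- NULL
  if (!is.null(expression) && !is.null(feature)) {
    if (is.character(expression)) expression <- readFeatureMatrix(expression)
    groups <- splitGroups(expression, feature, scheme)
  }
  km <- kmCurves(survival, groups)
  lr <- logrankTest(survival, groups)
  cox <- coxHazardRatio(survival, groups)
  .writeTsv(km, file.path(outDir, "survival_km.tsv"))
  .writeTsv(data.frame(logrank_chisq = lr$chisq, logrank_df = lr$df,
                       logrank_p = lr$p, hazard_ratio = cox$hr,
                       hr_ci_lower = cox$ci_lower,
                       hr_ci_upper = cox$ci_upper,
                       cox_coef = cox$coef, worse_group = cox$worse_group),
            file.path(outDir, "survival_report.tsv"))
  .appendManifest(outDir, "survive",
                  list(scheme = if (is.null(groups)) "table_groups"
                       else scheme,
                       feature = if (is.null(feature)) "NA" else feature,
                       cox_ties = "breslow", ci = "log-log 95%"))
  invisible(list(km = km, logrank = lr, cox = cox))
}
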