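# S4 data containers. Matrix-like omics tables extend SummarizedExperiment;
# record-style tables extend S4Vectors DFrame so they keep DataFrame
# semantics (subsetting, show) while enforcing their column contracts.

## ---------------------------------------------------------------------------
## AlterationMatrix
## ---------------------------------------------------------------------------

#' Sample-by-gene alteration status container
#'
#' An \code{AlterationMatrix} stores a logical genes x samples alteration
#' matrix as a \code{SummarizedExperiment} with one assay named
#' \code{"altered"} and a per-sample \code{cancer_type} column in
#' \code{colData}. It is the substrate for co-alteration, mutual-exclusivity
#' and altered-versus-unaltered group splits.
#'
#' @param altered logical (or 0/1) genes x samples matrix with unique row
#'   and column names.
#' @param cancerType character vector of per-sample cancer-type labels
#'   (recycled if length 1); defaults to \code{"pan"}.
#' @param x an \code{AlterationMatrix}.
#'
#' @return \code{AlterationMatrix()} returns the container;
#'   \code{alteredStatus()} the logical matrix; \code{cancerType()} the
#'   per-sample label vector.
#'
#' @examples
#' m <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2,
#'             dimnames = list(c("FERMT1", "ILK"), c("s1", "s2")))
#' am <- AlterationMatrix(m)
#' alteredStatus(am)
#' @aliases alteredStatus cancerType
#' @export
AlterationMatrix <- function(altered, cancerType = "pan") {
  altered <- as.matrix(altered)
  storage.mode(altered) <- "logical"
  if (is.null(rownames(altered))) {
    rownames(altered) <- sprintf("g%03d", seq_len(nrow(altered)))
  }
  if (is.null(colnames(altered))) {
    colnames(altered) <- sprintf("S%04d", seq_len(ncol(altered)))
  }
  cancerType <- rep_len(as.character(cancerType), ncol(altered))
  se <- SummarizedExperiment(
    assays = list(altered = altered),
    colData = DataFrame(cancer_type = cancerType,
                        row.names = colnames(altered)))
  new("AlterationMatrix", se)
}

#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass AlterationMatrix
setClass("AlterationMatrix", contains = "SummarizedExperiment")

setValidity("AlterationMatrix", function(object) {
  msg <- character()
  if (!"altered" %in% assayNames(object)) {
    msg <- c(msg, "assay 'altered' is required")
  } else if (!is.logical(assay(object, "altered"))) {
    msg <- c(msg, "assay 'altered' must be logical")
  } else if (anyNA(assay(object, "altered"))) {
    msg <- c(msg, "alteration status must be defined for every (sample, gene)")
  }
  if (!"cancer_type" %in% colnames(colData(object))) {
    msg <- c(msg, "colData column 'cancer_type' is required")
  }
  if (anyDuplicated(colnames(object))) {
    msg <- c(msg, "sample identifiers must be unique")
  }
  if (anyDuplicated(rownames(object))) {
    msg <- c(msg, "gene identifiers must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname AlterationMatrix
#' @export
setMethod("alteredStatus", "AlterationMatrix",
          function(x) assay(x, "altered"))

#' @rdname AlterationMatrix
#' @export
setMethod("cancerType", "AlterationMatrix",
          function(x) setNames(colData(x)$cancer_type, colnames(x)))

setMethod("show", "AlterationMatrix", function(object) {
  st <- assay(object, "altered")
  cat("AlterationMatrix with", nrow(object), "genes x", ncol(object),
      "samples\n")
  cat("  altered cells:", sum(st), sprintf("(%.1f%%)", 100 * mean(st)), "\n")
  cat("  cancer types:", length(unique(colData(object)$cancer_type)), "\n")
})

## ---------------------------------------------------------------------------
## FeatureMatrix
## ---------------------------------------------------------------------------

#' Sample-by-feature continuous value container
#'
#' A \code{FeatureMatrix} holds continuous omics values (expression on the
#' log2(TPM+1) scale, methylation beta, phospho/protein TMT ratios, RPPA
#' component levels) as a \code{SummarizedExperiment} with one assay named
#' \code{"values"}. Optional \code{pair_id}/\code{tissue} columns in
#' \code{colData} record tumor/normal pairing: every non-missing pairing key
#' must match exactly one tumor and one normal sample. The value-scale tag
#' lives in \code{metadata(x)$value_scale}.
#'
#' @param values numeric features x samples matrix.
#' @param pairId optional per-sample pairing key (NA for unpaired samples).
#' @param tissue optional per-sample tissue label, \code{"tumor"} or
#'   \code{"normal"}.
#' @param valueScale scale tag, e.g. \code{"log2(TPM+1)"}, \code{"beta"},
#'   \code{"ratio"}, \code{"rppa"}.
#' @param x a \code{FeatureMatrix}.
#'
#' @return \code{FeatureMatrix()} returns the container; accessors return
#'   the value matrix, pairing keys, tissue labels and scale tag.
#'
#' @examples
#' v <- matrix(rnorm(4), 2, dimnames = list(c("f1", "f2"), c("a", "b")))
#' fm <- FeatureMatrix(v, valueScale = "log2(TPM+1)")
#' valueScale(fm)
#' @aliases featureValues pairId tissueType valueScale
#' @export
FeatureMatrix <- function(values, pairId = NULL, tissue = NULL,
                          valueScale = "log2(TPM+1)") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("f%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("S%04d", seq_len(ncol(values)))
  }
  cd <- DataFrame(row.names = colnames(values))
  if (!is.null(pairId)) cd$pair_id <- rep_len(as.character(pairId),
                                              ncol(values))
  if (!is.null(tissue)) cd$tissue <- rep_len(as.character(tissue),
                                             ncol(values))
  se <- SummarizedExperiment(assays = list(values = values), colData = cd)
  metadata(se)$value_scale <- valueScale
  new("FeatureMatrix", se)
}

#' @exportClass FeatureMatrix
setClass("FeatureMatrix", contains = "SummarizedExperiment")

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (!"values" %in% assayNames(object)) {
    msg <- c(msg, "assay 'values' is required")
  }
  cd <- colData(object)
  if ("pair_id" %in% colnames(cd)) {
    if (!"tissue" %in% colnames(cd)) {
      msg <- c(msg, "'pair_id' requires a 'tissue' column")
    } else {
      keep <- !is.na(cd$pair_id)
      if (any(keep)) {
        if (!all(cd$tissue[keep] %in% c("tumor", "normal"))) {
          msg <- c(msg, "tissue labels must be 'tumor' or 'normal'")
        } else {
          tab <- table(cd$pair_id[keep], cd$tissue[keep])
          if (!all(tab %in% 0:1) ||
              any(rowSums(tab) > 0 & (tab[, "tumor"] != tab[, "normal"]))) {
            msg <- c(msg,
              "each pairing key must match exactly one tumor and one normal")
          }
        }
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' @rdname FeatureMatrix
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) assay(x, "values"))

#' @rdname FeatureMatrix
#' @export
setMethod("pairId", "FeatureMatrix", function(x) {
  cd <- colData(x)
  if ("pair_id" %in% colnames(cd)) setNames(cd$pair_id, colnames(x)) else NULL
})

#' @rdname FeatureMatrix
#' @export
setMethod("tissueType", "FeatureMatrix", function(x) {
  cd <- colData(x)
  if ("tissue" %in% colnames(cd)) setNames(cd$tissue, colnames(x)) else NULL
})

#' @rdname FeatureMatrix
#' @export
setMethod("valueScale", "FeatureMatrix",
          function(x) metadata(x)$value_scale)

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix with", nrow(object), "features x", ncol(object),
      "samples\n")
  cat("  scale:", metadata(object)$value_scale, "\n")
  if ("pair_id" %in% colnames(colData(object))) {
    np <- sum(!is.na(unique(colData(object)$pair_id)))
    cat("  tumor/normal pairs:", np, "\n")
  }
})

## ---------------------------------------------------------------------------
## SurvivalData
## ---------------------------------------------------------------------------

#' Per-sample time-to-event table
#'
#' A \code{DataFrame} subclass with required columns \code{sample}
#' (unique identifiers), \code{time} (nonnegative follow-up), \code{event}
#' (1 = event observed, 0 = censored) and \code{group} (stratum label).
#'
#' @param sample character sample identifiers (unique).
#' @param time nonnegative follow-up times.
#' @param event 0/1 (or logical) event indicator.
#' @param group optional group labels; defaults to \code{"all"}.
#' @return a \code{SurvivalData} object.
#' @examples
#' SurvivalData(c("s1", "s2"), time = c(5, 10), event = c(1, 0))
#' @export
SurvivalData <- function(sample, time, event, group = "all") {
  new("SurvivalData", DataFrame(
    sample = as.character(sample),
    time = as.numeric(time),
    event = as.integer(event),
    group = rep_len(as.character(group), length(sample))))
}

#' @importClassesFrom S4Vectors DFrame
#' @exportClass SurvivalData
setClass("SurvivalData", contains = "DFrame")

setValidity("SurvivalData", function(object) {
  req <- c("sample", "time", "event", "group")
  if (!all(req %in% colnames(object))) {
    return(paste("required columns:", paste(req, collapse = ", ")))
  }
  msg <- character()
  if (anyDuplicated(object$sample)) msg <- c(msg, "sample ids must be unique")
  if (any(!is.finite(object$time)) || any(object$time < 0)) {
    msg <- c(msg, "times must be finite and nonnegative")
  }
  if (!all(object$event %in% c(0L, 1L))) {
    msg <- c(msg, "event must be 0 (censored) or 1 (event)")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## MutantTable
## ---------------------------------------------------------------------------

#' Per-mutant stability/flexibility record table
#'
#' A \code{DataFrame} subclass with one row per observed mutant. Required
#' columns: \code{protein_id}, \code{substitution} (e.g. \code{"A123T"},
#' frameshifts carry an \code{fs} suffix and may lack \eqn{\Delta\Delta S}),
#' \code{ddG} (\eqn{\Delta\Delta G = \Delta G_{WT} - \Delta G_{mut}},
#' kJ/mol, positive = stabilizing), \code{ddS} (\eqn{\Delta\Delta S},
#' unitless, positive = increased flexibility; may be NA for frameshifts)
#' and \code{recurrence} (integer >= 1, the mutation frequency weight).
#' Optional columns: \code{sift_score} in [0,1], binding-affinity inputs
#' \code{ba_dimer_wt}, \code{ba_dimer_mut}, \code{ba_trimer_wt},
#' \code{ba_trimer_mut} (kcal/mol) and \code{cancer_type}.
#'
#' @param data a data.frame (or DataFrame) with the columns above.
#' @return a \code{MutantTable}.
#' @examples
#' MutantTable(data.frame(protein_id = "FERMT1", substitution = "A5T",
#'                        ddG = 1.5, ddS = -0.2, recurrence = 2L))
#' @export
MutantTable <- function(data) {
  data <- as(as.data.frame(data), "DataFrame")
  if ("recurrence" %in% colnames(data)) {
    data$recurrence <- as.integer(data$recurrence)
  }
  new("MutantTable", data)
}

#' @exportClass MutantTable
setClass("MutantTable", contains = "DFrame")

setValidity("MutantTable", function(object) {
  req <- c("protein_id", "substitution", "ddG", "ddS", "recurrence")
  if (!all(req %in% colnames(object))) {
    return(paste("required columns:", paste(req, collapse = ", ")))
  }
  msg <- character()
  if (any(is.na(object$recurrence)) || any(object$recurrence < 1L)) {
    msg <- c(msg, "recurrence must be an integer >= 1")
  }
  if ("sift_score" %in% colnames(object)) {
    s <- object$sift_score
    if (any(s < 0 | s > 1, na.rm = TRUE)) {
      msg <- c(msg, "sift_score must lie in [0, 1]")
    }
  }
  if (length(msg)) msg else TRUE
})

# Accept plain data.frames wherever a MutantTable is expected.
.asMutantTable <- function(x) {
  if (is(x, "MutantTable")) x else MutantTable(x)
}

## ---------------------------------------------------------------------------
## PathwayDefinition
## ---------------------------------------------------------------------------

#' Signed pathway membership
#'
#' Names a pathway and lists its positive- and negative-regulator
#' components (disjoint, with a non-empty union). Pathway activity scores
#' sum normalized positive components and subtract negative ones.
#'
#' @param name pathway name.
#' @param positive character vector of positive-regulator components.
#' @param negative character vector of negative-regulator components.
#' @param x a \code{PathwayDefinition}.
#' @return a \code{PathwayDefinition}.
#' @examples
#' PathwayDefinition("Apoptosis", positive = c("BAX", "CASP7"),
#'                   negative = "BCL2")
#' @aliases positiveComponents negativeComponents
#' @export
PathwayDefinition <- function(name, positive = character(),
                              negative = character()) {
  new("PathwayDefinition", name = as.character(name),
      positive = as.character(positive), negative = as.character(negative))
}

#' @exportClass PathwayDefinition
setClass("PathwayDefinition",
         representation(name = "character", positive = "character",
                        negative = "character"))

setValidity("PathwayDefinition", function(object) {
  msg <- character()
  if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
  if (length(object@positive) + length(object@negative) == 0L) {
    msg <- c(msg, "at least one component is required")
  }
  if (length(intersect(object@positive, object@negative))) {
    msg <- c(msg, "positive and negative component lists must be disjoint")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname PathwayDefinition
#' @export
setMethod("positiveComponents", "PathwayDefinition", function(x) x@positive)

#' @rdname PathwayDefinition
#' @export
setMethod("negativeComponents", "PathwayDefinition", function(x) x@negative)

setMethod("show", "PathwayDefinition", function(object) {
  cat("PathwayDefinition:", object@name, "\n")
  cat("  positive:", paste(object@positive, collapse = ", "), "\n")
  cat("  negative:", paste(object@negative, collapse = ", "), "\n")
})

#' @rdname PathwayDefinition
#' @param pathways a list of \code{PathwayDefinition} objects.
#' @export
pathwayNames <- function(pathways) {
  vapply(pathways, function(p) p@name, character(1))
}

## ---------------------------------------------------------------------------
## CohortSpec
## ---------------------------------------------------------------------------

#' @exportClass CohortSpec
setClass("CohortSpec", representation(
  nSamples = "integer",
  nCancerTypes = "integer",
  geneNames = "character",
  baselineProb = "numeric",
  plantedOR = "data.frame",
  plantedShift = "numeric",
  plantedHR = "numeric",
  censoringFraction = "numeric",
  baselineHazard = "numeric",
  ddgDdsCorrelation = "numeric",
  ddgScale = "numeric",
  recurrenceExponent = "numeric",
  recurrenceMax = "integer",
  nMutants = "integer",
  frameshiftFraction = "numeric",
  expressionNoiseSd = "numeric",
  pathways = "list",
  pathwayEffects = "data.frame",
  nNullComponents = "integer",
  seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nSamples < 2L) msg <- c(msg, "nSamples must be >= 2")
  if (object@nCancerTypes < 1L) msg <- c(msg, "nCancerTypes must be >= 1")
  if (anyDuplicated(object@geneNames)) {
    msg <- c(msg, "gene names must be unique")
  }
  p <- object@baselineProb
  if (length(p) != length(object@geneNames) ||
      any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    msg <- c(msg, "baseline alteration probabilities must lie in (0, 1), one per gene")
  }
  or <- object@plantedOR
  if (nrow(or)) {
    if (!all(c("gene_a", "gene_b", "odds_ratio") %in% colnames(or))) {
      msg <- c(msg, "plantedOR needs columns gene_a, gene_b, odds_ratio")
    } else {
      unknown <- setdiff(c(or$gene_a, or$gene_b), object@geneNames)
      if (length(unknown)) {
        msg <- c(msg, paste("unknown gene in plantedOR:",
                            paste(unknown, collapse = ", ")))
      }
      if (any(!is.finite(or$odds_ratio)) || any(or$odds_ratio <= 0)) {
        msg <- c(msg, "planted odds ratios must be positive")
      }
    }
  }
  unknown <- setdiff(names(object@plantedShift), object@geneNames)
  if (length(unknown)) {
    msg <- c(msg, paste("unknown gene in plantedShift:",
                        paste(unknown, collapse = ", ")))
  }
  hr <- object@plantedHR
  if (length(hr) < 1L || is.null(names(hr)) ||
      any(!is.finite(hr)) || any(hr <= 0)) {
    msg <- c(msg, "plantedHR must be a named vector of positive hazard ratios")
  }
  if (object@nSamples < 2L * length(hr)) {
    msg <- c(msg, "degenerate cohort: fewer than 2 samples per survival group")
  }
  cf <- object@censoringFraction
  if (!is.finite(cf) || cf < 0 || cf >= 1) {
    msg <- c(msg, "censoringFraction must lie in [0, 1)")
  }
  if (abs(object@ddgDdsCorrelation) > 1) {
    msg <- c(msg, "ddgDdsCorrelation must lie in [-1, 1]")
  }
  if (object@ddgScale <= 0) msg <- c(msg, "ddgScale must be positive")
  if (object@frameshiftFraction < 0 || object@frameshiftFraction >= 1) {
    msg <- c(msg, "frameshiftFraction must lie in [0, 1)")
  }
  pe <- object@pathwayEffects
  if (nrow(pe)) {
    if (!all(c("gene", "pathway", "shift") %in% colnames(pe))) {
      msg <- c(msg, "pathwayEffects needs columns gene, pathway, shift")
    } else {
      unknown <- setdiff(pe$gene, object@geneNames)
      if (length(unknown)) {
        msg <- c(msg, paste("unknown gene in pathwayEffects:",
                            paste(unknown, collapse = ", ")))
      }
      unknown <- setdiff(pe$pathway, pathwayNames(object@pathways))
      if (length(unknown)) {
        msg <- c(msg, paste("unknown pathway in pathwayEffects:",
                            paste(unknown, collapse = ", ")))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", object@nSamples, "samples,",
      length(object@geneNames), "genes,", object@nCancerTypes,
      "cancer types, seed", object@seed, "\n")
  cat("  planted ORs:", nrow(object@plantedOR),
      "| expression shifts:", length(object@plantedShift),
      "| survival groups:", paste(names(object@plantedHR), collapse = "/"),
      "\n")
  cat("  mutants:", object@nMutants,
      sprintf("(ddG-ddS correlation %.2f, ddG scale %.3f kJ/mol)",
              object@ddgDdsCorrelation, object@ddgScale), "\n")
})

## ---------------------------------------------------------------------------
## CohortBundle
## ---------------------------------------------------------------------------

#' Generated synthetic cohort bundle
#'
#' Holds every table a cohort analysis consumes — alterations, paired
#' tumor/normal expression, survival, RPPA components and the mutant
#' stability table — together with the generating \code{CohortSpec} and a
#' truth record of all
#' planted parameters. All tables share one sample identifier space
#' (expression columns carry \code{_T}/\code{_N} suffixes linked by
#' \code{pair_id}).
#'
#' @param x a \code{CohortBundle}.
#' @return accessors return the corresponding table; \code{cohortTruth()}
#'   the immutable list of planted parameters.
#' @aliases alterations expressionData survivalData rppaData mutantTable
#'   cohortTruth
#' @name CohortBundle
#' @exportClass CohortBundle
setClass("CohortBundle", representation(
  alterations = "AlterationMatrix",
  expression = "FeatureMatrix",
  survival = "SurvivalData",
  rppa = "FeatureMatrix",
  mutants = "MutantTable",
  truth = "list",
  spec = "CohortSpec"))

setValidity("CohortBundle", function(object) {
  msg <- character()
  samples <- colnames(object@alterations)
  if (!identical(sort(samples), sort(object@survival$sample))) {
    msg <- c(msg, "alteration and survival tables must share sample ids")
  }
  pid <- colData(object@expression)$pair_id
  if (!is.null(pid) && !all(unique(pid) %in% samples)) {
    msg <- c(msg, "expression pairing keys must be cohort sample ids")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname CohortBundle
#' @export
setMethod("alterations", "CohortBundle", function(x) x@alterations)

#' @rdname CohortBundle
#' @export
setMethod("expressionData", "CohortBundle", function(x) x@expression)

#' @rdname CohortBundle
#' @export
setMethod("survivalData", "CohortBundle", function(x) x@survival)

#' @rdname CohortBundle
#' @export
setMethod("rppaData", "CohortBundle", function(x) x@rppa)

#' @rdname CohortBundle
#' @export
setMethod("mutantTable", "CohortBundle", function(x) x@mutants)

#' @rdname CohortBundle
#' @export
setMethod("cohortTruth", "CohortBundle", function(x) x@truth)

setMethod("show", "CohortBundle", function(object) {
  cat("CohortBundle (seed", object@spec@seed, ")\n")
  cat("  alterations:", nrow(object@alterations), "genes x",
      ncol(object@alterations), "samples\n")
  cat("  expression:", nrow(object@expression), "genes x",
      ncol(object@expression), "columns (paired tumor/normal)\n")
  cat("  survival:", nrow(object@survival), "samples, groups:",
      paste(unique(object@survival$group), collapse = "/"), "\n")
  cat("  rppa:", nrow(object@rppa), "components x", ncol(object@rppa),
      "samples\n")
  cat("  mutants:", nrow(object@mutants), "records\n")
})
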