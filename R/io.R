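# Plain-text readers and writers for the package's tables. All formats are
# TSV; the feature matrix carries its value-scale tag as a '#' header line.

.writeTsv <- function(df, path) {
  write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read and write alteration tables
#'
#' The binary-matrix format has one row per sample with columns
#' \code{sample_id}, \code{cancer_type} and one 0/1 column per gene. The
#' minimal-MAF format has one row per altered (sample, gene) cell with
#' columns \code{Hugo_Symbol}, \code{Tumor_Sample_Barcode},
#' \code{Variant_Classification} and \code{HGVSp_Short}; reading a MAF
#' requires the full sample universe (samples without any alteration do
#' not appear in a MAF).
#'
#' @param x an \code{\link{AlterationMatrix}}.
#' @param path file path.
#' @param samples character vector of all cohort sample ids (MAF only).
#' @param cancerType optional named cancer-type labels (MAF only).
#' @param types optional subset of \code{Variant_Classification} values to
#'   count as altered (default: any non-empty label).
#' @return readers return an \code{AlterationMatrix}; writers the path,
#'   invisibly.
#' @name alteration-io
NULL

#' @rdname alteration-io
#' @export
writeAlterationMatrix <- function(x, path) {
  st <- alteredStatus(x)
  df <- data.frame(sample_id = colnames(st),
                   cancer_type = cancerType(x),
                   t(st) * 1L, check.names = FALSE)
  .writeTsv(df, path)
}

#' @rdname alteration-io
#' @export
readAlterationMatrix <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  genes <- setdiff(colnames(df), c("sample_id", "cancer_type"))
  m <- t(as.matrix(df[, genes, drop = FALSE]) > 0)
  colnames(m) <- df$sample_id
  AlterationMatrix(m, cancerType = df$cancer_type)
}

#' @rdname alteration-io
#' @export
writeAlterationMaf <- function(x, path) {
  st <- alteredStatus(x)
  idx <- which(st, arr.ind = TRUE)
  df <- data.frame(
    Hugo_Symbol = rownames(st)[idx[, 1]],
    Tumor_Sample_Barcode = colnames(st)[idx[, 2]],
    Variant_Classification = "Missense_Mutation",
    HGVSp_Short = "p.?")
  .writeTsv(df[order(df$Tumor_Sample_Barcode, df$Hugo_Symbol), ], path)
}

#' @rdname alteration-io
#' @export
readAlterationMaf <- function(path, samples = NULL, cancerType = NULL,
                              types = NULL) {
  df <- read.delim(path, check.names = FALSE)
  req <- c("Hugo_Symbol", "Tumor_Sample_Barcode")
  if (!all(req %in% colnames(df))) {
    stop("MAF requires columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(types) && "Variant_Classification" %in% colnames(df)) {
    df <- df[df$Variant_Classification %in% types, , drop = FALSE]
  }
  if (is.null(samples)) samples <- sort(unique(df$Tumor_Sample_Barcode))
  genes <- sort(unique(df$Hugo_Symbol))
  m <- matrix(FALSE, length(genes), length(samples),
              dimnames = list(genes, samples))
  keep <- df$Tumor_Sample_Barcode %in% samples
  m[cbind(match(df$Hugo_Symbol[keep], genes),
          match(df$Tumor_Sample_Barcode[keep], samples))] <- TRUE
  ct <- if (is.null(cancerType)) "pan" else cancerType[samples]
  AlterationMatrix(m, cancerType = ct)
}

#' Read and write feature matrices
#'
#' One row per sample: columns \code{sample_id}, \code{pair_id},
#' \code{tissue} (the latter two may be absent) and one numeric column per
#' feature. The value-scale tag is stored in a leading
#' \code{# value_scale=...} comment line.
#'
#' @param x a \code{\link{FeatureMatrix}}.
#' @param path file path.
#' @return the reader returns a \code{FeatureMatrix}; the writer the path,
#'   invisibly.
#' @name feature-io
NULL

#' @rdname feature-io
#' @export
writeFeatureMatrix <- function(x, path) {
  m <- featureValues(x)
  df <- data.frame(sample_id = colnames(m), check.names = FALSE)
  if (!is.null(pairId(x))) df$pair_id <- pairId(x)
  if (!is.null(tissueType(x))) df$tissue <- tissueType(x)
  df <- cbind(df, as.data.frame(t(m), check.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# value_scale=", valueScale(x)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname feature-io
#' @export
readFeatureMatrix <- function(path) {
  first <- readLines(path, n = 1L)
  scale <- if (startsWith(first, "# value_scale=")) {
    sub("^# value_scale=", "", first)
  } else {
    "unknown"
  }
  df <- read.delim(path, comment.char = "#", check.names = FALSE)
  meta <- intersect(c("sample_id", "pair_id", "tissue"), colnames(df))
  m <- t(as.matrix(df[, setdiff(colnames(df), meta), drop = FALSE]))
  colnames(m) <- df$sample_id
  FeatureMatrix(m,
                pairId = if ("pair_id" %in% meta) df$pair_id else NULL,
                tissue = if ("tissue" %in% meta) df$tissue else NULL,
                valueScale = scale)
}

#' Read and write survival tables
#'
#' TSV with columns \code{sample}, \code{time}, \code{event},
#' \code{group}.
#'
#' @param x a \code{\link{SurvivalData}} table.
#' @param path file path.
#' @return the reader returns a \code{SurvivalData}; the writer the path,
#'   invisibly.
#' @export
writeSurvivalTable <- function(x, path) .writeTsv(x, path)

#' @rdname writeSurvivalTable
#' @export
readSurvivalTable <- function(path) {
  df <- read.delim(path)
  SurvivalData(df$sample, df$time, df$event,
               if ("group" %in% colnames(df)) df$group else "all")
}

#' Read and write mutant tables
#'
#' TSV with the \code{\link{MutantTable}} columns.
#'
#' @param x a \code{\link{MutantTable}}.
#' @param path file path.
#' @return the reader returns a \code{MutantTable}; the writer the path,
#'   invisibly.
#' @export
writeMutantTable <- function(x, path) .writeTsv(x, path)

#' @rdname writeMutantTable
#' @export
readMutantTable <- function(path) MutantTable(read.delim(path))

#' Read gene sets from a GMT file
#'
#' Standard GMT (set name, description, members per tab-separated line).
#'
#' @param path path to a \code{.gmt} file.
#' @return named list of character vectors.
#' @export
readGeneSets <- function(path) {
  fgsea::gmtPathways(path)
}

#' Read and write signed pathway definitions
#'
#' Two-column signed membership TSV: \code{pathway}, \code{component},
#' \code{sign} (\code{+} or \code{-}).
#'
#' @param pathways a list of \code{\link{PathwayDefinition}}s.
#' @param path file path.
#' @return the reader returns a named list of \code{PathwayDefinition}s;
#'   the writer the path, invisibly.
#' @export
writePathwayDefinitions <- function(pathways, path) {
  rows <- lapply(pathways, function(p) {
    data.frame(pathway = p@name,
               component = c(positiveComponents(p), negativeComponents(p)),
               sign = c(rep("+", length(positiveComponents(p))),
                        rep("-", length(negativeComponents(p)))))
  })
  .writeTsv(do.call(rbind, rows), path)
}

#' @rdname writePathwayDefinitions
#' @export
readPathwayDefinitions <- function(path) {
  df <- read.delim(path)
  if (!all(c("pathway", "component", "sign") %in% colnames(df))) {
    stop("pathway definitions need columns pathway, component, sign",
         call. = FALSE)
  }
  sets <- split(df, df$pathway)
  out <- lapply(sets, function(s) {
    PathwayDefinition(s$pathway[1],
                      positive = s$component[s$sign == "+"],
                      negative = s$component[s$sign == "-"])
  })
  out[unique(df$pathway)]
}

#' Write the truth record of a synthetic cohort
#'
#' Serializes every planted parameter as \code{key = value} lines
#' (vectors joined with commas, tables flattened per row).
#'
#' @param truth the truth list of a \code{\link{CohortBundle}}.
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeTruthRecord <- function(truth, path) {
  fmt <- function(v) paste(format(v, trim = TRUE, digits = 15),
                           collapse = ",")
  lines <- character()
  for (key in names(truth)) {
    val <- truth[[key]]
    if (is.data.frame(val)) {
      for (i in seq_len(nrow(val))) {
        lines <- c(lines, paste0(key, ".", i, " = ",
                                 paste(vapply(val[i, ], fmt, character(1)),
                                       collapse = ",")))
      }
    } else if (!is.null(names(val)) && length(val) > 1L) {
      lines <- c(lines, paste0(key, ".", names(val), " = ",
                               vapply(val, fmt, character(1))))
    } else {
      lines <- c(lines, paste0(key, " = ", fmt(val)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a cohort specification from a YAML config
#'
#' Accepts a YAML file whose top-level keys mirror the arguments of
#' \code{\link{CohortSpec}} (unknown keys are an error). Tabular fields
#' (\code{plantedOR}, \code{pathwayEffects}) are lists of records; planted
#' shifts and hazard ratios are named mappings.
#'
#' @param path path to a YAML file.
#' @return a validated \code{\link{CohortSpec}}.
#' @export
readCohortSpec <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- names(formals(CohortSpec))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  emptyCols <- list(
    plantedOR = data.frame(gene_a = character(), gene_b = character(),
                           odds_ratio = numeric()),
    pathwayEffects = data.frame(gene = character(), pathway = character(),
                                shift = numeric()))
  for (key in names(emptyCols)) {
    if (key %in% names(cfg)) {
      cfg[[key]] <- if (length(cfg[[key]])) {
        do.call(rbind, lapply(cfg[[key]], as.data.frame))
      } else {
        emptyCols[[key]]
      }
    }
  }
  for (key in c("plantedShift", "plantedHR", "baselineProb")) {
    if (!is.null(cfg[[key]]) && is.list(cfg[[key]])) {
      cfg[[key]] <- unlist(cfg[[key]])
    }
  }
  do.call(CohortSpec, cfg)
}

#' Write every table of a cohort bundle to a directory
#'
#' Writes the alteration table (both minimal-MAF and binary-matrix
#' formats), the paired expression matrix, the RPPA component matrix, the
#' survival table, the mutant table, the pathway definitions and the truth
#' record.
#'
#' @param bundle a \code{\link{CohortBundle}}.
#' @param dir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
writeCohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    maf = writeAlterationMaf(alterations(bundle),
                             file.path(dir, "alterations.maf.tsv")),
    matrix = writeAlterationMatrix(alterations(bundle),
                                   file.path(dir, "alterations.matrix.tsv")),
    expression = writeFeatureMatrix(expressionData(bundle),
                                    file.path(dir, "expression.tsv")),
    rppa = writeFeatureMatrix(rppaData(bundle), file.path(dir, "rppa.tsv")),
    survival = writeSurvivalTable(survivalData(bundle),
                                  file.path(dir, "survival.tsv")),
    mutants = writeMutantTable(mutantTable(bundle),
                               file.path(dir, "mutants.tsv")),
    pathways = writePathwayDefinitions(bundle@spec@pathways,
                                       file.path(dir, "pathways.tsv")),
    truth = writeTruthRecord(cohortTruth(bundle),
                             file.path(dir, "truth.txt")))
  invisible(paths)
}
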