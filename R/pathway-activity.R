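# RPPA-style component normalization, pathway activity scores (PAS) and
# median-split activation/inhibition calls.

#' Median-center and SD-normalize RPPA components
#'
#' Per component (row): subtract the median across samples, then divide by
#' the standard deviation across samples, yielding relative protein
#' levels. The operation is idempotent up to floating point.
#'
#' @param x a \code{\link{FeatureMatrix}} or numeric matrix (components x
#'   samples) with at least 2 samples.
#' @return the normalized object, same class as the input.
#' @export
normalizeComponents <- function(x) {
  m <- .valuesMatrix(x)
  if (ncol(m) < 2L) stop("at least 2 samples are required", call. = FALSE)
  sds <- apply(m, 1L, sd)
  if (any(sds == 0 | !is.finite(sds))) {
    bad <- rownames(m)[sds == 0 | !is.finite(sds)]
    stop("constant component: ", paste(bad, collapse = ", "),
         " has zero variance across samples", call. = FALSE)
  }
  norm <- (m - apply(m, 1L, median)) / sds
  if (is(x, "FeatureMatrix")) {
    FeatureMatrix(norm, valueScale = valueScale(x))
  } else {
    norm
  }
}

#' Pathway activity score
#'
#' PAS(sample) = sum of the pathway's positive-regulator components minus
#' the sum of its negative-regulator components, computed on the values as
#' given (normalize first with \code{\link{normalizeComponents}} for
#' relative protein levels).
#'
#' @param x a \code{\link{FeatureMatrix}} or matrix (components x samples).
#' @param pathway a \code{\link{PathwayDefinition}}; all its components
#'   must be present in \code{x}.
#' @return named numeric vector of per-sample scores.
#' @examples
#' m <- matrix(c(1, 2, 0.5), 3, 1,
#'             dimnames = list(c("a", "b", "c"), "s1"))
#' pathwayScore(m, PathwayDefinition("demo", c("a", "b"), "c"))  # 2.5
#' @export
pathwayScore <- function(x, pathway) {
  m <- .valuesMatrix(x)
  comps <- c(positiveComponents(pathway), negativeComponents(pathway))
  missing <- setdiff(comps, rownames(m))
  if (length(missing)) {
    stop("unknown component: ", paste(missing, collapse = ", "),
         " absent from the matrix", call. = FALSE)
  }
  pos <- colSums(m[positiveComponents(pathway), , drop = FALSE])
  neg <- if (length(negativeComponents(pathway))) {
    colSums(m[negativeComponents(pathway), , drop = FALSE])
  } else 0
  pos - neg
}

#' @rdname pathwayScore
#' @param pathways a list of \code{PathwayDefinition}s.
#' @return \code{pathwayScores()} returns a samples x pathways matrix.
#' @export
pathwayScores <- function(x, pathways) {
  out <- vapply(pathways, function(p) pathwayScore(x, p),
                numeric(ncol(.valuesMatrix(x))))
  colnames(out) <- pathwayNames(pathways)
  out
}

# Median split on one gene's expression: above the median -> high, ties
# and below -> low.
.medianSplit <- function(values) {
  med <- median(values)
  high <- values > med
  if (sum(high) < 2L || sum(!high) < 2L) {
    stop("degenerate split: ties at the median leave fewer than 2 ",
         "samples on one side", call. = FALSE)
  }
  high
}

#' Pathway activation/inhibition calls from median expression splits
#'
#' For each gene, samples are split at the gene's median expression
#' (ties to the low group); for each pathway, the pathway activity scores
#' of the high and low groups are compared with a two-sided Welch t-test.
#' p-values are Benjamini-Hochberg adjusted across all (gene, pathway)
#' pairs submitted in the batch. A pair with FDR <= \code{fdrCutoff} is
#' called \code{activate} when mean PAS(high) > mean PAS(low) and
#' \code{inhibit} when mean PAS(high) <= mean PAS(low); otherwise
#' \code{none}.
#'
#' @param pas samples x pathways matrix of activity scores (a named vector
#'   is treated as one pathway), e.g. from \code{\link{pathwayScores}}.
#' @param expression a \code{\link{FeatureMatrix}} or matrix (genes x
#'   samples); for paired matrices only tumor columns are used, keyed by
#'   \code{pair_id}.
#' @param genes genes whose median split drives the comparison.
#' @param cancerType optional per-sample cancer-type labels (named by
#'   sample); when supplied, splits and tests run within each cancer type
#'   and the result carries a \code{cancer_type} column (the BH family is
#'   still the whole batch).
#' @param fdrCutoff FDR threshold for a non-\code{none} call.
#' @return \code{DataFrame} with columns \code{gene}, \code{pathway}
#'   (and \code{cancer_type} if stratified), \code{mean_high},
#'   \code{mean_low}, \code{t}, \code{p}, \code{fdr}, \code{effect}.
#' @export
pathwayAssociation <- function(pas, expression, genes, cancerType = NULL,
                               fdrCutoff = 0.05) {
  if (is.null(dim(pas))) {
    pas <- matrix(pas, ncol = 1L,
                  dimnames = list(names(pas), "pathway"))
  }
  expr <- .valuesMatrix(expression)
  if (is(expression, "FeatureMatrix") && !is.null(tissueType(expression))) {
    tumor <- tissueType(expression) == "tumor"
    expr <- expr[, tumor, drop = FALSE]
    colnames(expr) <- pairId(expression)[tumor]
  }
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) {
    stop("unknown gene: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  samples <- intersect(rownames(pas), colnames(expr))
  if (length(samples) < 4L) {
    stop("too few samples shared between PAS and expression", call. = FALSE)
  }
  strata <- if (is.null(cancerType)) {
    list(pan = samples)
  } else {
    split(samples, cancerType[samples])
  }
  rows <- list()
  for (stratum in names(strata)) {
    ss <- strata[[stratum]]
    for (g in genes) {
      high <- .medianSplit(expr[g, ss])
      for (pw in colnames(pas)) {
        sc <- pas[ss, pw]
        tt <- t.test(sc[high], sc[!high], var.equal = FALSE)
        rows[[length(rows) + 1L]] <- DataFrame(
          gene = g, pathway = pw, cancer_type = stratum,
          mean_high = mean(sc[high]), mean_low = mean(sc[!high]),
          t = unname(tt$statistic), p = tt$p.value)
      }
    }
  }
  res <- do.call(rbind, rows)
  res$fdr <- .bh(res$p)
  res$effect <- ifelse(res$fdr > fdrCutoff, "none",
                       ifelse(res$mean_high > res$mean_low,
                              "activate", "inhibit"))
  if (is.null(cancerType)) res$cancer_type <- NULL
  res
}

#' Global percentage of pathway activation/inhibition across cancer types
#'
#' For each (gene, pathway) and direction, 100 x (number of cancer types
#' with that call) / (number of cancer types). Since a cancer type yields
#' at most one direction per gene and pathway, activation and inhibition
#' percentages sum to at most 100.
#'
#' @param calls output of \code{\link{pathwayAssociation}} stratified by
#'   cancer type (must carry a \code{cancer_type} column; a \code{gene}
#'   column is optional).
#' @param nCancerTypes total number of cancer types (>= 1).
#' @return \code{DataFrame} with columns \code{gene}, \code{pathway},
#'   \code{direction}, \code{n_cancer_types}, \code{percent}.
#' @export
globalPercentage <- function(calls, nCancerTypes) {
  if (nCancerTypes < 1L) stop("nCancerTypes must be >= 1", call. = FALSE)
  if (is.null(calls$cancer_type) || anyNA(calls$cancer_type)) {
    stop("missing label: every call needs a cancer_type label",
         call. = FALSE)
  }
  gene <- if (is.null(calls$gene)) rep("all", NROW(calls)) else calls$gene
  key <- unique(data.frame(gene = gene, pathway = calls$pathway))
  rows <- lapply(seq_len(nrow(key)), function(i) {
    sel <- gene == key$gene[i] & calls$pathway == key$pathway[i]
    sub <- calls[sel, , drop = FALSE]
    n <- vapply(c("activate", "inhibit"), function(dir) {
      length(unique(sub$cancer_type[sub$effect == dir]))
    }, integer(1))
    DataFrame(gene = key$gene[i], pathway = key$pathway[i],
              direction = c("activate", "inhibit"),
              n_cancer_types = unname(n),
              percent = unname(100 * n / nCancerTypes))
  })
  do.call(rbind, rows)
}
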