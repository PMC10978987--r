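# Co-alteration frequencies, mean co-alteration dynamics, and pairwise
# mutual-exclusivity odds ratios.

#' Two-sided exact test of a 2x2 contingency table
#'
#' Fisher's exact test (two-sided, conditional on margins) on the table
#' \code{[both, a_only; b_only, neither]}. This is the significance test
#' behind co-alteration frequencies and mutual-exclusivity calls.
#'
#' @param both,aOnly,bOnly,neither nonnegative integer cell counts.
#' @return the two-sided p-value.
#' @examples
#' exactTest2x2(6, 4, 2, 8)
#' @export
exactTest2x2 <- function(both, aOnly, bOnly, neither) {
  counts <- c(both, aOnly, bOnly, neither)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be nonnegative integers", call. = FALSE)
  }
  fisher.test(matrix(counts, 2L, 2L, byrow = TRUE))$p.value
}

#' Partition samples by anchor alteration status
#'
#' Splits the cohort into the anchor-altered and anchor-unaltered sample
#' sets (disjoint and exhaustive).
#'
#' @param x an \code{\link{AlterationMatrix}}.
#' @param anchor anchor gene name.
#' @return list with character vectors \code{altered} and \code{unaltered}.
#' @export
partitionByAlteration <- function(x, anchor) {
  st <- alteredStatus(x)
  if (!anchor %in% rownames(st)) {
    stop("unknown gene: '", anchor, "' is not in the alteration table",
         call. = FALSE)
  }
  a <- st[anchor, ]
  if (!any(a)) {
    warning("anchor '", anchor, "' is never altered: empty altered set")
  }
  list(altered = colnames(st)[a], unaltered = colnames(st)[!a])
}

#' Partner co-alteration frequencies in altered vs unaltered cohorts
#'
#' For each partner gene, A\% is the percentage of anchor-altered samples
#' in which the partner is also altered and U\% the analogous percentage
#' among anchor-unaltered samples. Each partner's 2x2 table (partner status
#' x anchor status) is tested with Fisher's exact test; q-values are
#' Benjamini-Hochberg adjusted across partners.
#'
#' @param x an \code{\link{AlterationMatrix}}.
#' @param anchor anchor gene (excluded from partners).
#' @param partners character vector of partner genes; defaults to all
#'   other genes.
#' @return \code{DataFrame} with columns \code{partner},
#'   \code{a_altered}, \code{u_altered}, \code{a_percent}, \code{u_percent},
#'   \code{p}, \code{q}.
#' @export
coalterationFrequencies <- function(x, anchor,
                                    partners = setdiff(rownames(x), anchor)) {
  st <- alteredStatus(x)
  if (!anchor %in% rownames(st)) {
    stop("unknown gene: '", anchor, "'", call. = FALSE)
  }
  missing <- setdiff(partners, rownames(st))
  if (length(missing)) {
    stop("unknown partner gene(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  partners <- setdiff(partners, anchor)
  a <- st[anchor, ]
  nA <- sum(a); nU <- sum(!a)
  if (nA == 0L || nU == 0L) {
    stop("degenerate cohort: anchor-altered and unaltered sets must both ",
         "be non-empty", call. = FALSE)
  }
  aAlt <- unname(rowSums(st[partners, a, drop = FALSE]))
  uAlt <- unname(rowSums(st[partners, !a, drop = FALSE]))
  p <- vapply(seq_along(partners), function(i) {
    exactTest2x2(aAlt[i], nA - aAlt[i], uAlt[i], nU - uAlt[i])
  }, numeric(1))
  DataFrame(partner = partners,
            a_altered = as.integer(aAlt),
            u_altered = as.integer(uAlt),
            a_percent = 100 * aAlt / nA,
            u_percent = 100 * uAlt / nU,
            p = p,
            q = .bh(p))
}

#' Mean co-alteration dynamics of a gene set
#'
#' \eqn{X = (\sum A\% - \sum U\%)/N} over the \eqn{N} genes of a set:
#' the average excess alteration percentage of the set's genes in
#' anchor-altered versus anchor-unaltered samples. The statistic is linear:
#' over a disjoint union of sets it equals the size-weighted mean of the
#' parts.
#'
#' @param results output of \code{\link{coalterationFrequencies}} (or any
#'   table with \code{a_percent}/\code{u_percent} columns), restricted to
#'   the gene set.
#' @param name gene-set name carried into the result.
#' @return \code{DataFrame} with columns \code{gene_set}, \code{n_genes},
#'   \code{X}.
#' @examples
#' meanCoalterationDynamics(
#'   S4Vectors::DataFrame(a_percent = c(60, 40), u_percent = c(20, 20)))
#' @export
meanCoalterationDynamics <- function(results, name = "gene_set") {
  if (NROW(results) < 1L) {
    stop("empty input: the gene set must contain at least one gene",
         call. = FALSE)
  }
  DataFrame(gene_set = name,
            n_genes = NROW(results),
            X = (sum(results$a_percent) - sum(results$u_percent)) /
              NROW(results))
}

.oddsRatio2x2 <- function(both, aOnly, bOnly, neither) {
  cells <- c(both, aOnly, bOnly, neither)
  if (any(cells == 0)) cells <- cells + 0.5  # Haldane correction
  (cells[1] * cells[4]) / (cells[2] * cells[3])
}

#' Mutual exclusivity / co-occurrence of two genes
#'
#' Builds the 2x2 contingency table of alteration status (both / A-only /
#' B-only / neither), computes the odds ratio (Haldane +0.5 correction
#' applied only when a zero cell occurs), its log2, and the two-sided
#' Fisher exact p-value. The call is \code{exclusive} when log2 OR < 0 and
#' q <= 0.05, \code{co-occurrent} when log2 OR > 0 and q <= 0.05, else
#' \code{none}. For a single pair q equals p; use
#' \code{\link{mutualExclusivityAll}} for a BH-adjusted family. Degenerate
#' margins (a gene altered in all or no samples) are reported with call
#' \code{none} and a warning.
#'
#' @param x an \code{\link{AlterationMatrix}} with at least 4 samples.
#' @param geneA,geneB gene names.
#' @return one-row \code{DataFrame} with the counts, \code{odds_ratio},
#'   \code{log2_odds_ratio}, \code{p}, \code{q} and \code{call}.
#' @export
mutualExclusivity <- function(x, geneA, geneB) {
  st <- alteredStatus(x)
  missing <- setdiff(c(geneA, geneB), rownames(st))
  if (length(missing)) {
    stop("unknown gene: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (ncol(st) < 4L) {
    stop("cohort size must be at least 4", call. = FALSE)
  }
  res <- .exclusivityRow(st[geneA, ], st[geneB, ], geneA, geneB)
  res$q <- res$p
  res$call <- .exclusivityCall(res$log2_odds_ratio, res$q, res$degenerate)
  if (res$degenerate) {
    warning("degenerate margins: '", geneA, "'/'", geneB,
            "' altered in all or no samples; call set to 'none'")
  }
  res$degenerate <- NULL
  res
}

.exclusivityRow <- function(a, b, geneA, geneB) {
  both <- sum(a & b); aOnly <- sum(a & !b)
  bOnly <- sum(!a & b); neither <- sum(!a & !b)
  or <- .oddsRatio2x2(both, aOnly, bOnly, neither)
  DataFrame(gene_a = geneA, gene_b = geneB,
            both = both, a_only = aOnly, b_only = bOnly, neither = neither,
            odds_ratio = or,
            log2_odds_ratio = log2(or),
            p = exactTest2x2(both, aOnly, bOnly, neither),
            degenerate = (both + aOnly) %in% c(0L, length(a)) ||
              (both + bOnly) %in% c(0L, length(a)))
}

.exclusivityCall <- function(log2or, q, degenerate = FALSE) {
  ifelse(degenerate | q > 0.05, "none",
         ifelse(log2or < 0, "exclusive",
                ifelse(log2or > 0, "co-occurrent", "none")))
}

#' @rdname mutualExclusivity
#' @param genes genes over which to test all pairs (default: all genes in
#'   \code{x}); q-values are BH-adjusted across the pairs.
#' @export
mutualExclusivityAll <- function(x, genes = rownames(x)) {
  st <- alteredStatus(x)
  missing <- setdiff(genes, rownames(st))
  if (length(missing)) {
    stop("unknown gene: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (ncol(st) < 4L) stop("cohort size must be at least 4", call. = FALSE)
  pairs <- combn(genes, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    .exclusivityRow(st[pairs[1, i], ], st[pairs[2, i], ],
                    pairs[1, i], pairs[2, i])
  })
  res <- do.call(rbind, rows)
  res$q <- .bh(res$p)
  res$call <- .exclusivityCall(res$log2_odds_ratio, res$q, res$degenerate)
  if (any(res$degenerate)) {
    warning("degenerate margins for ", sum(res$degenerate),
            " pair(s); their call is 'none'")
  }
  res$degenerate <- NULL
  res
}

#' Label-permutation null for the co-alteration dynamics statistic
#'
#' Permutes the anchor's alteration labels across samples, recomputes the
#' mean co-alteration dynamics X each time, and reports the null
#' distribution and the empirical two-sided p-value of the observed X.
#' Under permutation the planted co-alteration structure is destroyed, so
#' X concentrates near 0.
#'
#' @param x an \code{\link{AlterationMatrix}}.
#' @param anchor anchor gene.
#' @param partners partner genes forming the set.
#' @param nPerm number of label permutations.
#' @return list with \code{observed}, \code{null} (numeric vector) and
#'   \code{p} (empirical two-sided).
#' @export
coalterationPermutationTest <- function(x, anchor,
                                        partners = setdiff(rownames(x),
                                                           anchor),
                                        nPerm = 1000L) {
  st <- alteredStatus(x)
  if (!anchor %in% rownames(st)) {
    stop("unknown gene: '", anchor, "'", call. = FALSE)
  }
  partners <- setdiff(partners, anchor)
  a <- st[anchor, ]
  pm <- st[partners, , drop = FALSE]
  xOf <- function(lab) {
    nA <- sum(lab); nU <- sum(!lab)
    mean(100 * rowSums(pm[, lab, drop = FALSE]) / nA -
         100 * rowSums(pm[, !lab, drop = FALSE]) / nU)
  }
  observed <- xOf(a)
  null <- vapply(seq_len(nPerm), function(i) xOf(sample(a)), numeric(1))
  list(observed = observed, null = null,
       p = (1 + sum(abs(null) >= abs(observed))) / (nPerm + 1))
}
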