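# Mutant stability/flexibility landscape classification.

#' Stability and flexibility change of a mutant
#'
#' \code{stabilityDelta()} computes \eqn{\Delta\Delta G = \Delta G_{WT} -
#' \Delta G_{mut}} (kJ/mol): positive values indicate stabilization,
#' negative destabilization. The identical contract applies to the
#' vibrational-entropy change \eqn{\Delta\Delta S} (positive = increased
#' flexibility).
#'
#' @param gWT,gMut finite numeric vectors of wild-type and mutant values
#'   (kJ/mol for free energies).
#' @return numeric vector of differences.
#' @examples
#' stabilityDelta(-5, -7)  # +2, stabilizing
#' @export
stabilityDelta <- function(gWT, gMut) {
  .checkFinite(gWT, "wild-type value")
  .checkFinite(gMut, "mutant value")
  gWT - gMut
}

#' Oligomerization binding-affinity shift of a mutant
#'
#' \eqn{\Delta BA = \Delta BA_{mut} - \Delta BA_{WT}} (kcal/mol). Positive
#' shifts are unfavorable for dimerization/trimerization, negative shifts
#' favorable.
#'
#' @param baWT,baMut finite numeric binding affinities (kcal/mol) of the
#'   wild-type and mutant oligomer.
#' @return data.frame with columns \code{shift} and \code{call}
#'   (\code{unfavorable}/\code{neutral}/\code{favorable}).
#' @examples
#' affinityShift(-5, -3)  # +2, unfavorable
#' @export
affinityShift <- function(baWT, baMut) {
  .checkFinite(baWT, "wild-type binding affinity")
  .checkFinite(baMut, "mutant binding affinity")
  shift <- baMut - baWT
  call <- ifelse(shift > 0, "unfavorable",
                 ifelse(shift < 0, "favorable", "neutral"))
  data.frame(shift = shift, call = call)
}

#' Stability/flexibility quadrant of a mutant
#'
#' Assigns the four-quadrant label of the \eqn{\Delta\Delta G} versus
#' \eqn{\Delta\Delta S} plane: Q1 = increase in both stability and
#' flexibility (\code{ddG>0, ddS>0}); Q2 = increased stability, decreased
#' flexibility; Q3 = decrease in both; Q4 = decreased stability, increased
#' flexibility. Any exact zero maps to \code{boundary}; undefined
#' \code{ddS} (frameshifts) yields \code{NA}.
#'
#' @param ddG,ddS numeric vectors (recycled to a common length).
#' @return factor with levels Q1, Q2, Q3, Q4, boundary.
#' @examples
#' assignQuadrant(c(2, -2, 0), c(1, 1, 3))
#' @export
assignQuadrant <- function(ddG, ddS) {
  n <- max(length(ddG), length(ddS))
  ddG <- rep_len(ddG, n); ddS <- rep_len(ddS, n)
  out <- rep(NA_character_, n)
  ok <- !is.na(ddG) & !is.na(ddS)
  out[ok & ddG > 0 & ddS > 0] <- "Q1"
  out[ok & ddG > 0 & ddS < 0] <- "Q2"
  out[ok & ddG < 0 & ddS < 0] <- "Q3"
  out[ok & ddG < 0 & ddS > 0] <- "Q4"
  out[ok & (ddG == 0 | ddS == 0)] <- "boundary"
  factor(out, levels = c("Q1", "Q2", "Q3", "Q4", "boundary"))
}

#' Recurrence-weighted expansion of mutant values
#'
#' Replicates each mutant's value by its recurrence count (the mutation
#' frequency across cancer types), producing the weighted multiset on which
#' percentile ranks are computed.
#'
#' @param mutants a \code{\link{MutantTable}} or data.frame.
#' @param column name of the value column to expand (default \code{"ddG"}).
#' @return numeric vector of length \code{sum(recurrence)}.
#' @examples
#' expandByRecurrence(data.frame(protein_id = "p", substitution = "A1T",
#'                               ddG = c(1, 2), ddS = 0,
#'                               recurrence = c(2, 1)))
#' @export
expandByRecurrence <- function(mutants, column = "ddG") {
  mt <- .asMutantTable(mutants)
  rep(mt[[column]], mt$recurrence)
}

#' Strictly-below nearest-rank percentile
#'
#' \eqn{P = 100 \, n / N} where \eqn{n} is the number of values strictly
#' below \code{x} and \eqn{N} the total count. Ties share a percentile.
#'
#' @param values non-empty numeric vector (the reference multiset).
#' @param x query values.
#' @return percentile(s) in [0, 100].
#' @examples
#' percentileOf(c(10, 20, 30, 40), 30)  # 50
#' @export
percentileOf <- function(values, x) {
  .strictPercentile(values, x)
}

#' Magnitude thresholds of the five-category scheme
#'
#' Container for the recurrence-weighted magnitude thresholds:
#' \code{averageLow} = mean of |median(P1 stabilizing)| and |median(P3
#' destabilizing)|; \code{averageHigh} = mean of |median(P3 stabilizing)|
#' and |median(P1 destabilizing)| (kJ/mol), plus the four region medians.
#'
#' @param averageLow,averageHigh nonnegative thresholds (kJ/mol).
#' @param medians named numeric of the four region medians.
#' @return a \code{MagnitudeThresholds} object.
#' @export
MagnitudeThresholds <- function(averageLow, averageHigh, medians) {
  new("MagnitudeThresholds", averageLow = averageLow,
      averageHigh = averageHigh, medians = medians)
}

#' @exportClass MagnitudeThresholds
setClass("MagnitudeThresholds",
         representation(averageLow = "numeric", averageHigh = "numeric",
                        medians = "numeric"))

setMethod("show", "MagnitudeThresholds", function(object) {
  cat("MagnitudeThresholds: Average(low) =", object@averageLow,
      "| Average(high) =", object@averageHigh, "kJ/mol\n")
  print(object@medians)
})

# Region label from strict percentiles: [0,25) -> P1, [25,75) -> P2,
# [75,100] -> P3 (half-open so every percentile maps to one region).
.percentileRegion <- function(p) {
  ifelse(p < 25, "P1", ifelse(p < 75, "P2", "P3"))
}

.regionMedian <- function(values, regions, region) {
  v <- values[regions == region]
  if (!length(v)) median(values) else median(v)  # empty region: side median
}

#' Five-category magnitude classification of mutants
#'
#' Classifies every nonzero-\eqn{\Delta\Delta G} mutant into one of five
#' magnitude categories (\code{slight}, \code{low}, \code{moderate},
#' \code{high}, \code{very_high}) with a sign tag (stabilizing /
#' destabilizing). The recurrence-expanded \eqn{\Delta\Delta G} multiset is
#' split into stabilizing (>0) and destabilizing (<0) cohorts; within each
#' cohort, strict percentiles define regions P1 [0,25), P2 [25,75),
#' P3 [75,100] (ascending \eqn{\Delta\Delta G}); stabilizing P1/P2/P3 map
#' to low/moderate/high and destabilizing P1/P2/P3 to high/moderate/low.
#' Average(low) and Average(high) are means of region-median magnitudes
#' (see \code{\link{MagnitudeThresholds}}); low-region mutants with
#' \eqn{|\Delta\Delta G| <} Average(low) become \code{slight}, high-region
#' mutants with \eqn{|\Delta\Delta G| \ge} Average(high) become
#' \code{very_high}. Exact zeros are excluded and counted.
#'
#' @param mutants a \code{\link{MutantTable}} or data.frame; each side must
#'   contribute at least 4 recurrence-expanded values.
#' @return list with elements \code{thresholds}
#'   (\code{\link{MagnitudeThresholds}}), \code{categories} (a
#'   \code{DataFrame} with one row per nonzero mutant: \code{ddG},
#'   \code{sign}, \code{region}, \code{category}) and \code{nZeroExcluded}.
#' @examples
#' mt <- data.frame(protein_id = "p", substitution = "A1T",
#'                  ddG = c(seq(0.1, 1.2, by = 0.1),
#'                          -c(0.05, 0.1, 0.15, 0.2, 0.3, 0.4, 0.5,
#'                             0.6, 0.7, 2, 2.5, 3)),
#'                  ddS = 0, recurrence = 1L)
#' classifyMagnitude(mt)$thresholds
#' @export
classifyMagnitude <- function(mutants) {
  mt <- .asMutantTable(mutants)
  ddg <- mt$ddG
  rec <- mt$recurrence
  if (any(rec < 1L)) stop("invalid record: recurrence must be >= 1",
                          call. = FALSE)
  zero <- ddg == 0
  nZero <- sum(rep(as.integer(zero), rec))
  keep <- which(!zero)
  sideOf <- ifelse(ddg > 0, "stabilizing", "destabilizing")

  expanded <- list(
    stabilizing = rep(ddg[ddg > 0], rec[ddg > 0]),
    destabilizing = rep(ddg[ddg < 0], rec[ddg < 0]))
  for (side in names(expanded)) {
    if (length(expanded[[side]]) < 4L) {
      stop("degenerate cohort: fewer than 4 recurrence-expanded ",
           side, " values", call. = FALSE)
    }
  }

  # Region medians on the expanded multisets (percentiles of each expanded
  # value within its own side, ascending ddG).
  regionsExp <- lapply(expanded, function(v) {
    .percentileRegion(.strictPercentile(v, v))
  })
  medians <- c(
    median_P1_stabilizing =
      .regionMedian(expanded$stabilizing, regionsExp$stabilizing, "P1"),
    median_P3_stabilizing =
      .regionMedian(expanded$stabilizing, regionsExp$stabilizing, "P3"),
    median_P1_destabilizing =
      .regionMedian(expanded$destabilizing, regionsExp$destabilizing, "P1"),
    median_P3_destabilizing =
      .regionMedian(expanded$destabilizing, regionsExp$destabilizing, "P3"))
  averageLow <- (abs(medians[["median_P1_stabilizing"]]) +
                 abs(medians[["median_P3_destabilizing"]])) / 2
  averageHigh <- (abs(medians[["median_P3_stabilizing"]]) +
                  abs(medians[["median_P1_destabilizing"]])) / 2

  # Per-mutant region and category (copies of one mutant share its ddG, so
  # per-row percentiles against the expanded multiset are equivalent to
  # expansion-first classification).
  side <- sideOf[keep]
  val <- ddg[keep]
  p <- numeric(length(val))
  p[side == "stabilizing"] <-
    .strictPercentile(expanded$stabilizing, val[side == "stabilizing"])
  p[side == "destabilizing"] <-
    .strictPercentile(expanded$destabilizing, val[side == "destabilizing"])
  region <- .percentileRegion(p)
  category <- ifelse(side == "stabilizing",
                     c(P1 = "low", P2 = "moderate", P3 = "high")[region],
                     c(P1 = "high", P2 = "moderate", P3 = "low")[region])
  # threshold comparisons carry a relative epsilon so that values which
  # are exactly on a threshold in real arithmetic are not misclassified
  # by floating-point noise in the averaged medians
  epsL <- 1e-9 * (1 + averageLow)
  epsH <- 1e-9 * (1 + averageHigh)
  category[category == "low" & abs(val) < averageLow - epsL] <- "slight"
  category[category == "high" & abs(val) >= averageHigh - epsH] <-
    "very_high"

  cats <- DataFrame(
    protein_id = mt$protein_id[keep],
    substitution = mt$substitution[keep],
    ddG = val,
    recurrence = rec[keep],
    sign = side,
    region = region,
    category = factor(category, levels = c("slight", "low", "moderate",
                                           "high", "very_high")))
  list(thresholds = MagnitudeThresholds(averageLow, averageHigh, medians),
       categories = cats,
       nZeroExcluded = nZero)
}

#' Screen mutants for high structural impact
#'
#' Retains mutants with \eqn{\Delta\Delta G \ge} \code{+cutoff} or
#' \eqn{\le} \code{-cutoff} (both inclusive), preserving row order. The
#' default cutoff of 1.24 kJ/mol marks highly stabilizing/destabilizing
#' mutants.
#'
#' @param mutants a \code{\link{MutantTable}} or data.frame.
#' @param cutoff positive threshold in kJ/mol.
#' @return the filtered \code{MutantTable}.
#' @examples
#' screenHighImpact(data.frame(protein_id = "p", substitution = "A1T",
#'                             ddG = c(1.3, -1.3, 0.5), ddS = 0,
#'                             recurrence = 1L))
#' @export
screenHighImpact <- function(mutants, cutoff = 1.24) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0) {
    stop("cutoff must be a single positive number", call. = FALSE)
  }
  mt <- .asMutantTable(mutants)
  mt[!is.na(mt$ddG) & abs(mt$ddG) >= cutoff, , drop = FALSE]
}

#' Stability-flexibility trend report
#'
#' Pearson correlation, two-sided p-value, least-squares regression of
#' \eqn{\Delta\Delta G} on \eqn{\Delta\Delta S} and the pointwise 95\%
#' confidence band of the mean line. Rows with undefined values
#' (frameshifts) are skipped.
#'
#' @param mutants a \code{\link{MutantTable}} or data.frame with at least 3
#'   complete (\code{ddG}, \code{ddS}) rows.
#' @return list with \code{r}, \code{p}, \code{slope}, \code{intercept},
#'   \code{n} and \code{band} (data.frame \code{ddS}, \code{fit},
#'   \code{lower}, \code{upper}).
#' @export
stabilityFlexibilityTrend <- function(mutants) {
  mt <- .asMutantTable(mutants)
  ok <- is.finite(mt$ddG) & is.finite(mt$ddS)
  ddG <- mt$ddG[ok]; ddS <- mt$ddS[ok]
  if (length(ddG) < 3L) {
    stop("at least 3 mutants with finite (ddG, ddS) are required",
         call. = FALSE)
  }
  if (sd(ddG) == 0 || sd(ddS) == 0) {
    stop("undefined correlation: constant input", call. = FALSE)
  }
  ct <- cor.test(ddS, ddG, method = "pearson")
  fit <- lm(ddG ~ ddS)
  grid <- data.frame(ddS = seq(min(ddS), max(ddS), length.out = 100L))
  pred <- predict(fit, newdata = grid, interval = "confidence",
                  level = 0.95)
  list(r = unname(ct$estimate),
       p = ct$p.value,
       slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       n = length(ddG),
       band = data.frame(ddS = grid$ddS, fit = pred[, "fit"],
                         lower = pred[, "lwr"], upper = pred[, "upr"]))
}

#' Deleteriousness call from a SIFT-type score
#'
#' Scores below 0.05 (strict) are called loss-of-function, scores of 0.05
#' or above neutral; missing scores are unclassified.
#'
#' @param siftScore numeric vector in [0, 1]; NA allowed.
#' @return factor with levels \code{loss_of_function}, \code{neutral},
#'   \code{unclassified}.
#' @examples
#' classifyFunction(c(0.04, 0.05, NA))
#' @export
classifyFunction <- function(siftScore) {
  if (any(siftScore < 0 | siftScore > 1, na.rm = TRUE)) {
    stop("invalid score: SIFT scores must lie in [0, 1]", call. = FALSE)
  }
  out <- ifelse(is.na(siftScore), "unclassified",
                ifelse(siftScore < 0.05, "loss_of_function", "neutral"))
  factor(out, levels = c("loss_of_function", "neutral", "unclassified"))
}
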