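# Shared cohort statistics: paired differentials, z-score flags, group
# splits, Kaplan-Meier / log-rank / Cox survival, rank comparisons and
# correlation reports.

#' Paired tumor/normal differential analysis
#'
#' Per feature, the log2 fold change is the mean over tumor/normal pairs
#' of the paired difference on the log scale (for ratio-scale inputs,
#' the log2 of the tumor/normal ratio); significance is a two-sided paired
#' Student t-test with Benjamini-Hochberg FDR across features. Features
#' with fewer than \code{minPairs} complete pairs are excluded and
#' counted. Zero-variance paired differences yield p = 1 by convention.
#'
#' @param x a \code{\link{FeatureMatrix}} with \code{pair_id}/\code{tissue}
#'   pairing columns.
#' @param minPairs minimum number of complete tumor/normal pairs per
#'   feature (default 10).
#' @return list with \code{results} (\code{DataFrame}: \code{feature},
#'   \code{log2_fold_change}, \code{p}, \code{fdr}, \code{n_pairs}) and
#'   \code{excluded} (features dropped by the pair filter, with counts).
#' @export
pairedDifferential <- function(x, minPairs = 10L) {
  if (!is(x, "FeatureMatrix") || is.null(pairId(x)) ||
      is.null(tissueType(x))) {
    stop("pairing error: tumor/normal pairing (pair_id, tissue) is required",
         call. = FALSE)
  }
  pid <- pairId(x); tis <- tissueType(x)
  if (anyNA(pid)) {
    stop("pairing error: unpaired sample present with pairing requested",
         call. = FALSE)
  }
  m <- featureValues(x)
  tumor <- m[, tis == "tumor", drop = FALSE]
  normal <- m[, tis == "normal", drop = FALSE]
  normal <- normal[, match(pid[tis == "tumor"], pid[tis == "normal"]),
                   drop = FALSE]
  d <- if (identical(valueScale(x), "ratio")) {
    log2(tumor / normal)
  } else {
    tumor - normal
  }
  nPairs <- rowSums(is.finite(d))
  keep <- nPairs >= minPairs
  stat <- vapply(which(keep), function(i) {
    di <- d[i, ][is.finite(d[i, ])]
    # zero-variance differences (up to fp noise): p = 1 by convention
    if (sd(di) <= 1e-10 * (abs(mean(di)) + 1)) c(mean(di), 1) else {
      c(mean(di), t.test(di)$p.value)
    }
  }, numeric(2))
  results <- DataFrame(feature = rownames(d)[keep],
                       log2_fold_change = unname(stat[1, ]),
                       p = unname(stat[2, ]),
                       fdr = .bh(unname(stat[2, ])),
                       n_pairs = unname(nPairs[keep]))
  list(results = results,
       excluded = DataFrame(feature = rownames(d)[!keep],
                            n_pairs = unname(nPairs[!keep])))
}

#' Flag expression z-scores
#'
#' z >= cutoff flags \code{up}, z <= -cutoff flags \code{down} (both
#' inclusive), otherwise \code{none}. The default cutoff of 1.96
#' corresponds to two-sided p < 0.05.
#'
#' @param z finite numeric z-scores.
#' @param cutoff positive threshold.
#' @return factor with levels \code{up}, \code{down}, \code{none}.
#' @examples
#' zscoreFlag(c(2.1, -1.96, 0))
#' @export
zscoreFlag <- function(z, cutoff = 1.96) {
  .checkFinite(z, "z score")
  factor(ifelse(z >= cutoff, "up", ifelse(z <= -cutoff, "down", "none")),
         levels = c("up", "down", "none"))
}

#' z-scores against a reference cohort
#'
#' Standardizes values against the mean and SD of a reference cohort
#' (e.g. expression of altered samples against the unaltered cohort of the
#' same feature).
#'
#' @param values numeric vector to standardize.
#' @param reference numeric reference cohort with positive SD.
#' @return numeric z-scores.
#' @export
zscoreAgainst <- function(values, reference) {
  s <- sd(reference)
  if (!is.finite(s) || s == 0) {
    stop("reference cohort has zero variance", call. = FALSE)
  }
  (values - mean(reference)) / s
}

#' Split samples into high/low groups on a feature
#'
#' Median scheme: values above the median are \code{high}, ties and below
#' are \code{low}. Quartile scheme: values at or above the 75th strict
#' percentile are \code{high}, at or below the 25th are \code{low}, the
#' middle half is \code{excluded} (percentile by the strictly-below
#' nearest-rank convention).
#'
#' @param x a \code{\link{FeatureMatrix}}, matrix, or named numeric vector;
#'   at least 4 samples. For paired matrices only tumor columns are used,
#'   keyed by \code{pair_id}.
#' @param feature feature to split on (ignored for a vector input).
#' @param scheme \code{"median"} or \code{"quartile"}.
#' @return named factor over samples with levels \code{low}, \code{high},
#'   \code{excluded} and attribute \code{"scheme"}.
#' @export
splitGroups <- function(x, feature = NULL,
                        scheme = c("median", "quartile")) {
  scheme <- match.arg(scheme)
  if (is.numeric(x) && is.null(dim(x))) {
    values <- x
  } else {
    m <- .valuesMatrix(x)
    if (is(x, "FeatureMatrix") && !is.null(tissueType(x))) {
      tumor <- tissueType(x) == "tumor"
      m <- m[, tumor, drop = FALSE]
      colnames(m) <- pairId(x)[tumor]
    }
    if (is.null(feature) || !feature %in% rownames(m)) {
      stop("unknown feature: '", feature, "'", call. = FALSE)
    }
    values <- m[feature, ]
  }
  if (length(values) < 4L) {
    stop("at least 4 samples are required", call. = FALSE)
  }
  if (length(unique(values)) == 1L) {
    stop("degenerate split: all values identical", call. = FALSE)
  }
  if (scheme == "median") {
    grp <- ifelse(values > median(values), "high", "low")
  } else {
    p <- .strictPercentile(values, values)
    grp <- ifelse(p >= 75, "high", ifelse(p <= 25, "low", "excluded"))
  }
  out <- factor(grp, levels = c("low", "high", "excluded"))
  names(out) <- names(values)
  attr(out, "scheme") <- scheme
  out
}

# Align a group assignment with a survival table, dropping excluded and
# unassigned samples. Level order is preserved from the assignment factor
# (low before high for splitGroups output) or order of first appearance,
# so the Cox coefficient is oriented as "second level vs first".
.survivalGroups <- function(survival, groups) {
  if (is.null(groups)) {
    grp <- survival$group
    keep <- rep(TRUE, nrow(survival))
    lev <- unique(grp)
  } else {
    grp <- as.character(groups[survival$sample])
    keep <- !is.na(grp) & grp != "excluded"
    lev <- if (is.factor(groups)) {
      setdiff(levels(groups), "excluded")
    } else {
      unique(grp[keep])
    }
  }
  list(time = survival$time[keep], event = survival$event[keep],
       group = factor(grp[keep], levels = lev))
}

#' Kaplan-Meier curves per group
#'
#' Product-limit estimates with Greenwood variance and log-log 95\%
#' confidence intervals. Curves start at 1 and are nonincreasing;
#' censoring never decreases the estimate. Groups without events are
#' reported with a warning (their CI is undefined over most of the curve).
#'
#' @param survival a \code{\link{SurvivalData}} table.
#' @param groups optional named factor over samples (e.g. from
#'   \code{\link{splitGroups}}); \code{excluded} samples are dropped.
#'   Defaults to the table's \code{group} column.
#' @return \code{DataFrame} of step-curve coordinates: \code{group},
#'   \code{time}, \code{n_risk}, \code{n_event}, \code{surv},
#'   \code{lower}, \code{upper}.
#' @export
kmCurves <- function(survival, groups = NULL) {
  g <- .survivalGroups(survival, groups)
  byGroup <- split(seq_along(g$time), g$group)
  noEvent <- vapply(byGroup, function(i) sum(g$event[i]) == 0L, logical(1))
  if (any(noEvent)) {
    warning("group(s) without events: ",
            paste(names(byGroup)[noEvent], collapse = ", "),
            "; confidence interval undefined")
  }
  fit <- survfit(Surv(g$time, g$event) ~ g$group, conf.type = "log-log")
  strata <- if (is.null(fit$strata)) {
    rep(levels(g$group)[1], length(fit$time))
  } else {
    rep(sub("^g\\$group=", "", names(fit$strata)), fit$strata)
  }
  DataFrame(group = strata, time = fit$time, n_risk = fit$n.risk,
            n_event = fit$n.event, surv = fit$surv,
            lower = fit$lower, upper = fit$upper)
}

#' Log-rank test across groups
#'
#' Standard log-rank chi-square comparing survival across two or more
#' groups.
#'
#' @inheritParams kmCurves
#' @return list with \code{chisq}, \code{df} and \code{p}.
#' @export
logrankTest <- function(survival, groups = NULL) {
  g <- .survivalGroups(survival, groups)
  if (nlevels(droplevels(g$group)) < 2L) {
    stop("invalid grouping: at least two groups are required",
         call. = FALSE)
  }
  sdf <- survdiff(Surv(g$time, g$event) ~ g$group)
  df <- length(sdf$n) - 1L
  list(chisq = sdf$chisq, df = df,
       p = pchisq(sdf$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards ratio between two groups
#'
#' Single-covariate Cox fit (group indicator, Breslow tie handling).
#' Returns the hazard ratio of the second factor level relative to the
#' first with its Wald 95\% CI, and the worse-survival direction by the
#' coefficient sign rule: a positive coefficient flags the indicator
#' (second) group as having worse survival.
#'
#' @inheritParams kmCurves
#' @return list with \code{hr}, \code{ci_lower}, \code{ci_upper},
#'   \code{coef}, \code{se}, \code{p}, \code{worse_group} and
#'   \code{reference_group}.
#' @export
coxHazardRatio <- function(survival, groups = NULL) {
  g <- .survivalGroups(survival, groups)
  g$group <- droplevels(g$group)
  if (nlevels(g$group) != 2L) {
    stop("exactly two groups are required", call. = FALSE)
  }
  if (any(tapply(g$event, g$group, sum) == 0L)) {
    stop("each group needs at least one event", call. = FALSE)
  }
  # monotone likelihoods make coxph warn about infinite coefficients;
  # that case is detected and reported as an error below
  fit <- suppressWarnings(coxph(Surv(g$time, g$event) ~ g$group,
                                ties = "breslow"))
  beta <- unname(coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15) {
    stop("non-convergence: monotone likelihood or complete separation ",
         "(|coef| = ", format(abs(beta)), ", se = ", format(se), ")",
         call. = FALSE)
  }
  lv <- levels(g$group)
  list(hr = exp(beta),
       ci_lower = exp(beta - 1.96 * se),
       ci_upper = exp(beta + 1.96 * se),
       coef = beta, se = se,
       p = 2 * pnorm(-abs(beta / se)),
       worse_group = if (beta > 0) lv[2] else lv[1],
       reference_group = lv[1])
}

#' Kruskal-Wallis rank comparison across groups
#'
#' Kruskal-Wallis chi-square test over k groups; with
#' \code{pairwise = TRUE} the two-group test is applied to each pair of
#' groups (no adjustment; the mode is recorded in the result).
#'
#' @param values named list of numeric vectors, one per group (>= 2
#'   groups, each non-empty).
#' @param pairwise apply the two-group test to every pair instead of one
#'   global test.
#' @return for the global mode, list with \code{chisq}, \code{df},
#'   \code{p}, \code{mode}; for pairwise, a \code{DataFrame} of pairs.
#' @export
rankCompare <- function(values, pairwise = FALSE) {
  if (!is.list(values) || length(values) < 2L) {
    stop("at least two groups are required", call. = FALSE)
  }
  if (any(lengths(values) == 0L)) {
    stop("every group must be non-empty", call. = FALSE)
  }
  if (any(lengths(values) < 2L)) {
    warning("group(s) with fewer than 2 observations")
  }
  if (is.null(names(values))) {
    names(values) <- paste0("g", seq_along(values))
  }
  if (!pairwise) {
    kt <- kruskal.test(values)
    return(list(chisq = unname(kt$statistic),
                df = unname(kt$parameter),
                p = kt$p.value, mode = "global"))
  }
  pairs <- combn(names(values), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    kt <- kruskal.test(values[pairs[, i]])
    DataFrame(group_a = pairs[1, i], group_b = pairs[2, i],
              chisq = unname(kt$statistic), p = kt$p.value)
  })
  res <- do.call(rbind, rows)
  metadata(res)$mode <- "pairwise"
  res
}

#' Correlation report
#'
#' Pearson or Spearman correlation with two-sided p-value; for Pearson the
#' Fisher-z 95\% confidence interval is included. Incomplete observations
#' are dropped pairwise and counted.
#'
#' @param x,y numeric vectors of equal length (>= 3 complete pairs).
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return list with \code{r}, \code{p}, \code{ci_lower}, \code{ci_upper}
#'   (NA for Spearman), \code{n} (complete pairs used) and
#'   \code{n_dropped}.
#' @export
correlationTest <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  ok <- is.finite(x) & is.finite(y)
  xs <- x[ok]; ys <- y[ok]
  if (length(xs) < 3L) {
    stop("at least 3 complete pairs are required", call. = FALSE)
  }
  if (sd(xs) == 0 || sd(ys) == 0) {
    stop("undefined correlation: constant vector", call. = FALSE)
  }
  ct <- if (method == "pearson") {
    cor.test(xs, ys, method = "pearson")
  } else {
    cor.test(xs, ys, method = "spearman", exact = FALSE)
  }
  ci <- if (method == "pearson") ct$conf.int else c(NA_real_, NA_real_)
  list(r = unname(ct$estimate), p = ct$p.value,
       ci_lower = ci[1], ci_upper = ci[2],
       n = length(xs), n_dropped = sum(!ok), method = method)
}
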