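# Paired differentials, group splits, survival statistics, rank and
# correlation reports.

makePaired <- function(tumor, normal, scale = "log2(TPM+1)") {
  n <- ncol(tumor)
  samples <- sprintf("P%02d", seq_len(n))
  values <- cbind(tumor, normal)
  colnames(values) <- c(paste0(samples, "_T"), paste0(samples, "_N"))
  FeatureMatrix(values, pairId = c(samples, samples),
                tissue = rep(c("tumor", "normal"), each = n),
                valueScale = scale)
}

test_that("paired differential reproduces the fold-change contract on both scales", {
  normal <- matrix(2, 1, 12, dimnames = list("f1", NULL))
  tumor <- normal * 2
  fm <- makePaired(tumor, normal, scale = "ratio")
  res <- pairedDifferential(fm)$results
  expect_equal(res$log2_fold_change, 1)       # log2 of the 2x ratio
  expect_equal(res$p, 1)                      # zero-variance differences

  set.seed(6)
  normal2 <- matrix(rnorm(24, 5), 2, 12, dimnames = list(c("f1", "f2"),
                                                         NULL))
  fm2 <- makePaired(normal2 + 1, normal2)     # log-scale: diff = +1
  res2 <- pairedDifferential(fm2)$results
  expect_equal(res2$log2_fold_change, c(1, 1))
  expect_equal(res2$p, c(1, 1))

  identical_fm <- makePaired(normal2, normal2)
  res3 <- pairedDifferential(identical_fm)$results
  expect_equal(res3$log2_fold_change, c(0, 0))
  expect_equal(res3$p, c(1, 1))
})

test_that("features with fewer than the minimum pairs are excluded and counted", {
  set.seed(7)
  normal <- matrix(rnorm(18, 5), 2, 9, dimnames = list(c("f1", "f2"),
                                                       NULL))
  fm <- makePaired(normal + rnorm(18, 0.5), normal)
  out <- pairedDifferential(fm, minPairs = 10)
  expect_identical(NROW(out$results), 0L)
  expect_identical(out$excluded$feature, c("f1", "f2"))
  out2 <- pairedDifferential(fm, minPairs = 9)
  expect_identical(NROW(out2$results), 2L)
  expect_true(all(diff(out2$results$fdr[order(out2$results$p)]) >= 0))

  unpaired <- FeatureMatrix(normal)
  expect_error(pairedDifferential(unpaired), "pairing")
})

test_that("z-score flags use the inclusive 1.96 cutoff", {
  expect_identical(as.character(zscoreFlag(c(2.1, -1.96, 0, 1.95))),
                   c("up", "down", "none", "none"))
  expect_error(zscoreFlag(NA), "invalid value")
  z <- zscoreAgainst(c(10, 12), reference = c(8, 9, 10, 11, 12))
  expect_equal(z, (c(10, 12) - 10) / sd(c(8, 9, 10, 11, 12)))
})

test_that("median and quartile splits follow the shared percentile conventions", {
  v <- setNames(sample(1:100), paste0("s", 1:100))
  q <- splitGroups(v, scheme = "quartile")
  expect_identical(sum(q == "high"), 25L)
  expect_identical(sum(q == "low"), 26L)   # 26 values have percentile <= 25
  expect_identical(sum(q == "excluded"), 49L)

  m <- splitGroups(v, scheme = "median")
  expect_lte(abs(sum(m == "high") - sum(m == "low")), 1L)

  ties <- setNames(c(1, 2, 2, 2, 9, 10), paste0("s", 1:6))
  mt <- splitGroups(ties, scheme = "median")  # median is 2
  expect_identical(as.character(mt[2:4]), rep("low", 3))  # ties at median

  expect_error(splitGroups(rep(1, 10), scheme = "median"), "degenerate")
})

test_that("KM curves equal the empirical survival function without censoring and a hand product-limit table with censoring", {
  sv <- SurvivalData(paste0("s", 1:8), time = c(1, 2, 3, 4, 5, 6, 7, 8),
                     event = 1)
  km <- kmCurves(sv)
  expect_equal(km$surv, (7:0) / 8)
  expect_true(all(diff(km$surv) <= 0))
  expect_equal(max(km$surv), 7 / 8)

  flat <- SurvivalData(paste0("s", 1:5), time = 1:5, event = 0)
  expect_warning(kmFlat <- kmCurves(flat), "without events")
  expect_true(all(kmFlat$surv == 1))

  # n = 12 with censoring: compare stepwise to an independent hand oracle
  set.seed(9)
  time <- c(2, 3, 3, 5, 6, 6, 8, 9, 11, 12, 14, 15)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 0, 1, 1)
  sv12 <- SurvivalData(paste0("s", 1:12), time, event)
  km12 <- kmCurves(sv12)
  oracle <- kmHand(time, event)
  merged <- merge(as.data.frame(km12), oracle, by = "time")
  expect_equal(merged$surv.x, merged$surv.y, tolerance = 1e-12)
})

test_that("log-rank test is null on identical groups and powerful under a planted hazard ratio", {
  sv <- SurvivalData(paste0("s", 1:20),
                     time = rep(c(1, 2, 3, 4, 6, 7, 9, 11, 13, 17), 2),
                     event = rep(c(1, 1, 0, 1, 1, 0, 1, 1, 1, 1), 2),
                     group = rep(c("a", "b"), each = 10))
  lr <- logrankTest(sv)
  expect_gt(lr$p, 0.95)

  single <- SurvivalData(paste0("s", 1:10), time = 1:10, event = 1)
  expect_error(logrankTest(single), "invalid grouping")

  b <- generateCohort(pairSpec(seed = 3, n = 2000, or = NULL))
  expect_lt(logrankTest(survivalData(b))$p, 1e-6)
})

test_that("Cox hazard ratio is null for identical groups, recovers planted effects and applies the sign rule", {
  sv <- SurvivalData(paste0("s", 1:40),
                     time = rep(c(1, 2, 3, 5, 7, 8, 9, 11, 12, 15), 4),
                     event = rep(c(1, 0, 1, 1, 1, 0, 1, 1, 1, 1), 4),
                     group = rep(c("a", "b"), each = 20))
  cox <- coxHazardRatio(sv)
  expect_equal(cox$hr, 1, tolerance = 1e-6)
  expect_true(cox$ci_lower < 1 && cox$ci_upper > 1)

  b <- generateCohort(pairSpec(seed = 8, n = 2000, or = NULL))
  cox2 <- coxHazardRatio(survivalData(b))
  expect_true(cox2$hr > 1.7 && cox2$hr < 2.3)
  expect_gt(cox2$coef, 0)
  expect_identical(cox2$worse_group, "high")  # positive coef: high is worse

  sep <- SurvivalData(paste0("s", 1:20),
                      time = c(1:10, 101:110),
                      event = 1,
                      group = rep(c("early", "late"), each = 10))
  expect_error(coxHazardRatio(sep), "non-convergence")
})

test_that("log-rank direction agrees with the Cox hazard ratio on separated data", {
  b <- generateCohort(pairSpec(seed = 12, n = 1000, or = NULL))
  cox <- coxHazardRatio(survivalData(b))
  km <- kmCurves(survivalData(b))
  kmdf <- as.data.frame(km)
  medSurv <- function(g) {
    sub <- kmdf[kmdf$group == g, ]
    min(sub$time[sub$surv <= 0.5])
  }
  expect_gt(cox$hr, 1)
  expect_lt(medSurv("high"), medSurv("low"))  # worse group's curve is lower
})

test_that("rank comparison matches the rank-sum correspondence for two groups", {
  set.seed(10)
  for (i in 1:5) {
    a <- rnorm(40); bb <- rnorm(40, mean = 0.5)
    kw <- rankCompare(list(a = a, b = bb))
    wc <- wilcox.test(a, bb, correct = FALSE, exact = FALSE)
    expect_equal(kw$p, wc$p.value, tolerance = 1e-10)
  }
  pw <- rankCompare(list(a = rnorm(20), b = rnorm(20), c = rnorm(20)),
                    pairwise = TRUE)
  expect_identical(NROW(pw), 3L)
  expect_error(rankCompare(list(a = 1:3)), "at least two")
  expect_error(rankCompare(list(a = 1:3, b = numeric(0))), "non-empty")
  expect_warning(rankCompare(list(a = 1, b = 1:9)), "fewer than 2")
})

test_that("rank comparison has power against a shifted distribution", {
  hits <- 0
  for (i in 1:40) {
    set.seed(300 + i)
    p <- rankCompare(list(a = rnorm(100), b = rnorm(100, 1)))$p
    if (p < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 38)
})

test_that("correlation report handles linear, monotone and missing data", {
  x <- 1:20
  lin <- correlationTest(x, 2 * x + 3)
  expect_equal(lin$r, 1)
  mono <- correlationTest(x, exp(x / 4), method = "spearman")
  expect_equal(mono$r, 1)
  monoP <- correlationTest(x, exp(x / 4), method = "pearson")
  expect_lt(monoP$r, 1)
  expect_true(monoP$ci_lower < monoP$r && monoP$ci_upper > monoP$r)

  xm <- c(x, NA); ym <- c(2 * x + 3, 5)
  withNA <- correlationTest(xm, ym)
  expect_identical(withNA$n, 20L)
  expect_identical(withNA$n_dropped, 1L)

  expect_error(correlationTest(rep(1, 10), rnorm(10)), "undefined")
  expect_error(correlationTest(1:3, 1:4), "equal length")
})

test_that("null correlations are small with approximately uniform p-values", {
  rs <- numeric(100); ps <- numeric(100)
  for (i in 1:100) {
    set.seed(700 + i)
    ct <- correlationTest(rnorm(1000), rnorm(1000))
    rs[i] <- ct$r; ps[i] <- ct$p
  }
  expect_true(all(abs(rs) < 0.12))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
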