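# Stability landscape: deltas, quadrants, percentile machinery, the
# five-category magnitude scheme and the trend report.

test_that("stability and affinity deltas follow their sign contracts", {
  expect_equal(stabilityDelta(-5, -7), 2)
  expect_equal(stabilityDelta(3.2, 3.2), 0)
  expect_equal(stabilityDelta(-7, -5), -2)
  expect_error(stabilityDelta(Inf, 1), "invalid value")

  up <- affinityShift(-5, -3)
  expect_equal(up$shift, 2)
  expect_identical(up$call, "unfavorable")
  same <- affinityShift(-4, -4)
  expect_equal(same$shift, 0)
  expect_identical(same$call, "neutral")
  down <- affinityShift(-3, -5)
  expect_equal(down$shift, -2)
  expect_identical(down$call, "favorable")
})

test_that("quadrant labels partition mutants with nonzero ddG and ddS", {
  expect_identical(as.character(assignQuadrant(c(2, 2, -2, -2, 0, 3, NA),
                                               c(1, -1, -1, 1, 3, 0, 1))),
                   c("Q1", "Q2", "Q3", "Q4", "boundary", "boundary", NA))
  set.seed(1)
  for (i in 1:5) {
    ddG <- rnorm(200); ddS <- rnorm(200)
    q <- assignQuadrant(ddG, ddS)
    expect_identical(sum(table(q)), 200L)   # exhaustive and exclusive
    expect_false(anyNA(q))
  }
})

test_that("recurrence expansion replicates values by their weights", {
  mt <- data.frame(protein_id = "p", substitution = c("A1T", "A2T"),
                   ddG = c(1.5, -0.5), ddS = 0, recurrence = c(2L, 1L))
  expect_equal(expandByRecurrence(mt), c(1.5, 1.5, -0.5))
  mt$recurrence <- c(1L, 1L)
  expect_equal(expandByRecurrence(mt), mt$ddG)
  set.seed(2)
  rmt <- randomMutantTable(2, n = 50)
  expect_length(expandByRecurrence(rmt), sum(rmt$recurrence))
  bad <- rmt; bad$recurrence[1] <- 0L
  expect_error(MutantTable(bad), "recurrence")
})

test_that("percentileOf implements the strictly-below nearest-rank formula and matches a sort-and-count oracle", {
  expect_equal(percentileOf(c(10, 20, 30, 40), 30), 50)
  expect_equal(percentileOf(c(10, 20, 30, 40), 10), 0)
  expect_error(percentileOf(numeric(0), 1), "empty")
  for (seed in 1:10) {
    set.seed(seed)
    v <- sample(round(rnorm(100), 2), 100, replace = TRUE)  # with ties
    oracle <- vapply(v, function(x) 100 * sum(sort(v) < x) / length(v),
                     numeric(1))
    expect_identical(percentileOf(v, v), oracle)
  }
})

test_that("magnitude classifier reproduces the hand-computed 24-value example", {
  stab <- seq(0.1, 1.2, by = 0.1)
  destab <- -c(0.05, 0.1, 0.15, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 2, 2.5, 3)
  mt <- data.frame(protein_id = "p",
                   substitution = paste0("A", 1:24, "T"),
                   ddG = c(stab, destab), ddS = 0, recurrence = 1L)
  res <- classifyMagnitude(mt)
  expect_equal(res$thresholds@averageLow, 0.15)
  expect_equal(res$thresholds@averageHigh, 1.8)
  catOf <- function(x) {
    vapply(x, function(xi) {
      as.character(res$categories$category[
        which(abs(res$categories$ddG - xi) < 1e-9)[1]])
    }, character(1))
  }
  expect_identical(catOf(0.1), "slight")
  expect_identical(catOf(c(1.0, 1.1, 1.2)), rep("high", 3))
  expect_identical(catOf(c(-2, -2.5, -3)), rep("very_high", 3))
  expect_identical(catOf(c(-0.05, -0.1)), rep("slight", 2))
  expect_identical(catOf(-0.15), "low")
})

test_that("mirror-symmetric cohorts yield mirrored thresholds and category counts", {
  set.seed(8)
  stab <- runif(40, 0.05, 3)
  mt <- data.frame(protein_id = "p",
                   substitution = paste0("A", 1:80, "T"),
                   ddG = c(stab, -stab), ddS = 0, recurrence = 1L)
  res <- classifyMagnitude(mt)
  tab <- table(as.character(res$categories$category),
               res$categories$sign)
  expect_equal(unname(tab[, "stabilizing"]), unname(tab[, "destabilizing"]))
  m <- res$thresholds@medians
  expect_equal(abs(m[["median_P1_stabilizing"]]),
               abs(m[["median_P3_destabilizing"]]))
  expect_equal(abs(m[["median_P3_stabilizing"]]),
               abs(m[["median_P1_destabilizing"]]))
})

test_that("all-tied stabilizing values collapse into one region without slight or very_high reassignments", {
  mt <- data.frame(protein_id = "p",
                   substitution = paste0("A", 1:16, "T"),
                   ddG = c(rep(1, 8), -seq(0.1, 0.8, by = 0.1)),
                   ddS = 0, recurrence = 1L)
  res <- classifyMagnitude(mt)
  stabCats <- as.character(res$categories$category[
    res$categories$sign == "stabilizing"])
  expect_true(all(stabCats == "low"))
  expect_true(res$thresholds@averageLow < 1)
})

test_that("category assignment conserves counts, is monotone in |ddG| and is invariant to doubling recurrences", {
  sev <- c(slight = 1, low = 2, moderate = 3, high = 4, very_high = 5)
  for (seed in 1:10) {
    mt <- randomMutantTable(seed, n = 200)
    res <- classifyMagnitude(mt)
    nonzero <- sum(mt$ddG != 0)
    expect_identical(NROW(res$categories) + sum(mt$ddG == 0), nrow(mt))
    for (side in c("stabilizing", "destabilizing")) {
      sub <- res$categories[res$categories$sign == side, ]
      ord <- order(abs(sub$ddG))
      expect_true(all(diff(sev[as.character(sub$category)[ord]]) >= 0))
    }
    doubled <- mt
    doubled$recurrence <- mt$recurrence * 2L
    res2 <- classifyMagnitude(doubled)
    expect_equal(res$thresholds@averageLow, res2$thresholds@averageLow)
    expect_equal(res$thresholds@averageHigh, res2$thresholds@averageHigh)
    expect_identical(as.character(res$categories$category),
                     as.character(res2$categories$category))
  }
})

test_that("degenerate sides are rejected with the side named", {
  mt <- data.frame(protein_id = "p", substitution = paste0("A", 1:6, "T"),
                   ddG = c(1, 2, 3, 4, 5, -1), ddS = 0, recurrence = 1L)
  expect_error(classifyMagnitude(mt), "destabilizing")
})

test_that("high-impact screen keeps |ddG| >= cutoff inclusively and preserves order", {
  mt <- data.frame(protein_id = "p", substitution = paste0("A", 1:4, "T"),
                   ddG = c(1.3, -1.3, 0.5, 1.24), ddS = 0, recurrence = 1L)
  kept <- screenHighImpact(mt)
  expect_equal(kept$ddG, c(1.3, -1.3, 1.24))
  empty <- screenHighImpact(mt[0, ])
  expect_identical(NROW(empty), 0L)
  expect_error(screenHighImpact(mt, cutoff = -1), "positive")
})

test_that("trend report recovers perfect anticorrelation and the planted -0.75 correlation", {
  mt <- data.frame(protein_id = "p", substitution = paste0("A", 1:20, "T"),
                   ddG = -seq(-2, 2, length.out = 20),
                   ddS = seq(-2, 2, length.out = 20), recurrence = 1L)
  tr <- stabilityFlexibilityTrend(mt)
  expect_equal(tr$r, -1)
  expect_equal(tr$slope, -1)

  big <- generateMutantTable(CohortSpec(nSamples = 100, nMutants = 5000,
                                        seed = 31))
  tr2 <- stabilityFlexibilityTrend(big)
  expect_lt(abs(tr2$r - (-0.75)), 0.05)
  expect_lt(tr2$p, 1e-10)

  const <- mt; const$ddG <- 1
  expect_error(stabilityFlexibilityTrend(const), "constant")
})

test_that("under independence the trend correlation is near zero with approximately uniform p-values", {
  ps <- numeric(200)
  for (i in 1:200) {
    set.seed(1000 + i)
    mt <- data.frame(protein_id = "p",
                     substitution = paste0("A", 1:200, "T"),
                     ddG = rnorm(200), ddS = rnorm(200), recurrence = 1L)
    tr <- stabilityFlexibilityTrend(mt)
    ps[i] <- tr$p
    if (i == 1) expect_lt(abs(tr$r), 0.2)
  }
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("SIFT threshold calls are strict at 0.05 and tolerate missing scores", {
  calls <- classifyFunction(c(0.04, 0.05, NA, 0.5))
  expect_identical(as.character(calls),
                   c("loss_of_function", "neutral", "unclassified",
                     "neutral"))
  expect_error(classifyFunction(1.2), "invalid score")
})
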