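test_that("median-of-ratios size factors match the brute-force oracle", {
  k <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2)   # exact 1:2 columns
  expect_equal(medianOfRatios(k), c(1 / sqrt(2), sqrt(2)))
  expect_equal(medianOfRatios(cbind(k[, 1], k[, 1])), c(1, 1))

  set.seed(42)
  for (i in 1:5) {
    k <- matrix(rnbinom(500 * 4, mu = 50, size = 5), ncol = 4) + 1
    expect_equal(medianOfRatios(k), unname(bruteMoR(k)), tolerance = 1e-12)
  }
  expect_error(medianOfRatios(matrix(c(0, 1, 1, 0), 2)), "spike windows")
})

test_that("spike size factors pre-normalize by mixing ratios", {
  k <- matrix(rep(c(10, 20, 40, 80), 50), ncol = 2, byrow = TRUE)[, 1:2]
  set.seed(1)
  k <- matrix(rnbinom(200, mu = 60, size = 10) + 1, ncol = 2)
  r <- c(1, 4)
  # dividing column 2's counts by (4 / geomean) must shift its factor
  sf <- spikeSizeFactors(k, r)
  pre <- sweep(k, 2, r / sqrt(prod(r)), "/")
  expect_equal(sf, unname(bruteMoR(pre)), tolerance = 1e-12)
  expect_error(spikeSizeFactors(k, c(1, 0)), "positive")
})

test_that("BH adjustment equals the step-up oracle", {
  expect_equal(adjustBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjustBH(c(0.005, 0.5)), c(0.01, 0.5))
  set.seed(8)
  p <- runif(1000)
  expect_equal(adjustBH(p), bruteBH(p), tolerance = 1e-15)
  expect_error(adjustBH(c(0.5, 1.2)), "0, 1")
  # NA (untested region) passes through
  expect_true(is.na(adjustBH(c(0.1, NA))[2]))
})

test_that("moment dispersions are calibrated on Poisson and NB data", {
  set.seed(31)
  grp <- factor(rep(1:2, each = 3))
  pois <- matrix(rpois(2000 * 6, 80), ncol = 6)
  dP <- momentDispersions(pois, rep(1, 6), grp)
  expect_lt(median(dP, na.rm = TRUE), 0.01)

  nb <- matrix(rnbinom(2000 * 6, mu = 100, size = 10), ncol = 6)
  dN <- momentDispersions(nb, rep(1, 6), grp)
  expect_gt(median(dN, na.rm = TRUE), 0.05)
  expect_lt(median(dN, na.rm = TRUE), 0.2)

  # constant equal counts: variance <= mean, estimate at the floor
  const <- matrix(50, nrow = 3, ncol = 6)
  dC <- momentDispersions(const, rep(1, 6), grp, priorDf = 0)
  expect_true(all(dC <= 1e-8 + 1e-15))
  # all-zero region flagged as NA
  z <- rbind(matrix(rpois(60, 20), ncol = 6), 0)
  expect_true(is.na(momentDispersions(z, rep(1, 6), grp)[11]))
})

test_that("nbWaldTest estimates planted fold changes and handles edge cases", {
  cd <- data.frame(condition = factor(rep(c("UNT", "OHT"), each = 3),
                                      levels = c("UNT", "OHT")))
  # identical groups -> log2FC 0, p ~ 1
  same <- matrix(rep(c(30L, 40L, 50L, 30L, 40L, 50L), 4), ncol = 6, byrow = TRUE)
  res <- nbWaldTest(same, rep(1, 6), cd, contrast = "conditionOHT")
  expect_equal(unname(res$log2FoldChange), rep(0, 4), tolerance = 1e-6)
  expect_true(all(res$pvalue > 0.99))

  # planted 4-fold increase, mean 100, alpha 0.05, 3v3
  set.seed(61)
  m <- 2000
  cnt <- cbind(matrix(rnbinom(m * 3, mu = 100, size = 20), ncol = 3),
               matrix(rnbinom(m * 3, mu = 400, size = 20), ncol = 3))
  res <- nbWaldTest(cnt, rep(1, 6), cd, contrast = "conditionOHT")
  expect_equal(mean(res$log2FoldChange), 2, tolerance = 0.1)

  # non-full-rank design errors with the offending column
  cd2 <- cbind(cd, dup = cd$condition)
  expect_error(nbWaldTest(same, rep(1, 6), cd2, design = ~ condition + dup,
                          contrast = "conditionOHT"), "full rank")

  # separation: all zeros in one group is flagged, LFC from pseudocounts
  sep <- rbind(c(0L, 0L, 0L, 20L, 25L, 30L))
  resS <- nbWaldTest(sep, rep(1, 6), cd, contrast = "conditionOHT",
                     dispersions = 0.05)
  expect_true(resS$separation[1])
  expect_true(is.finite(resS$log2FoldChange[1]))
})

test_that("significance calls honor both thresholds", {
  df <- S4Vectors::DataFrame(
    log2FoldChange = c(0.6, 3, -1.5, 0.5),
    padj = c(0.04, 0.06, 0.01, 0.04))
  calls <- callSignificant(df)
  expect_identical(as.character(calls), c("up", "ns", "down", "ns"))
  # fold = 2 variant for the signal-loss filter
  expect_identical(as.character(callSignificant(df, fold = 2)),
                   c("ns", "ns", "down", "ns"))
})

test_that("power: delta = 0.2 regions are called down via the calibrated route", {
  cfg <- simConfig(seed = 71, nTargetRegions = 1000L, nSpikeRegions = 300L,
                   depthRange = c(8e5L, 10e5L), depletionFactor = 0.2)
  sim <- simulateDualGenomeExperiment(cfg)
  res <- calibratedTest(sim)
  keep <- res$baseMean >= 100
  calls <- callSignificant(res)
  expect_gt(mean(calls[keep] == "down"), 0.9)
})

test_that("interaction test detects differential treatment effects", {
  set.seed(91)
  cd <- expand.grid(replicate = 1:3,
                    treatment = factor(c("UNT", "OHT"), levels = c("UNT", "OHT")),
                    line = factor(c("A", "B"), levels = c("A", "B")))
  m <- 600
  muBase <- 100
  effA <- 8; effB <- 2
  mu <- sapply(seq_len(nrow(cd)), function(i) {
    e <- if (cd$treatment[i] == "OHT") (if (cd$line[i] == "A") effA else effB) else 1
    muBase * e
  })
  cnt <- sapply(mu, function(mm) rnbinom(m, mu = mm, size = 20))
  res <- interactionTest(cnt, rep(1, nrow(cd)), cd)
  # interaction log2FC ~ log2(2/8) = -2
  expect_equal(median(res$log2FoldChange), -2, tolerance = 0.15)
  expect_gt(mean(res$padj < 0.05), 0.8)

  # swapping line labels flips the estimate's sign exactly
  cdSw <- cd
  cdSw$line <- factor(ifelse(cd$line == "A", "B", "A"), levels = c("A", "B"))
  resSw <- interactionTest(cnt, rep(1, nrow(cd)), cdSw,
                           dispersions = res$dispersion)
  expect_equal(resSw$log2FoldChange, -res$log2FoldChange, tolerance = 1e-6)

  # no planted interaction -> near-zero interaction estimates
  cnt0 <- sapply(seq_len(nrow(cd)), function(i) {
    e <- if (cd$treatment[i] == "OHT") 4 else 1
    rnbinom(m, mu = muBase * e, size = 20)
  })
  res0 <- interactionTest(cnt0, rep(1, nrow(cd)), cd)
  expect_lt(abs(median(res0$log2FoldChange)), 0.1)
  expect_lt(mean(res0$padj < 0.05, na.rm = TRUE), 0.05)

  cdBad <- cd[cd$line == "A" | cd$treatment == "UNT", ]
  expect_error(interactionTest(cnt[, cd$line == "A" | cd$treatment == "UNT"],
                               rep(1, nrow(cdBad)), cdBad), "empty design cell")
})

test_that("spike size factors are independent of the planted depletion while
           target-derived factors absorb it", {
  cfgs <- list(simConfig(seed = 81, nTargetRegions = 600L, nSpikeRegions = 200L,
                         depthRange = c(4e5L, 5e5L), depletionFactor = 0.2),
               simConfig(seed = 82, nTargetRegions = 600L, nSpikeRegions = 200L,
                         depthRange = c(4e5L, 5e5L), depletionFactor = 1))
  for (cfg in cfgs) {
    sim <- simulateDualGenomeExperiment(cfg)
    cd <- chipColData(sim)
    cal <- computeCalibration(sim$samples)
    sfS <- spikeSizeFactors(spikeCounts(sim$counts)[, cd$sample_id],
                            cal$mixing_ratio)
    sfT <- medianOfRatios(targetCounts(sim$counts)[, cd$sample_id])
    grpRatioS <- mean(sfS[cd$condition == "OHT"]) / mean(sfS[cd$condition == "UNT"])
    grpRatioT <- mean(sfT[cd$condition == "OHT"]) / mean(sfT[cd$condition == "UNT"])
    if (cfg$depletionFactor < 1) {
      # spike factors shift opposite to delta (compositional gain of spike
      # reads) by design; target factors track delta and erase the signal.
      expect_gt(grpRatioS / grpRatioT, 2)
    } else {
      expect_equal(grpRatioS, 1, tolerance = 0.15)
      expect_equal(grpRatioT, 1, tolerance = 0.15)
    }
  }
})

test_that("size factors agree with an established median-of-ratios implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(5)
  k <- matrix(rnbinom(400 * 5, mu = 80, size = 8) + 1L, ncol = 5)
  expect_equal(medianOfRatios(k),
               unname(DESeq2::estimateSizeFactorsForMatrix(k)),
               tolerance = 1e-4)  # even-length medians: arithmetic vs geometric centre
})
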