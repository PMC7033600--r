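test_that("config validation names the offending field", {
  expect_error(simConfig(depletionFactor = 0), "depletion_factor")
  expect_error(simConfig(depthRange = c(100, 10)), "depth_range")
  expect_error(simConfig(mixingJitterCV = -1), "mixing_jitter_cv")
  expect_error(simConfig(fractionResponsive = 2), "fraction_responsive")
  expect_error(simConfig(nTargetRegions = 0), "n_target_regions")
})

test_that("generator is deterministic and conserves configured depth", {
  cfg <- smallConfig(seed = 5)
  a <- simulateDualGenomeExperiment(cfg)
  b <- simulateDualGenomeExperiment(cfg)
  expect_identical(regionCounts(a$counts), regionCounts(b$counts))
  expect_identical(a$truth$mixing, b$truth$mixing)
  tot <- a$samples$target_reads + a$samples$spike_reads
  expect_equal(unname(tot), unname(as.numeric(a$truth$depth[a$samples$sample_id])))
  expect_equal(sum(a$truth$responsive),
               round(cfg$fractionResponsive * cfg$nTargetRegions))
})

test_that("planted depletion shows up in per-cell-normalized count ratios", {
  # delta = 0.2, all regions responsive: spike/mixing-corrected treated vs
  # untreated group ratio at target regions ~ 0.2 (Monte-Carlo mean)
  cfg <- simConfig(seed = 21, nTargetRegions = 2000L, nSpikeRegions = 400L,
                   depthRange = c(5e5L, 8e5L), depletionFactor = 0.2)
  sim <- simulateDualGenomeExperiment(cfg)
  cd <- chipColData(sim)
  cal <- computeCalibration(sim$samples)
  # per-cell scaling: corrected spike depth per sample
  S <- cal$effective_spike_depth[match(cd$sample_id, cal$sample_id)]
  tc <- sweep(targetCounts(sim$counts)[, cd$sample_id], 2, S, "/")
  ratio <- rowMeans(tc[, cd$condition == "OHT"]) /
    rowMeans(tc[, cd$condition == "UNT"])
  expect_equal(mean(ratio), 0.2, tolerance = 0.1)

  # spike regions are unaffected by delta once depth/mixing is corrected
  sc <- sweep(spikeCounts(sim$counts)[, cd$sample_id], 2, S, "/")
  sratio <- rowMeans(sc[, cd$condition == "OHT"]) /
    rowMeans(sc[, cd$condition == "UNT"])
  expect_equal(median(sratio), 1, tolerance = 0.1)
})

test_that("null generator plants no effect", {
  sim <- simulateDualGenomeExperiment(smallConfig(seed = 31, delta = 1))
  cd <- chipColData(sim)
  cal <- computeCalibration(sim$samples)
  S <- cal$effective_spike_depth[match(cd$sample_id, cal$sample_id)]
  tc <- sweep(targetCounts(sim$counts)[, cd$sample_id], 2, S, "/")
  ratio <- rowMeans(tc[, cd$condition == "OHT"]) /
    rowMeans(tc[, cd$condition == "UNT"])
  expect_equal(median(ratio), 1, tolerance = 0.1)
})

test_that("read records match sample tallies and are reproducible", {
  cfg <- simConfig(seed = 7, nTargetRegions = 100L, nSpikeRegions = 40L,
                   depthRange = c(5e3L, 8e3L))
  rr <- simulateReadRecords(cfg)
  tal <- table(rr$records$sample_id, rr$records$genome)
  sam <- rr$experiment$samples
  for (s in sam$sample_id) {
    expect_identical(unname(tal[s, "target"]), as.integer(sam$target_reads[sam$sample_id == s]))
    expect_identical(unname(tal[s, "spike"]), as.integer(sam$spike_reads[sam$sample_id == s]))
  }
  rr2 <- simulateReadRecords(cfg)
  expect_identical(rr$records, rr2$records)

  # per-chromosome totals equal a brute-force recount
  one <- rr$records[rr$records$sample_id == sam$sample_id[1], ]
  recount <- table(one$chrom)
  expect_identical(as.vector(table(one$chrom)), as.vector(recount))
  regions <- SummarizedExperiment::rowRanges(rr$experiment$counts)
  cnt <- countInIntervals(one, regions)
  expect_identical(as.vector(cnt),
                   unname(regionCounts(rr$experiment$counts)[, sam$sample_id[1]]))
})

test_that("annotation fixtures carry a correct planted truth table", {
  fx <- genAnnotationFixtures(seed = 3)
  # brute-force overlap scan over emitted intervals reproduces truth classes
  hw <- 2500L
  cls <- character(nrow(fx$genes))
  for (i in seq_len(nrow(fx$genes))) {
    g <- fx$genes$gene_id[i]
    tss <- fx$transcripts$tss[fx$transcripts$gene_id == g]
    prom <- GenomicRanges::GRanges(fx$genes$chrom[i],
              IRanges::IRanges(tss - hw, tss + hw - 1L))
    ov <- function(x) any(GenomicRanges::countOverlaps(prom, x) > 0)
    ring <- filterPeaks(fx$peaks$ring1b, fx$blacklist)
    suz <- filterPeaks(fx$peaks$suz12, fx$blacklist)
    cls[i] <- if (!ov(fx$nmi)) "Non-NMI"
              else if (ov(ring) && ov(suz)) "PcG" else "Non-PcG"
  }
  expect_identical(cls, fx$truth$geneClasses$class)

  # blacklisted decoy peaks are present in raw sets and recorded as excluded
  bl <- fx$truth$peakStatus[fx$truth$peakStatus$status == "blacklisted", ]
  raw <- fx$peaks$ring1b$lineA
  blGr <- GenomicRanges::GRanges(bl$chrom, IRanges::IRanges(bl$start, bl$end))
  expect_true(all(GenomicRanges::countOverlaps(blGr, raw) > 0))
  filt <- filterPeaks(fx$peaks$ring1b, fx$blacklist)
  expect_true(all(GenomicRanges::countOverlaps(blGr, filt) == 0))
})

test_that("capture-C simulation plants truthful spans and a clean background", {
  sim0 <- simulateCaptureC(seed = 9, plantedPeaks = list())
  expect_true(all(sim0$calls$score < 5))
  expect_identical(nrow(sim0$truth), 0L)

  sim <- simulateCaptureC(seed = 9,
                          plantedPeaks = list(bait1 = list(c(40L, 44L))),
                          baits = c(bait1 = 25000))
  expect_identical(sim$truth$lo, 40L + 0L)
  expect_identical(sim$truth$hi, 44L + 0L)
  inPk <- sim$calls$frag_index >= 40 & sim$calls$frag_index <= 44
  expect_true(all(sim$calls$score[inPk] >= 5))
  expect_true(all(sim$calls$score[!inPk] < 5))
  expect_error(simulateCaptureC(seed = 1, baits = c(b = 1e9)), "outside")
})

test_that("image-stack simulation is deterministic with truthful foci", {
  a <- simulateImageStack(seed = 4, dim = c(10L, 48L, 48L), nFoci = 5)
  b <- simulateImageStack(seed = 4, dim = c(10L, 48L, 48L), nFoci = 5)
  expect_identical(a$stack, b$stack)
  expect_identical(nrow(a$truth), 5L)
  expect_true(all(a$mask[cbind(round(a$truth$z), round(a$truth$y),
                               round(a$truth$x))]))
  z <- simulateImageStack(seed = 4, dim = c(8L, 32L, 32L), nFoci = 0)
  expect_identical(nrow(z$truth), 0L)
  # impossible placement errors out after bounded retries
  expect_error(simulateImageStack(seed = 1, dim = c(6L, 20L, 20L),
                                  nFoci = 500, maxTries = 600),
               "could not place")
})
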