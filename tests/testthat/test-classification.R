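test_that("filterPeaks applies line intersection then blacklist removal", {
  gr <- function(...) GenomicRanges::GRanges("chr1", IRanges::IRanges(...))
  lineA <- gr(c(100, 500, 900), width = 100)
  lineB <- gr(c(120, 910), width = 100)            # no peak near 500
  out <- filterPeaks(list(lineA, lineB))
  expect_identical(GenomicRanges::start(out), c(100L, 900L))

  # 1 bp blacklist overlap drops a peak
  bl <- gr(199, 199)
  out2 <- filterPeaks(list(lineA, lineB), blacklist = bl)
  expect_identical(GenomicRanges::start(out2), 900L)

  expect_error(filterPeaks(list()), "non-empty")
  expect_error(filterPeaks(list(lineA, GenomicRanges::GRanges())), "empty raw")
})

test_that("the planted decoy fixture is filtered to exactly the shared peaks", {
  fx <- genAnnotationFixtures(seed = 2, nSharedPeaks = 4L,
                              nBlacklistPeaks = 3L, nPrivatePeaks = 5L)
  filt <- filterPeaks(fx$peaks$ring1b, fx$blacklist, mode = "both_lines")
  st <- fx$truth$peakStatus
  decoyZone <- GenomicRanges::GRanges(st$chrom, IRanges::IRanges(st$start, st$end))
  kept <- filt[GenomicRanges::countOverlaps(filt, decoyZone) > 0]
  expect_identical(length(kept), 4L)
  shared <- decoyZone[st$status == "shared"]
  expect_true(all(bruteOverlap(kept, shared)))

  # all-replicates mode on the PCGF2-style sets
  filt2 <- filterPeaks(fx$peaks$pcgf2, fx$blacklist, mode = "all_replicates")
  expect_identical(length(filt2), fx$truth$pcgf2Retained)
})

test_that("signal-loss filter keeps only significantly lost peaks", {
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 100, 200), width = 50))
  names(peaks) <- c("p1", "p2", "p3")
  de <- S4Vectors::DataFrame(
    log2FoldChange = c(-1.5, -0.8, -3),
    padj = c(0.01, 0.01, 0.2),
    row.names = c("p1", "p2", "p3"))
  out <- filterBySignalLoss(peaks, de)
  expect_identical(names(out), "p1")   # p2 fails fold > 2, p3 fails padj

  names(peaks)[3] <- "unknown"
  expect_error(filterBySignalLoss(peaks, de), "missing from")
})

test_that("signal-loss filter has power and specificity in simulation", {
  set.seed(13)
  m <- 400
  lost <- seq_len(320)                     # 80% planted delta = 0.1
  mu0 <- 200
  cd <- data.frame(condition = factor(rep(c("UNT", "OHT"), each = 3),
                                      levels = c("UNT", "OHT")))
  mu <- matrix(mu0, m, 6)
  mu[lost, 4:6] <- mu0 * 0.1
  cnt <- matrix(rnbinom(m * 6, mu = mu, size = 20), m, 6)
  rownames(cnt) <- sprintf("pk%03d", seq_len(m))
  res <- nbWaldTest(cnt, rep(1, 6), cd, contrast = "conditionOHT")
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(seq_len(m) * 100, width = 50))
  names(peaks) <- rownames(cnt)
  out <- filterBySignalLoss(peaks, res)
  expect_gt(mean(names(peaks)[lost] %in% names(out)), 0.95)
  expect_lt(mean(names(peaks)[-lost] %in% names(out)), 0.10)
})

test_that("joint targets equal a brute-force overlap scan", {
  a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 50, 200), width = 20))
  b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(400, 500), width = 20))
  expect_identical(length(defineJointTargets(a, b)), 0L)
  inside <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(5, 55), width = 5))
  expect_identical(length(defineJointTargets(inside, a)), 2L)

  set.seed(19)
  ra <- GenomicRanges::GRanges(sample(c("c1", "c2"), 60, TRUE),
                               IRanges::IRanges(sample(1:5000, 60), width = 80))
  rb <- GenomicRanges::GRanges(sample(c("c1", "c2"), 40, TRUE),
                               IRanges::IRanges(sample(1:5000, 40), width = 80))
  expect_identical(defineJointTargets(ra, rb), ra[bruteOverlap(ra, rb)])
})

test_that("gene classification follows the promoter-overlap rules", {
  # TSS at 0-based 10,000; NMI [9,000-9,600) overlaps promoter [7,500-12,500)
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+")
  tx <- data.frame(gene_id = "g1", tss = 10001L)   # 1-based
  nmi <- GenomicRanges::GRanges("chr1", IRanges::IRanges(9001, 9600))
  none <- GenomicRanges::GRanges()
  cls <- classifyGenes(genes, tx, nmi, none, none)
  expect_identical(as.character(cls$class), "Non-PcG")  # NMI but no peaks

  ring <- GenomicRanges::GRanges("chr1", IRanges::IRanges(9500, 9800))
  cls2 <- classifyGenes(genes, tx, nmi, ring, none)
  expect_identical(as.character(cls2$class), "Non-PcG") # RING1B without SUZ12

  farNmi <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 200))
  cls3 <- classifyGenes(genes, tx, farNmi, ring, ring)
  expect_identical(as.character(cls3$class), "Non-NMI")

  expect_error(classifyGenes(genes, tx[0, ], nmi, none, none), "transcript")
})

test_that("fixture genes are classified to the truth table in both modes", {
  fx <- genAnnotationFixtures(seed = 6)
  ring <- filterPeaks(fx$peaks$ring1b, fx$blacklist)
  suz <- filterPeaks(fx$peaks$suz12, fx$blacklist)
  cls <- classifyGenes(fx$genes, fx$transcripts, fx$nmi, ring, suz)
  expect_identical(as.character(cls$class), fx$truth$geneClasses$class)
  clsSame <- classifyGenes(fx$genes, fx$transcripts, fx$nmi, ring, suz,
                           samePromoter = TRUE)
  expect_identical(as.character(clsSame$class),
                   fx$truth$geneClasses$class_same_promoter)
  # split-promoter genes are the only ones that differ between modes
  expect_gt(sum(cls$class != clsSame$class), 0)

  # partition: every gene gets exactly one class
  expect_identical(sum(table(cls$class)), nrow(fx$genes))

  # monotonicity: growing the promoter window never creates Non-NMI genes
  clsWide <- classifyGenes(fx$genes, fx$transcripts, fx$nmi, ring, suz,
                           halfwidth = 5000L)
  wasNmi <- cls$class != "Non-NMI"
  expect_true(all(clsWide$class[wasNmi] != "Non-NMI"))
})

test_that("PRC1-repressed flags require PcG class and significant gain", {
  classification <- data.frame(
    gene_id = c("a", "b", "c"),
    class = factor(c("PcG", "Non-PcG", "PcG"),
                   levels = c("Non-NMI", "Non-PcG", "PcG")))
  de <- S4Vectors::DataFrame(
    log2FoldChange = c(2, 2, 0.1),
    padj = c(0.001, 0.001, 0.9),
    row.names = c("a", "b", "c"))
  out <- definePrc1Repressed(classification, de)
  expect_identical(out$prc1_repressed, c(TRUE, FALSE, FALSE))
})

test_that("derepression classes use union semantics over the two approaches", {
  classification <- data.frame(
    gene_id = c("a", "b", "c", "d"),
    class = factor(rep("PcG", 4), levels = c("Non-NMI", "Non-PcG", "PcG")),
    prc1_repressed = c(TRUE, TRUE, TRUE, FALSE))
  mk <- function(lfc, padj, ids)
    S4Vectors::DataFrame(log2FoldChange = lfc, padj = padj, row.names = ids)
  deDirect <- mk(c(-2, 0, 0, -2), c(0.01, 0.9, 0.9, 0.01), c("a", "b", "c", "d"))
  deInter <- mk(c(0, -2, 0, 0), c(0.9, 0.01, 0.9, 0.9), c("a", "b", "c", "d"))
  out <- classifyDerepression(classification, deDirect, deInter)
  expect_identical(as.character(out$derepression),
                   c("partial", "partial", "full", "n/a"))
})
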