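#' Generate annotation fixtures with planted gene-class structure
#'
#' Builds, on a two-chromosome toy genome, a gene set with known membership in
#' the three promoter classes used throughout the package (Non-NMI: no
#' non-methylated island at any promoter; Non-PcG: NMI but not both RING1B and
#' SUZ12; PcG: NMI plus RING1B plus SUZ12), together with the input files the
#' classification module consumes: NMI intervals, a blacklist, and raw peak
#' sets per factor and line/replicate.  The raw RING1B sets additionally carry
#' a dedicated peak-filter fixture in a gene-free decoy zone: peaks shared
#' between lines, peaks private to one line, and shared peaks overlapping the
#' blacklist.  All planted memberships are recorded in truth tables.
#'
#' A small number of PcG-truth genes are given two promoters such that RING1B
#' and SUZ12 are contacted by different promoters: these are "PcG" under the
#' any-promoter rule but "Non-PcG" under the stricter same-promoter rule, and
#' the truth table records both labels.
#'
#' @param seed RNG seed.
#' @param nPerClass named integer vector: genes per planted class
#'   (\code{nonNMI}, \code{nonPcG}, \code{pcg}).
#' @param nSharedPeaks,nPrivatePeaks,nBlacklistPeaks decoy-zone peak counts
#'   for the peak-filter fixture.
#' @param nSplitPromoter number of PcG genes with split promoters.
#' @param promoterHalfwidth promoter half-width in bp (default 2500).
#' @return list with \code{seqlengths}, \code{genes} (data.frame),
#'   \code{transcripts} (gene_id, tss), \code{nmi}, \code{blacklist}
#'   (GRanges), \code{peaks} (nested list: ring1b/suz12 per line, pcgf2 per
#'   replicate), and \code{truth} (geneClasses, peakStatus, pcgf2Retained).
#' @export
genAnnotationFixtures <- function(seed = 1L,
                                  nPerClass = c(nonNMI = 8L, nonPcG = 10L, pcg = 12L),
                                  nSharedPeaks = 4L, nPrivatePeaks = 5L,
                                  nBlacklistPeaks = 3L,
                                  nSplitPromoter = 2L,
                                  promoterHalfwidth = 2500L) {
  withSeed(seed, {
    sl <- c(chrS1 = 1e6L, chrS2 = 1e6L)
    nG <- sum(nPerClass)
    classes <- sample(rep(c("Non-NMI", "Non-PcG", "PcG"), nPerClass))
    gene_id <- sprintf("g%03d", seq_len(nG))
    chrom <- rep(c("chrS1", "chrS2"), length.out = nG)
    slot <- ave(seq_len(nG), chrom, FUN = seq_along)
    tss <- 20000L + (slot - 1L) * 20000L
    strand <- rep(c("+", "-"), length.out = nG)

    # Non-PcG subtypes cycle: NMI only / NMI+RING1B / NMI+SUZ12
    subtype <- character(nG)
    subtype[classes == "Non-PcG"] <-
      rep(c("nmi_only", "nmi_ring1b", "nmi_suz12"),
          length.out = sum(classes == "Non-PcG"))

    split_ids <- utils::head(gene_id[classes == "PcG"], nSplitPromoter)

    tx <- data.frame(gene_id = gene_id, tss = tss, stringsAsFactors = FALSE)
    nmi_l <- list(); ring_l <- list(); suz_l <- list()
    for (i in seq_len(nG)) {
      g <- gene_id[i]; t1 <- tss[i]; chr <- chrom[i]
      if (classes[i] == "Non-NMI") next
      if (g %in% split_ids) {
        # promoter 1: NMI + RING1B; promoter 2 (second transcript): NMI + SUZ12
        t2 <- t1 + 4L * promoterHalfwidth   # outside promoter 1, clear of neighbours
        tx <- rbind(tx, data.frame(gene_id = g, tss = t2))
        nmi_l[[length(nmi_l) + 1L]] <- GenomicRanges::GRanges(chr,
          IRanges::IRanges(c(t1 - 300L, t2 - 300L), c(t1 + 300L, t2 + 300L)))
        ring_l[[length(ring_l) + 1L]] <- GenomicRanges::GRanges(chr,
          IRanges::IRanges(t1 - 800L, t1 + 400L))
        suz_l[[length(suz_l) + 1L]] <- GenomicRanges::GRanges(chr,
          IRanges::IRanges(t2 - 500L, t2 + 700L))
        next
      }
      nmi_l[[length(nmi_l) + 1L]] <- GenomicRanges::GRanges(chr,
        IRanges::IRanges(t1 - 300L, t1 + 300L))
      wantRing <- classes[i] == "PcG" || subtype[i] == "nmi_ring1b"
      wantSuz <- classes[i] == "PcG" || subtype[i] == "nmi_suz12"
      if (wantRing)
        ring_l[[length(ring_l) + 1L]] <- GenomicRanges::GRanges(chr,
          IRanges::IRanges(t1 - 800L, t1 + 400L))
      if (wantSuz)
        suz_l[[length(suz_l) + 1L]] <- GenomicRanges::GRanges(chr,
          IRanges::IRanges(t1 - 500L, t1 + 700L))
    }
    catGr <- function(lst) suppressWarnings(sort(unname(do.call(c, lst))))
    nmi <- catGr(nmi_l)
    ringGene <- catGr(ring_l)
    suzGene <- catGr(suz_l)

    # decoy zone (gene-free): peak-filter fixture + blacklist
    zone0 <- 620000L
    mkPeak <- function(k) {
      st <- zone0 + (k - 1L) * 3000L
      GenomicRanges::GRanges("chrS2", IRanges::IRanges(st, st + 999L))
    }
    nDecoy <- nSharedPeaks + nBlacklistPeaks + nPrivatePeaks
    decoy <- suppressWarnings(do.call(c, lapply(seq_len(nDecoy), mkPeak)))
    status <- rep(c("shared", "blacklisted", "private"),
                  c(nSharedPeaks, nBlacklistPeaks, nPrivatePeaks))
    blacklist <- decoy[status == "blacklisted"]
    # blacklist intervals clipped so overlap with their peak is partial
    blacklist <- GenomicRanges::resize(blacklist, width = 200L, fix = "center")

    ringA <- suppressWarnings(sort(c(ringGene, decoy)))            # line A: all decoys
    ringB <- suppressWarnings(sort(c(ringGene, decoy[status != "private"])))  # line B: no private
    suzA <- suzGene; suzB <- suzGene

    # PCGF2-style replicate sets: decoy "private" peaks are missing in rep3
    pcgf2 <- list(rep1 = ringA, rep2 = ringA, rep3 = ringB)

    genes <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                        body_start = tss, body_end = tss + 4000L,
                        stringsAsFactors = FALSE)
    classes_same <- classes
    classes_same[gene_id %in% split_ids] <- "Non-PcG"
    truth <- list(
      geneClasses = data.frame(gene_id = gene_id, class = classes,
                               class_same_promoter = classes_same,
                               stringsAsFactors = FALSE),
      peakStatus = data.frame(
        chrom = as.character(GenomeInfoDb::seqnames(decoy)),
        start = GenomicRanges::start(decoy), end = GenomicRanges::end(decoy),
        status = status, stringsAsFactors = FALSE),
      pcgf2Retained = length(ringGene) + nSharedPeaks)  # after all-reps + blacklist

    list(seqlengths = sl, genes = genes, transcripts = tx,
         nmi = nmi, blacklist = blacklist,
         peaks = list(ring1b = list(lineA = ringA, lineB = ringB),
                      suz12 = list(lineA = suzA, lineB = suzB),
                      pcgf2 = pcgf2),
         truth = truth)
  })
}
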