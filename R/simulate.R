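#' Build a toy genome and a set of equal-width regions tiling it
#'
#' Chromosome names follow the package's toy dialect (\code{chrS1, chrS2, ...},
#' lengths capped at 1 Mb); spike-genome contigs carry a \code{spike_} prefix
#' so composite-reference records can be split by name.
#'
#' @param nRegions number of regions to place.
#' @param prefix chromosome-name prefix.
#' @param regionWidth,gap region width and inter-region gap in bp.
#' @param maxChromLen chromosome length cap in bp.
#' @return list with \code{seqlengths} (named integer vector) and
#'   \code{regions} (\linkS4class{GRanges}).
#' @export
toyGenome <- function(nRegions, prefix = "chrS", regionWidth = 1000L,
                      gap = 500L, maxChromLen = 1e6L) {
  per <- max(1L, floor(maxChromLen / (regionWidth + gap)))
  nChrom <- ceiling(nRegions / per)
  chrom <- character(0); starts <- integer(0)
  for (k in seq_len(nChrom)) {
    n_k <- min(per, nRegions - (k - 1L) * per)
    chrom <- c(chrom, rep(paste0(prefix, k), n_k))
    starts <- c(starts, (seq_len(n_k) - 1L) * (regionWidth + gap) + 1L)
  }
  sl <- setNames(rep(maxChromLen, nChrom), paste0(prefix, seq_len(nChrom)))
  gr <- GenomicRanges::GRanges(chrom,
          IRanges::IRanges(starts, width = regionWidth),
          seqlengths = sl)
  list(seqlengths = sl, regions = gr)
}

# core generator; assumes the RNG is already seeded
.simDualGenome <- function(config) {
  nT <- config$nTargetRegions; nS <- config$nSpikeRegions
  n <- config$nSamplesPerGroup
  tg <- toyGenome(nT, prefix = "chrS")
  sg <- toyGenome(nS, prefix = "spike_chrS")
  regions <- suppressWarnings(c(tg$regions, sg$regions))
  regions$genome <- rep(c("target", "spike"), c(nT, nS))
  names(regions) <- c(sprintf("t%05d", seq_len(nT)), sprintf("s%05d", seq_len(nS)))

  lambda <- rlnorm(nT, meanlog = 0, sdlog = 0.5)
  sigma <- rlnorm(nS, meanlog = 0, sdlog = 0.5)
  sigma <- sigma * sum(lambda) / sum(sigma)   # per-cell spike signal ~ target scale
  nResp <- round(config$fractionResponsive * nT)
  responsive <- rep(FALSE, nT)
  if (nResp > 0) responsive[sample.int(nT, nResp)] <- TRUE

  cond <- rep(c("UNT", "OHT"), each = n)
  repl <- rep(seq_len(n), 2L)
  chipId <- sprintf("chip_%s_%d", cond, repl)
  inputId <- sprintf("input_%s_%d", cond, repl)
  nChip <- length(chipId)

  mixing <- config$mixingRatioBase * jitterLognormal(nChip, config$mixingJitterCV)
  depthC <- as.integer(round(runif(nChip, config$depthRange[1], config$depthRange[2])))
  depthI <- as.integer(round(runif(nChip, config$depthRange[1], config$depthRange[2])))

  counts <- matrix(0L, nrow = nT + nS, ncol = 2L * nChip,
                   dimnames = list(names(regions), c(chipId, inputId)))
  widths <- GenomicRanges::width(regions)
  for (i in seq_len(nChip)) {
    dEff <- ifelse(cond[i] == "OHT" & responsive, config$depletionFactor, 1)
    wChip <- c(lambda * dEff, mixing[i] * sigma)
    counts[, i] <- dirichletMultinomial(depthC[i], wChip, config$dispersion)
    # matched input: spike/target split reflects cell mixing only, signal-free
    pS <- mixing[i] / (1 + mixing[i])
    iS <- rbinom(1L, depthI[i], pS)
    iT <- depthI[i] - iS
    ci <- integer(nT + nS)
    ci[seq_len(nT)] <- dirichletMultinomial(iT, widths[seq_len(nT)], 0.02)
    ci[nT + seq_len(nS)] <- dirichletMultinomial(iS, widths[nT + seq_len(nS)], 0.02)
    counts[, nChip + i] <- ci
  }

  colData <- data.frame(
    sample_id = c(chipId, inputId),
    role = rep(c("chip", "input"), each = nChip),
    condition = rep(cond, 2L),
    line = "WT",
    replicate = rep(repl, 2L),
    matched_input_id = c(inputId, rep(NA_character_, nChip)),
    stringsAsFactors = FALSE)
  rownames(colData) <- colData$sample_id

  rc <- RegionCounts(counts, regions, colData)
  tag <- regions$genome
  samples <- cbind(colData,
                   target_reads = colSums(counts[tag == "target", , drop = FALSE]),
                   spike_reads = colSums(counts[tag == "spike", , drop = FALSE]))
  truth <- list(mixing = setNames(mixing, chipId),
                depth = setNames(c(depthC, depthI), c(chipId, inputId)),
                strengthTarget = lambda, strengthSpike = sigma,
                responsive = responsive, delta = config$depletionFactor)
  list(counts = rc, samples = samples, truth = truth)
}

#' Simulate a dual-genome (spike-in calibrated) sequencing experiment
#'
#' Generates region-level counts for an untreated and a treated group of
#' ChIP-style samples plus matched input samples, on a toy target genome mixed
#' with a toy spike-in genome.  Per-cell target signal is multiplied by
#' \code{depletionFactor} in treated, responsive regions while per-cell spike
#' signal is untouched; read counts are compositional, so a global target
#' depletion inflates the spike read share exactly as in a calibrated ChIP
#' experiment.  Sample totals equal the drawn depth exactly.
#'
#' @param config a \code{\link{simConfig}} object.
#' @return list with \code{counts} (\linkS4class{RegionCounts} holding chip and
#'   input columns), \code{samples} (per-sample tallies: \code{target_reads},
#'   \code{spike_reads}, metadata) and \code{truth} (mixing ratios, depths,
#'   region strengths, responsive flags, delta).
#' @export
simulateDualGenomeExperiment <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  withSeed(config$seed, .simDualGenome(config))
}

#' Simulate per-read records for a dual-genome experiment
#'
#' Expands the counts of \code{\link{simulateDualGenomeExperiment}} into
#' per-read records (genome tag, chromosome, position) for testing read-level
#' operations such as calibrated subsampling.  Record tallies per genome match
#' the sample tallies exactly by construction.
#'
#' @param config a \code{\link{simConfig}} object (use small depths).
#' @return list with \code{records} (data.frame: sample_id, genome, chrom,
#'   pos) and \code{experiment} (the underlying simulation).
#' @export
simulateReadRecords <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  withSeed(config$seed, {
    sim <- .simDualGenome(config)
    cnt <- regionCounts(sim$counts)
    rr <- SummarizedExperiment::rowRanges(sim$counts)
    recs <- lapply(colnames(cnt), function(s) {
      k <- cnt[, s]
      idx <- rep(seq_along(k), k)
      off <- floor(runif(length(idx)) * GenomicRanges::width(rr)[idx])
      data.frame(sample_id = s,
                 genome = rr$genome[idx],
                 chrom = as.character(GenomeInfoDb::seqnames(rr))[idx],
                 pos = GenomicRanges::start(rr)[idx] + as.integer(off),
                 stringsAsFactors = FALSE)
    })
    list(records = do.call(rbind, recs), experiment = sim)
  })
}

#' Simulate a 2x2 line-by-treatment calibrated expression experiment
#'
#' Generates spike-calibrated RNA-style counts for two cell lines
#' (e.g. conditional-knockout vs catalytic point mutant) before and after
#' treatment, with a planted set of upregulated (derepressed) genes.  A subset
#' of those can respond with a reduced fold change in the second line
#' ("partial" genes), which is what the direct-contrast and interaction tests
#' are meant to recover.  Matched gDNA samples carry the mixing information.
#'
#' @param seed RNG seed.
#' @param geneIds character vector of target gene identifiers.
#' @param upGenes ids of genes upregulated \code{foldUp}-fold upon treatment.
#' @param partialGenes subset of \code{upGenes} whose fold change in line
#'   \code{lines[2]} is multiplied by \code{partialFactor}.
#' @param foldUp planted treatment fold change (default 4).
#' @param partialFactor fold-change attenuation in the second line (default 0.5).
#' @param nSpikeGenes number of spike-in genes used for size factors.
#' @param reps replicates per design cell.
#' @param lines,treatments factor levels (reference level first).
#' @param depthRange,mixingRatioBase,mixingJitterCV,dispersion as in
#'   \code{\link{simConfig}}.
#' @return list with \code{counts} (\linkS4class{RegionCounts}; rna + gdna
#'   columns), \code{samples}, and \code{truth}.
#' @export
simulateExpression2x2 <- function(seed, geneIds, upGenes,
                                  partialGenes = character(0),
                                  foldUp = 4, partialFactor = 0.5,
                                  nSpikeGenes = 200L, reps = 3L,
                                  lines = c("CKO", "CPM"),
                                  treatments = c("UNT", "OHT"),
                                  depthRange = c(8e5, 12e5),
                                  mixingRatioBase = 0.4,
                                  mixingJitterCV = 0.1,
                                  dispersion = 0.05) {
  stopifnot(all(upGenes %in% geneIds), all(partialGenes %in% upGenes))
  nG <- length(geneIds)
  withSeed(seed, {
    base <- rlnorm(nG, meanlog = 0, sdlog = 1)
    sigma <- rlnorm(nSpikeGenes, meanlog = 0, sdlog = 0.5)
    sigma <- sigma * sum(base) / sum(sigma)
    fold <- matrix(1, nrow = nG, ncol = 2, dimnames = list(geneIds, lines))
    fold[upGenes, 1] <- foldUp
    fold[upGenes, 2] <- foldUp
    fold[partialGenes, 2] <- foldUp * partialFactor

    design <- expand.grid(replicate = seq_len(reps), treatment = treatments,
                          line = lines, stringsAsFactors = FALSE)
    ns <- nrow(design)
    rnaId <- sprintf("rna_%s_%s_%d", design$line, design$treatment, design$replicate)
    gdnaId <- sprintf("gdna_%s_%s_%d", design$line, design$treatment, design$replicate)
    mixing <- mixingRatioBase * jitterLognormal(ns, mixingJitterCV)
    depthR <- as.integer(round(runif(ns, depthRange[1], depthRange[2])))
    depthG <- as.integer(round(runif(ns, depthRange[1], depthRange[2])))

    rowIds <- c(geneIds, sprintf("spike_g%04d", seq_len(nSpikeGenes)))
    counts <- matrix(0L, nrow = nG + nSpikeGenes, ncol = 2L * ns,
                     dimnames = list(rowIds, c(rnaId, gdnaId)))
    for (i in seq_len(ns)) {
      eff <- if (design$treatment[i] == treatments[2]) fold[, design$line[i]] else rep(1, nG)
      w <- c(base * eff, mixing[i] * sigma)
      counts[, i] <- dirichletMultinomial(depthR[i], w, dispersion)
      pS <- mixing[i] / (1 + mixing[i])
      gS <- rbinom(1L, depthG[i], pS)
      ci <- integer(nG + nSpikeGenes)
      ci[seq_len(nG)] <- dirichletMultinomial(depthG[i] - gS, rep(1, nG), 0.02)
      ci[nG + seq_len(nSpikeGenes)] <- dirichletMultinomial(gS, rep(1, nSpikeGenes), 0.02)
      counts[, ns + i] <- ci
    }

    colData <- data.frame(
      sample_id = c(rnaId, gdnaId),
      role = rep(c("rna", "gdna"), each = ns),
      condition = rep(design$treatment, 2L),
      treatment = factor(rep(design$treatment, 2L), levels = treatments),
      line = factor(rep(design$line, 2L), levels = lines),
      replicate = rep(design$replicate, 2L),
      matched_input_id = c(gdnaId, rep(NA_character_, ns)),
      stringsAsFactors = FALSE)
    rownames(colData) <- colData$sample_id
    tags <- rep(c("target", "spike"), c(nG, nSpikeGenes))
    rc <- RegionCounts(counts, tags, colData)
    samples <- cbind(colData,
                     target_reads = colSums(counts[tags == "target", , drop = FALSE]),
                     spike_reads = colSums(counts[tags == "spike", , drop = FALSE]))
    truth <- list(upGenes = upGenes, partialGenes = partialGenes,
                  foldUp = foldUp, partialFactor = partialFactor,
                  mixing = setNames(mixing, rnaId), baseline = setNames(base, geneIds))
    list(counts = rc, samples = samples, truth = truth)
  })
}
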