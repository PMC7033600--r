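# shared helpers: compact configs and the calibrated / naive test pipelines

smallConfig <- function(seed, delta = 1, ...) {
  simConfig(seed = seed, nTargetRegions = 300L, nSpikeRegions = 120L,
            depthRange = c(1e5L, 1.5e5L), depletionFactor = delta, ...)
}

chipColData <- function(sim) {
  si <- sampleInfo(sim$counts)
  cd <- si[si$role == "chip", , drop = FALSE]
  cd$condition <- factor(cd$condition, levels = c("UNT", "OHT"))
  cd
}

# spike-anchored (calibrated) treated-vs-untreated Wald test
calibratedTest <- function(sim, ...) {
  cd <- chipColData(sim)
  cal <- computeCalibration(sim$samples)
  sf <- spikeSizeFactors(spikeCounts(sim$counts)[, cd$sample_id],
                         cal$mixing_ratio[match(cd$sample_id, cal$sample_id)])
  nbWaldTest(targetCounts(sim$counts)[, cd$sample_id], sf, cd,
             design = ~ condition, contrast = "conditionOHT", ...)
}

# target-library-size (naive) normalization of the same contrast
naiveTest <- function(sim, ...) {
  cd <- chipColData(sim)
  sf <- medianOfRatios(targetCounts(sim$counts)[, cd$sample_id])
  nbWaldTest(targetCounts(sim$counts)[, cd$sample_id], sf, cd,
             design = ~ condition, contrast = "conditionOHT", ...)
}

# brute-force interval overlap count for a single-bp read table
bruteCountReads <- function(reads, intervals) {
  out <- integer(length(intervals))
  ic <- as.character(GenomeInfoDb::seqnames(intervals))
  is <- GenomicRanges::start(intervals); ie <- GenomicRanges::end(intervals)
  for (k in seq_len(nrow(reads))) {
    hit <- which(ic == reads$chrom[k] & is <= reads$pos[k] & ie >= reads$pos[k])
    out[hit] <- out[hit] + 1L
  }
  out
}
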