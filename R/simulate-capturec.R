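#' Simulate promoter Capture-C per-fragment count/score tables
#'
#' Digests a toy genome (generated on the fly unless supplied) at the DpnII
#' motif, picks bait fragments, and emits per-fragment weighted counts and
#' interaction significance scores per sample.  Planted interaction peaks are
#' contiguous runs of fragments whose counts are elevated and whose scores are
#' at or above the significance cutoff in every sample; background scores stay
#' strictly below the cutoff.  The planted spans are returned as a truth
#' table in per-chromosome fragment-index units.
#'
#' @param seed RNG seed.
#' @param fasta \code{DNAStringSet} to digest; a random 50 kb single-contig
#'   toy sequence is generated when \code{NULL}.
#' @param baits base-pair positions of the captured promoters (one bait per
#'   position, named \code{bait1, ...}); defaults to evenly spaced positions.
#' @param plantedPeaks list (one element per bait) of lists of length-2
#'   integer vectors \code{c(lo, hi)}: planted spans in fragment indices.
#'   \code{NULL} plants two well-separated spans per bait;
#'   \code{list()} per bait plants none.
#' @param nSamples number of samples.
#' @param motif digestion motif (default \code{"GATC"}).
#' @param bgCountMu,peakCountMu mean background / in-peak fragment counts.
#' @param scoreMin significance cutoff emulated by the planted scores.
#' @param dispersion NB dispersion of fragment counts.
#' @return list with \code{fasta}, \code{fragmentMap}
#'   (\linkS4class{FragmentMap}), \code{calls} (data.frame: bait_id, chrom,
#'   frag_index, fragment_start, count, score, sample) and \code{truth}
#'   (data.frame: bait_id, lo, hi).
#' @export
simulateCaptureC <- function(seed = 1L, fasta = NULL, baits = NULL,
                             plantedPeaks = NULL, nSamples = 2L,
                             motif = "GATC", bgCountMu = 2, peakCountMu = 20,
                             scoreMin = 5, dispersion = 0.1) {
  withSeed(seed, {
    if (is.null(fasta)) {
      seqc <- paste(sample(c("A", "C", "G", "T"), 50000L, replace = TRUE),
                    collapse = "")
      fasta <- Biostrings::DNAStringSet(seqc)
      names(fasta) <- "chrS1"
    }
    fmap <- digestGenome(fasta, motif = motif)
    fr <- fragments(fmap)

    seqlens <- setNames(Biostrings::width(fasta), names(fasta))
    if (is.null(baits)) {
      baits <- setNames(round(seqlens[1] * c(0.25, 0.5, 0.75)),
                        paste0("bait", 1:3))
      baits <- baits[seq_len(min(3L, length(baits)))]
    }
    if (is.null(names(baits))) names(baits) <- paste0("bait", seq_along(baits))
    if (any(baits < 1 | baits > seqlens[1]))
      stop("bait position outside the genome", call. = FALSE)

    chr <- names(fasta)[1]
    frc <- fr[as.character(GenomeInfoDb::seqnames(fr)) == chr]
    nF <- length(frc)
    if (is.null(plantedPeaks)) {
      plantedPeaks <- lapply(seq_along(baits), function(b) {
        lo1 <- 30L + 25L * (b - 1L)
        list(c(lo1, lo1 + 4L), c(lo1 + 60L, lo1 + 61L))
      })
      names(plantedPeaks) <- names(baits)
    }

    calls <- list(); truth <- list()
    for (b in names(baits)) {
      spans <- plantedPeaks[[b]]
      inPeak <- rep(FALSE, nF)
      for (sp in spans) {
        if (sp[1] < 1 || sp[2] > nF || sp[1] > sp[2])
          stop("planted span outside the fragment map", call. = FALSE)
        inPeak[sp[1]:sp[2]] <- TRUE
        truth[[length(truth) + 1L]] <- data.frame(bait_id = b,
                                                  lo = sp[1], hi = sp[2])
      }
      for (s in seq_len(nSamples)) {
        mu <- ifelse(inPeak, peakCountMu, bgCountMu)
        cnt <- rnbinom(nF, mu = mu, size = 1 / dispersion)
        score <- runif(nF, 0, 0.9 * scoreMin)
        score[inPeak] <- scoreMin + stats::rexp(sum(inPeak), rate = 0.3)
        calls[[length(calls) + 1L]] <- data.frame(
          bait_id = b, chrom = chr,
          frag_index = seq_len(nF),
          fragment_start = GenomicRanges::start(frc),
          count = cnt, score = score,
          sample = sprintf("s%d", s), stringsAsFactors = FALSE)
      }
    }
    list(fasta = fasta, fragmentMap = fmap,
         calls = do.call(rbind, calls),
         truth = if (length(truth)) do.call(rbind, truth)
                 else data.frame(bait_id = character(0), lo = integer(0),
                                 hi = integer(0)))
  })
}
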