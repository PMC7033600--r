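#' Tile a genome into fixed-width windows
#'
#' Produces, per chromosome, \code{ceiling(L / width)} successive windows,
#' with the last one truncated at the chromosome end — the tiling used for
#' genome-wide signal blankets (100 kb windows), chromosome-wide density
#' profiles (250 kb bins) and spike-genome size-factor intervals (10 kb /
#' 1 kb windows).
#'
#' @param genome named numeric vector of chromosome lengths, or a two-column
#'   data.frame (chrom, length).
#' @param width window width in bp.
#' @return \linkS4class{GRanges} of windows, ordered by chromosome then start.
#' @export
makeWindows <- function(genome, width) {
  if (is.data.frame(genome))
    genome <- setNames(as.numeric(genome[[2]]), as.character(genome[[1]]))
  if (is.null(names(genome)) || anyDuplicated(names(genome)))
    stop("chromosome names must be present and unique", call. = FALSE)
  if (any(genome <= 0)) stop("chromosome lengths must be > 0", call. = FALSE)
  if (!is.numeric(width) || length(width) != 1L || width < 1)
    stop("'width' must be a positive number", call. = FALSE)
  sl <- setNames(as.integer(genome), names(genome))
  # a width beyond the longest chromosome still yields one window per
  # chromosome under the ceiling rule
  width <- min(as.integer(width), max(sl))
  GenomicRanges::tileGenome(sl, tilewidth = width,
                            cut.last.tile.in.chrom = TRUE)
}

#' Count reads in genomic intervals
#'
#' Assigns reads to intervals under the any-overlap rule (a read overlapping k
#' intervals increments all k) or, optionally, by its midpoint.  Reads on
#' chromosomes absent from the interval set are tallied as unassigned with a
#' warning.
#'
#' @param reads \linkS4class{GRanges}, or a data.frame with columns
#'   \code{chrom} and \code{pos} (single-bp reads) or \code{chrom},
#'   \code{start}, \code{end}.
#' @param intervals \linkS4class{GRanges} of the counting intervals.
#' @param rule \code{"any"} (default) or \code{"midpoint"}.
#' @return integer vector of counts, one per interval (named when the
#'   intervals are), with attribute \code{"unassigned"} giving the number of
#'   reads on unknown chromosomes.
#' @export
countInIntervals <- function(reads, intervals, rule = c("any", "midpoint")) {
  rule <- match.arg(rule)
  if (is.data.frame(reads)) {
    if (all(c("start", "end") %in% colnames(reads)))
      reads <- GenomicRanges::GRanges(reads$chrom,
                                      IRanges::IRanges(reads$start, reads$end))
    else if (all(c("chrom", "pos") %in% colnames(reads)))
      reads <- GenomicRanges::GRanges(reads$chrom,
                                      IRanges::IRanges(reads$pos, width = 1L))
    else stop("reads data.frame needs chrom+pos or chrom+start+end columns",
              call. = FALSE)
  }
  if (length(intervals) == 0L) {
    out <- integer(0); attr(out, "unassigned") <- length(reads); return(out)
  }
  known <- as.character(GenomeInfoDb::seqnames(reads)) %in%
    GenomeInfoDb::seqlevelsInUse(intervals)
  nUnassigned <- sum(!known)
  if (nUnassigned > 0)
    warning(nUnassigned, " reads on chromosomes absent from the intervals",
            " were left unassigned")
  reads <- reads[known]
  if (rule == "midpoint")
    reads <- GenomicRanges::resize(reads, width = 1L, fix = "center")
  hits <- GenomicRanges::countOverlaps(intervals, reads, ignore.strand = TRUE)
  out <- as.integer(hits)
  names(out) <- names(intervals)
  attr(out, "unassigned") <- nUnassigned
  out
}

#' Scale a count matrix to per-kb signal anchored on the untreated median
#'
#' Converts counts to per-kb densities and rescales so that the median per-kb
#' value across the untreated samples maps to \code{scaleTo} (default 2, i.e.
#' log2 = 1) — the convention used for comparative boxplot signal.
#'
#' @param mat numeric matrix, regions x samples.
#' @param regionLengths region lengths in bp (> 0).
#' @param untreated column names or indices of the untreated reference
#'   samples.
#' @param scaleTo the value the untreated median is mapped to.
#' @return numeric matrix of scaled per-kb signal.
#' @export
normalizeSignal <- function(mat, regionLengths, untreated, scaleTo = 2) {
  stopifnot(nrow(mat) == length(regionLengths))
  if (any(regionLengths <= 0)) stop("region lengths must be > 0", call. = FALSE)
  perKb <- mat / (regionLengths / 1000)
  med <- median(perKb[, untreated, drop = FALSE])
  if (!is.finite(med) || med <= 0)
    stop("untreated per-kb median is not positive; add a pseudocount or ",
         "filter empty regions", call. = FALSE)
  perKb / med * scaleTo
}

#' Expression-percentile signal profile
#'
#' Ranks promoter-associated sites by the expression of the associated gene,
#' splits them into \code{nbins} equal-size bins (any remainder spread over
#' the leading bins, larger bins first), and reports per-bin mean signal
#' relative to the middle bin, whose value is 1 by construction.
#'
#' @param signal per-site signal (e.g. per-kb read density).
#' @param expression per-site expression of the associated gene.
#' @param nbins number of percentile bins (default 100).
#' @return numeric vector of length \code{nbins}: relative mean signal per
#'   expression percentile.
#' @export
percentileProfile <- function(signal, expression, nbins = 100L) {
  stopifnot(length(signal) == length(expression))
  if (!all(is.finite(expression)))
    stop("expression values must be finite", call. = FALSE)
  n <- length(signal)
  if (n < nbins)
    stop("need at least ", nbins, " sites; use the 'nbins' option to bin ",
         "more coarsely", call. = FALSE)
  ord <- order(expression, seq_len(n))        # deterministic tie-break
  sizes <- rep(n %/% nbins, nbins)
  rem <- n %% nbins
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  bin <- rep(seq_len(nbins), sizes)
  means <- tapply(signal[ord], bin, mean)
  ref <- means[[ceiling(nbins / 2)]]
  if (!is.finite(ref) || ref == 0)
    stop("reference (middle) bin mean is zero", call. = FALSE)
  as.numeric(means / ref)
}

#' Replicate correlation gate
#'
#' Pearson correlation of raw region counts for each replicate pair, with the
#' pass threshold used for merging biological replicates (r > 0.9).
#'
#' @param mat counts matrix, regions x samples.
#' @param pairs two-column matrix/data.frame of sample names or indices.
#' @param minR pass threshold (exclusive).
#' @return data.frame with columns \code{sample1}, \code{sample2}, \code{r},
#'   \code{pass}.
#' @export
replicateCorrelation <- function(mat, pairs, minR = 0.9) {
  if (nrow(mat) < 3) stop("need at least 3 regions", call. = FALSE)
  pairs <- as.matrix(pairs)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- mat[, pairs[i, 1]]; b <- mat[, pairs[i, 2]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      stop("zero-variance sample in pair ", i, call. = FALSE)
    r <- cor(a, b)
    data.frame(sample1 = as.character(pairs[i, 1]),
               sample2 = as.character(pairs[i, 2]),
               r = r, pass = r > minR, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
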