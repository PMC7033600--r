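#' In-silico restriction digestion of a genome
#'
#' Scans each sequence for exact occurrences of the recognition motif
#' (default GATC, the DpnII site) and cuts immediately before the motif's
#' first base, so fragments tile each chromosome without gaps or overlaps.
#' Ambiguity codes (N) never match.
#'
#' @param sequences a \code{DNAStringSet}, or path to a FASTA file.
#' @param motif recognition motif (default \code{"GATC"}).
#' @return a \linkS4class{FragmentMap}.
#' @export
digestGenome <- function(sequences, motif = "GATC") {
  if (is.character(sequences))
    sequences <- Biostrings::readDNAStringSet(sequences)
  if (!nchar(motif)) stop("motif must be non-empty", call. = FALSE)
  if (length(sequences) == 0 || any(Biostrings::width(sequences) == 0))
    stop("empty sequence supplied", call. = FALSE)
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  sl <- setNames(Biostrings::width(sequences), names(sequences))
  frs <- lapply(names(sequences), function(chr) {
    L <- sl[[chr]]
    hits <- Biostrings::matchPattern(motif, sequences[[chr]], fixed = TRUE)
    cuts <- sort(unique(Biostrings::start(hits)))       # cut before the motif
    cuts <- cuts[cuts > 1]                               # no zero-length lead
    starts <- c(1L, cuts)
    ends <- c(cuts - 1L, L)
    GenomicRanges::GRanges(chr, IRanges::IRanges(starts, ends),
                           frag_index = seq_along(starts), seqlengths = sl)
  })
  fr <- suppressWarnings(do.call(c, frs))
  fr$fragment_id <- seq_along(fr)
  methods::new("FragmentMap", fragments = fr, motif = motif)
}

#' Capture-normalized interaction counts
#'
#' Normalizes per-fragment weighted read counts to the total number of reads
#' aligning to the captured promoters and to the number of captured promoters
#' in the experiment, times a scale constant.
#'
#' @param w per-fragment weighted counts.
#' @param total total reads on captured promoters in the sample.
#' @param nPromoters number of captured promoters in the experiment.
#' @param scale scale constant (default 1e6).
#' @return normalized counts: \code{w / total / nPromoters * scale}.
#' @export
normalizeCaptureCounts <- function(w, total, nPromoters, scale = 1e6) {
  if (any(total <= 0)) stop("total promoter reads must be > 0", call. = FALSE)
  if (any(nPromoters < 1)) stop("need at least one promoter", call. = FALSE)
  w / total / nPromoters * scale
}

#' Merge significant interactions into interaction peaks
#'
#' Aggregates, per bait, the fragments whose interaction score reaches
#' \code{scoreMin} in \emph{any} sample, and merges successive significant
#' fragments whose index distance is strictly less than \code{maxGap} into a
#' single interaction peak, emitting maximal spans.
#'
#' @param calls data.frame with columns \code{bait_id}, \code{frag_index},
#'   \code{score} (and anything else, e.g. \code{sample}).
#' @param scoreMin significance cutoff (default 5).
#' @param maxGap merge distance in fragments; gaps \code{>= maxGap} separate
#'   peaks (default 10).
#' @param fragmentMap optional \linkS4class{FragmentMap}; when supplied,
#'   fragment indices outside the map raise an error.
#' @return data.frame: \code{bait_id}, \code{lo}, \code{hi} (fragment-index
#'   span), \code{n_sig} (significant fragments in the span).
#' @export
mergeInteractions <- function(calls, scoreMin = 5, maxGap = 10,
                              fragmentMap = NULL) {
  stopifnot(all(c("bait_id", "frag_index", "score") %in% colnames(calls)))
  if (!is.null(fragmentMap)) {
    nF <- max(fragments(fragmentMap)$frag_index)
    if (any(calls$frag_index < 1 | calls$frag_index > nF))
      stop("fragment index outside the fragment map", call. = FALSE)
  }
  out <- lapply(split(calls, calls$bait_id), function(cb) {
    sig <- sort(unique(cb$frag_index[cb$score >= scoreMin]))
    if (!length(sig)) return(NULL)
    grp <- cumsum(c(1L, diff(sig) >= maxGap))
    lo <- tapply(sig, grp, min); hi <- tapply(sig, grp, max)
    data.frame(bait_id = cb$bait_id[1], lo = as.integer(lo),
               hi = as.integer(hi),
               n_sig = as.integer(table(grp)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(bait_id = character(0), lo = integer(0),
                      hi = integer(0), n_sig = integer(0))
  rownames(out) <- NULL
  out[order(out$bait_id, out$lo), , drop = FALSE]
}

#' Quantify merged interaction peaks
#'
#' For each interaction peak and sample, the simple mean of normalized read
#' counts and of interaction scores over \emph{all} fragments inside the span
#' (including non-significant ones); fragments absent from the call table
#' contribute zero.
#'
#' @param peaks output of \code{\link{mergeInteractions}}.
#' @param calls data.frame with \code{bait_id}, \code{frag_index},
#'   \code{sample}, \code{score} and a count column.
#' @param countCol name of the (normalized) count column (default
#'   \code{"count"}).
#' @return data.frame: \code{bait_id}, \code{lo}, \code{hi}, \code{sample},
#'   \code{mean_count}, \code{mean_score}.
#' @export
quantifyPeaks <- function(peaks, calls, countCol = "count") {
  stopifnot(countCol %in% colnames(calls))
  res <- list()
  for (i in seq_len(nrow(peaks))) {
    span <- peaks$lo[i]:peaks$hi[i]
    cb <- calls[calls$bait_id == peaks$bait_id[i] &
                  calls$frag_index %in% span, , drop = FALSE]
    for (s in unique(calls$sample)) {
      cs <- cb[cb$sample == s, , drop = FALSE]
      nSpan <- length(span)
      res[[length(res) + 1L]] <- data.frame(
        bait_id = peaks$bait_id[i], lo = peaks$lo[i], hi = peaks$hi[i],
        sample = s,
        mean_count = sum(cs[[countCol]]) / nSpan,
        mean_score = sum(cs$score) / nSpan,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}
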