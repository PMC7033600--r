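#' Filter raw peak sets by replicate/line reproducibility and blacklist
#'
#' Keeps a peak of the reference (first) set iff it overlaps by at least 1 bp
#' a peak in every other supplied set — "both cell lines" for RING1B/SUZ12
#' style sets, "all biological replicates" for PCGF2 style sets — and then
#' discards any retained peak overlapping the blacklist.  Retained
#' coordinates are those of the reference set.
#'
#' @param peakSets list of \linkS4class{GRanges}, the reference set first.
#' @param blacklist \linkS4class{GRanges} of blacklisted regions (may be
#'   empty).
#' @param mode \code{"both_lines"} or \code{"all_replicates"} — provenance
#'   label only; the intersection rule is identical (overlap with every other
#'   set).
#' @return \linkS4class{GRanges} of retained peaks; provenance in
#'   \code{metadata()}.
#' @export
filterPeaks <- function(peakSets, blacklist = GenomicRanges::GRanges(),
                        mode = c("both_lines", "all_replicates")) {
  mode <- match.arg(mode)
  if (!is.list(peakSets) || length(peakSets) == 0)
    stop("'peakSets' must be a non-empty list of GRanges", call. = FALSE)
  if (any(vapply(peakSets, length, 1L) == 0))
    stop("empty raw peak set supplied", call. = FALSE)
  ref <- peakSets[[1]]
  keep <- rep(TRUE, length(ref))
  for (other in peakSets[-1])
    keep <- keep & GenomicRanges::countOverlaps(ref, other,
                                                ignore.strand = TRUE) > 0
  out <- ref[keep]
  if (length(blacklist))
    out <- out[GenomicRanges::countOverlaps(out, blacklist,
                                            ignore.strand = TRUE) == 0]
  S4Vectors::metadata(out) <- list(mode = mode, n_sets = length(peakSets),
                                   blacklist_removed = TRUE)
  out
}

#' Filter peaks by significant signal loss
#'
#' Retains only peaks with a significant signal decrease in the differential
#' result (padj < alpha and fold change > \code{fold}, default 2) — the
#' filter applied to RING1B peaks using the knockout-line data, which removes
#' peaks whose signal does not depend on the factor.
#'
#' @param peaks \linkS4class{GRanges}; rownames of \code{deResult} must cover
#'   \code{names(peaks)}.
#' @param deResult \linkS4class{NBResult} for the factor's loss contrast
#'   (negative log2FoldChange = loss).
#' @param alpha,fold significance thresholds.
#' @return \linkS4class{GRanges} of peaks with significant loss.
#' @export
filterBySignalLoss <- function(peaks, deResult, alpha = 0.05, fold = 2) {
  if (is.null(names(peaks)))
    stop("'peaks' must be named to match the differential result",
         call. = FALSE)
  idx <- match(names(peaks), rownames(deResult))
  if (anyNA(idx))
    stop("peak(s) missing from the differential result: ",
         paste(utils::head(names(peaks)[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  call <- callSignificant(deResult[idx, ], alpha = alpha, fold = fold)
  out <- peaks[call == "down"]
  S4Vectors::metadata(out) <- c(S4Vectors::metadata(peaks),
                                list(signal_loss_filter = TRUE,
                                     alpha = alpha, fold = fold))
  out
}

#' Joint targets of two peak sets
#'
#' Intervals of set \code{a} that overlap (>= 1 bp) any interval of set
#' \code{b} — e.g. PcG-occupied regions as RING1B peaks overlapping SUZ12
#' peaks.  Coordinates come from the first-named set.
#'
#' @param a,b \linkS4class{GRanges}.
#' @return subset of \code{a}.
#' @export
defineJointTargets <- function(a, b) {
  a[GenomicRanges::countOverlaps(a, b, ignore.strand = TRUE) > 0]
}

# promoter windows (TSS +/- halfwidth) for a transcript table
.promoterRanges <- function(transcripts, genes, halfwidth) {
  idx <- match(transcripts$gene_id, genes$gene_id)
  if (anyNA(idx)) stop("transcript with unknown gene_id", call. = FALSE)
  GenomicRanges::GRanges(genes$chrom[idx],
    IRanges::IRanges(pmax(transcripts$tss - halfwidth, 1L),
                     transcripts$tss + halfwidth - 1L),
    gene_id = transcripts$gene_id)
}

#' Classify genes by promoter overlap with NMIs and Polycomb peaks
#'
#' Implements the three-way promoter classification: a gene is
#' \code{Non-NMI} when no promoter (TSS +/- halfwidth, any transcript)
#' overlaps a non-methylated island; otherwise \code{PcG} when its promoters
#' overlap both a RING1B and a SUZ12 peak, else \code{Non-PcG}.  Under the
#' default any-promoter rule each feature may be satisfied by a different
#' promoter of a multi-transcript gene; \code{samePromoter = TRUE} requires a
#' single promoter to contact both peak sets.
#'
#' @param genes data.frame: \code{gene_id}, \code{chrom}, \code{strand}.
#' @param transcripts data.frame: \code{gene_id}, \code{tss} (1-based); one
#'   row per transcript.  Every gene needs at least one transcript.
#' @param nmi \linkS4class{GRanges} of non-methylated islands.
#' @param ring1b,suz12 filtered peak \linkS4class{GRanges}.
#' @param halfwidth promoter half-width in bp (default 2500).
#' @param samePromoter require RING1B and SUZ12 on the same promoter.
#' @return data.frame: \code{gene_id}, \code{class} (factor Non-NMI /
#'   Non-PcG / PcG).
#' @export
classifyGenes <- function(genes, transcripts, nmi, ring1b, suz12,
                          halfwidth = 2500L, samePromoter = FALSE) {
  if (!all(genes$gene_id %in% transcripts$gene_id))
    stop("gene(s) without any transcript TSS: ",
         paste(utils::head(setdiff(genes$gene_id, transcripts$gene_id), 5),
               collapse = ", "), call. = FALSE)
  prom <- .promoterRanges(transcripts, genes, halfwidth)
  ovl <- function(peaks)
    GenomicRanges::countOverlaps(prom, peaks, ignore.strand = TRUE) > 0
  hasNmi <- ovl(nmi); hasRing <- ovl(ring1b); hasSuz <- ovl(suz12)
  byGene <- function(flag)
    tapply(flag, prom$gene_id, any)[genes$gene_id]
  gNmi <- byGene(hasNmi)
  gPcg <- if (samePromoter) byGene(hasRing & hasSuz)
          else byGene(hasRing) & byGene(hasSuz)
  cls <- ifelse(!gNmi, "Non-NMI", ifelse(gPcg, "PcG", "Non-PcG"))
  data.frame(gene_id = genes$gene_id,
             class = factor(cls, levels = c("Non-NMI", "Non-PcG", "PcG")),
             stringsAsFactors = FALSE)
}

#' Flag PRC1-repressed genes
#'
#' PRC1-repressed genes are PcG-occupied genes with a significant expression
#' increase upon conditional PRC1 removal (padj < alpha, fold > fold).
#'
#' @param classification output of \code{\link{classifyGenes}}.
#' @param deCko \linkS4class{NBResult} of the knockout-line treated-vs-
#'   untreated expression contrast, rownames = gene ids.
#' @param alpha,fold significance thresholds (0.05, 1.5).
#' @return the classification with a logical \code{prc1_repressed} column.
#' @export
definePrc1Repressed <- function(classification, deCko, alpha = 0.05,
                                fold = 1.5) {
  idx <- match(classification$gene_id, rownames(deCko))
  call <- rep(factor("ns", levels = c("up", "down", "ns")),
              nrow(classification))
  call[!is.na(idx)] <- callSignificant(deCko[idx[!is.na(idx)], ],
                                       alpha = alpha, fold = fold)
  classification$prc1_repressed <-
    classification$class == "PcG" & call == "up"
  classification
}

#' Classify derepression as full or partial
#'
#' Among PRC1-repressed genes, calls a gene \emph{partially} derepressed in
#' the catalytic-mutant line when either complementary approach fires: the
#' direct contrast (mutant-treated vs knockout-treated expression) shows
#' significantly lower expression in the mutant, OR the line-by-treatment
#' interaction is significant with a smaller treatment effect in the mutant.
#' Both results must be oriented so that a negative log2 fold change means
#' "smaller in the mutant line".  Remaining flagged genes are \emph{fully}
#' derepressed; unflagged genes get \code{n/a}.
#'
#' @param classification output of \code{\link{definePrc1Repressed}}.
#' @param deDirect \linkS4class{NBResult}, mutant-treated vs knockout-treated.
#' @param deInteraction \linkS4class{NBResult} of the interaction
#'   coefficient (mutant x treated).
#' @param alpha,fold thresholds applied to both results.
#' @return the classification with a \code{derepression} factor column
#'   (\code{full}, \code{partial}, \code{n/a}).
#' @export
classifyDerepression <- function(classification, deDirect, deInteraction,
                                 alpha = 0.05, fold = 1.5) {
  stopifnot("prc1_repressed" %in% colnames(classification))
  gid <- classification$gene_id
  lowerIn <- function(de) {
    idx <- match(gid, rownames(de))
    out <- rep(FALSE, length(gid))
    ok <- !is.na(idx)
    out[ok] <- callSignificant(de[idx[ok], ], alpha = alpha,
                               fold = fold) == "down"
    out
  }
  partial <- lowerIn(deDirect) | lowerIn(deInteraction)   # union semantics
  der <- rep("n/a", length(gid))
  der[classification$prc1_repressed] <-
    ifelse(partial[classification$prc1_repressed], "partial", "full")
  classification$derepression <- factor(der,
                                        levels = c("full", "partial", "n/a"))
  classification
}
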