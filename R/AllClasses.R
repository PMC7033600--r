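#' RegionCounts: regions-by-samples counts with genome-of-origin labels
#'
#' A thin extension of \linkS4class{RangedSummarizedExperiment} that is the
#' backbone of all quantitation in the package.  Rows are genomic regions
#' carrying a \code{genome} tag (\code{"target"} or \code{"spike"}); columns
#' are sequencing samples with the metadata the calibration and differential
#' modules need (\code{sample_id}, \code{role}, \code{condition}, \code{line},
#' \code{replicate}, \code{matched_input_id}).
#'
#' @slot .. inherited from RangedSummarizedExperiment; the first assay is an
#'   integer count matrix.
#' @export
setClass("RegionCounts", contains = "RangedSummarizedExperiment")

setValidity("RegionCounts", function(object) {
  msg <- NULL
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(cnt < 0, na.rm = TRUE)) msg <- c(msg, "counts must be >= 0")
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!"genome" %in% colnames(rd))
    msg <- c(msg, "rowData column 'genome' (target|spike) is required")
  else if (!all(rd$genome %in% c("target", "spike")))
    msg <- c(msg, "rowData$genome values must be 'target' or 'spike'")
  if (is.null(msg)) TRUE else msg
})

#' Construct a RegionCounts object
#'
#' @param counts integer matrix, regions x samples.
#' @param rowRanges \linkS4class{GRanges} of the regions (same length as
#'   \code{nrow(counts)}) with a \code{genome} metadata column, or a character
#'   vector of genome tags (then unranged rows are created).
#' @param colData \code{DataFrame}/\code{data.frame} of per-sample metadata.
#' @return A \linkS4class{RegionCounts} object.
#' @export
RegionCounts <- function(counts, rowRanges, colData) {
  if (is.character(rowRanges)) {
    tags <- rowRanges
    rowRanges <- GenomicRanges::GRanges(
      rep("unplaced", nrow(counts)),
      IRanges::IRanges(seq_len(nrow(counts)), width = 1L))
    rowRanges$genome <- tags
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowRanges = rowRanges,
    colData = S4Vectors::DataFrame(colData))
  methods::new("RegionCounts", se)
}

#' @describeIn RegionCounts genome-of-origin tag per region
#' @param x a RegionCounts object
#' @export
genomeTag <- function(x) SummarizedExperiment::rowData(x)$genome

#' @describeIn RegionCounts integer count matrix
#' @export
regionCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' @describeIn RegionCounts count sub-matrix of target-genome regions
#' @export
targetCounts <- function(x) regionCounts(x)[genomeTag(x) == "target", , drop = FALSE]

#' @describeIn RegionCounts count sub-matrix of spike-genome regions
#' @export
spikeCounts <- function(x) regionCounts(x)[genomeTag(x) == "spike", , drop = FALSE]

#' @describeIn RegionCounts per-sample metadata as a data.frame
#' @export
sampleInfo <- function(x) as.data.frame(SummarizedExperiment::colData(x))

setMethod("show", "RegionCounts", function(object) {
  tags <- genomeTag(object)
  cat("RegionCounts:", nrow(object), "regions (",
      sum(tags == "target"), "target /", sum(tags == "spike"), "spike ) x",
      ncol(object), "samples\n")
  roles <- SummarizedExperiment::colData(object)$role
  if (!is.null(roles)) cat("  roles:", paste(names(table(roles)),
                                             table(roles), collapse = ", "), "\n")
})

#' NBResult: per-region negative-binomial Wald test results
#'
#' A \code{DataFrame} subclass with columns \code{baseMean},
#' \code{log2FoldChange}, \code{lfcSE}, \code{stat}, \code{pvalue},
#' \code{padj}, \code{dispersion} and logical \code{separation}; design and
#' contrast are kept in \code{metadata()}.
#' @export
setClass("NBResult", contains = "DFrame")

setValidity("NBResult", function(object) {
  need <- c("baseMean", "log2FoldChange", "lfcSE", "stat", "pvalue", "padj",
            "dispersion")
  miss <- setdiff(need, colnames(object))
  if (length(miss)) paste("missing columns:", paste(miss, collapse = ", "))
  else TRUE
})

setMethod("show", "NBResult", function(object) {
  md <- S4Vectors::metadata(object)
  cat("NBResult with", nrow(object), "regions\n")
  if (!is.null(md$design)) cat("  design:  ", deparse(md$design), "\n")
  if (!is.null(md$contrast)) cat("  contrast:", paste(md$contrast, collapse = " "), "\n")
  show(S4Vectors::DataFrame(utils::head(as.data.frame(object), 5)))
  if (nrow(object) > 5) cat("  ...", nrow(object) - 5, "more rows\n")
})

#' FragmentMap: in-silico restriction digest of a genome
#'
#' Ordered restriction fragments per chromosome plus the digestion motif.
#' Fragments tile each chromosome without gaps or overlaps, with boundaries at
#' motif cut positions.
#'
#' @slot fragments \linkS4class{GRanges} with metadata column
#'   \code{fragment_id} (integer, global order) and \code{frag_index}
#'   (integer, per-chromosome order).
#' @slot motif the recognition motif, e.g. \code{"GATC"} for DpnII.
#' @export
setClass("FragmentMap",
         representation(fragments = "GRanges", motif = "character"))

setValidity("FragmentMap", function(object) {
  fr <- object@fragments
  msg <- NULL
  if (length(object@motif) != 1L || nchar(object@motif) < 1L)
    msg <- c(msg, "motif must be a single non-empty string")
  sl <- GenomeInfoDb::seqlengths(fr)
  for (chr in GenomeInfoDb::seqlevels(fr)) {
    f <- fr[GenomeInfoDb::seqnames(fr) == chr]
    f <- f[order(GenomicRanges::start(f))]
    if (length(f) == 0) next
    if (GenomicRanges::start(f)[1] != 1L)
      msg <- c(msg, sprintf("chromosome %s does not start at 1", chr))
    if (!is.na(sl[chr]) && GenomicRanges::end(f)[length(f)] != sl[chr])
      msg <- c(msg, sprintf("chromosome %s fragments do not reach its end", chr))
    if (length(f) > 1 &&
        any(GenomicRanges::start(f)[-1] != GenomicRanges::end(f)[-length(f)] + 1L))
      msg <- c(msg, sprintf("fragments on %s have gaps or overlaps", chr))
  }
  if (is.null(msg)) TRUE else msg
})

#' @describeIn FragmentMap the fragment GRanges
#' @param x a FragmentMap
#' @export
fragments <- function(x) x@fragments

setMethod("show", "FragmentMap", function(object) {
  cat("FragmentMap:", length(object@fragments), "fragments on",
      length(GenomeInfoDb::seqlevels(object@fragments)),
      "sequences; motif", object@motif, "\n")
})
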