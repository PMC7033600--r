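#' Read / write chromosome sizes (two-column TSV)
#' @param path file path.
#' @return named integer vector of sequence lengths.
#' @export
readChromSizes <- function(path) {
  tab <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  setNames(as.integer(tab[[2]]), as.character(tab[[1]]))
}

#' @rdname readChromSizes
#' @param seqlengths named integer vector.
#' @export
writeChromSizes <- function(seqlengths, path) {
  write.table(data.frame(names(seqlengths), unname(seqlengths)), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write BED intervals
#'
#' Thin wrappers over \code{rtracklayer} import/export, which handle the
#' 0-based half-open convention of BED at the file boundary; in memory the
#' package uses 1-based closed \linkS4class{GRanges} throughout.
#' @param path file path.
#' @return \linkS4class{GRanges}.
#' @export
readBedFile <- function(path) rtracklayer::import(path, format = "BED")

#' @rdname readBedFile
#' @param gr \linkS4class{GRanges} to write.
#' @export
writeBedFile <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read / write a region count matrix TSV (region_id + one column per sample)
#' @param path file path.
#' @return integer matrix with region rownames.
#' @export
readCountMatrix <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m
}

#' @rdname readCountMatrix
#' @param mat matrix with region rownames.
#' @export
writeCountMatrix <- function(mat, path) {
  tab <- data.frame(region_id = rownames(mat), mat, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample sheet CSV
#'
#' Columns: sample_id, role (chip|input|rna|gdna), condition, line,
#' replicate, matched_input_id.
#' @param path file path.
#' @return data.frame.
#' @export
readSampleSheet <- function(path)
  read.csv(path, stringsAsFactors = FALSE)

#' @rdname readSampleSheet
#' @param samples data.frame.
#' @export
writeSampleSheet <- function(samples, path) {
  write.csv(samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write 3D image stacks as multi-page TIFF
#'
#' Stacks are stored as 16-bit multi-page TIFF (one page per z slice);
#' intensities are divided by \code{maxVal} on write and multiplied back on
#' read, so integer intensities up to \code{maxVal} round-trip exactly.
#' @param path file path.
#' @param maxVal full-scale intensity (default 65535).
#' @return 3D array (z, y, x).
#' @export
readImageStack <- function(path, maxVal = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  arr <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]] * maxVal
  round(arr)
}

#' @rdname readImageStack
#' @param stack 3D array (z, y, x), intensities in [0, maxVal].
#' @export
writeImageStack <- function(stack, path, maxVal = 65535) {
  pages <- lapply(seq_len(dim(stack)[1]),
                  function(z) pmin(pmax(stack[z, , ] / maxVal, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Write scaled coverage as bedGraph
#' @param gr \linkS4class{GRanges} with a numeric \code{score} column.
#' @param path file path.
#' @export
writeBedGraph <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
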