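#' Mixing ratio from a matched input/gDNA sample
#'
#' The spike-to-target read ratio of an input or genomic-DNA library estimates
#' the achieved spike-in cell-mixing proportion independently of
#' immunoprecipitation efficiency, and is used to correct calibration and
#' size factors for minor variations in cell mixing between samples.
#'
#' @param targetReads,spikeReads read tallies of the input/gDNA sample.
#' @return the mixing ratio r = spikeReads / targetReads.
#' @export
computeMixingRatio <- function(targetReads, spikeReads) {
  if (any(targetReads == 0))
    stop("input sample has zero target-genome reads", call. = FALSE)
  if (any(spikeReads == 0))
    stop("input sample has zero spike-in reads; calibration impossible",
         call. = FALSE)
  spikeReads / targetReads
}

#' Spike-in calibration factors with mixing-ratio correction
#'
#' For every ChIP/RNA sample in a sample sheet, computes the mixing ratio r
#' from its matched input/gDNA sample, the mixing-corrected effective spike
#' depth S = spike_reads / r, and the downsampling fraction
#' f = min(S) / S, so that the sample with the smallest corrected spike depth
#' keeps all of its reads (f = 1) and the expected corrected spike depth is
#' equal across samples after subsampling.
#'
#' @param samples data.frame with columns \code{sample_id}, \code{role}
#'   (chip|input|rna|gdna), \code{target_reads}, \code{spike_reads},
#'   \code{matched_input_id}.
#' @param reference \code{"min"} (default, consistent with subsampling: all
#'   f <= 1) or the \code{sample_id} of a designated reference sample.
#' @param seed optional seed recorded in the output for downstream
#'   subsampling reproducibility.
#' @return data.frame (one row per chip/rna sample): \code{sample_id},
#'   \code{target_reads}, \code{spike_reads}, \code{mixing_ratio},
#'   \code{effective_spike_depth}, \code{downsample_fraction}, \code{seed}.
#' @export
computeCalibration <- function(samples, reference = "min", seed = NA_integer_) {
  need <- c("sample_id", "role", "target_reads", "spike_reads",
            "matched_input_id")
  miss <- setdiff(need, colnames(samples))
  if (length(miss))
    stop("sample sheet lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  sig <- samples[samples$role %in% c("chip", "rna"), , drop = FALSE]
  inp <- samples[samples$role %in% c("input", "gdna"), , drop = FALSE]
  if (nrow(sig) == 0) stop("no chip/rna samples in the sheet", call. = FALSE)
  idx <- match(sig$matched_input_id, inp$sample_id)
  if (anyNA(idx))
    stop("missing matched input/gDNA for sample(s): ",
         paste(sig$sample_id[is.na(idx)], collapse = ", "), call. = FALSE)
  if (any(sig$spike_reads == 0))
    stop("zero spike-in reads in sample(s): ",
         paste(sig$sample_id[sig$spike_reads == 0], collapse = ", "),
         call. = FALSE)
  r <- computeMixingRatio(inp$target_reads[idx], inp$spike_reads[idx])
  S <- sig$spike_reads / r
  ref <- if (identical(reference, "min")) min(S)
         else {
           j <- match(reference, sig$sample_id)
           if (is.na(j)) stop("reference sample '", reference,
                              "' not found", call. = FALSE)
           S[j]
         }
  data.frame(sample_id = sig$sample_id,
             target_reads = sig$target_reads,
             spike_reads = sig$spike_reads,
             mixing_ratio = r,
             effective_spike_depth = S,
             downsample_fraction = ref / S,
             seed = seed,
             stringsAsFactors = FALSE)
}

#' Downsample target-genome reads by a calibration fraction
#'
#' In \code{"bernoulli"} mode each target-genome record is kept independently
#' with probability f; spike-genome records are bookkeeping only and are never
#' dropped.  In \code{"scale"} mode no record is dropped and a per-record
#' weight f is attached instead (for deterministic coverage scaling).
#'
#' @param records data.frame with at least a \code{genome} column
#'   (\code{"target"}/\code{"spike"}).
#' @param f downsampling fraction in (0, 1].
#' @param seed RNG seed (bernoulli mode).
#' @param mode \code{"bernoulli"} or \code{"scale"}.
#' @return the records, subsampled (bernoulli) or with a \code{weight}
#'   column (scale).
#' @export
downsampleReads <- function(records, f, seed = 1L,
                            mode = c("bernoulli", "scale")) {
  mode <- match.arg(mode)
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f > 1)
    stop("'f' must be in (0, 1]", call. = FALSE)
  if (mode == "scale") {
    records$weight <- ifelse(records$genome == "target", f, 1)
    return(records)
  }
  withSeed(seed, {
    keep <- records$genome != "target" | runif(nrow(records)) < f
    records[keep, , drop = FALSE]
  })
}
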