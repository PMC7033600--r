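#' Simulation configuration for dual-genome experiments
#'
#' Holds the knobs of the synthetic dual-genome (target + spike-in) sequencing
#' generator.  The defaults emulate a calibrated ChIP experiment: a fixed
#' proportion of spike-in cells mixed into every sample (with small per-sample
#' jitter), sequencing depth varying between samples, and a global
#' multiplicative depletion \code{depletionFactor} of per-cell target-genome
#' signal in the treated group while per-cell spike signal is unaffected.
#'
#' @param seed integer RNG seed.
#' @param nSamplesPerGroup replicates per condition group (default 3).
#' @param nTargetRegions number of target-genome regions (default 2000).
#' @param nSpikeRegions number of spike-genome regions (default 500).
#' @param depthRange length-2 integer vector, min/max total reads per sample.
#' @param mixingRatioBase spike cells per target cell (default 0.04, i.e. the
#'   ~1:25 mixing used in calibrated ChIP protocols).
#' @param mixingJitterCV coefficient of variation of per-sample mixing jitter.
#' @param depletionFactor per-cell target signal multiplier in treated,
#'   responsive regions; in (0, 1], 1 = null.
#' @param dispersion negative-binomial dispersion alpha of region counts
#'   (variance = mu + alpha mu^2).
#' @param fractionResponsive fraction of target regions carrying the planted
#'   depletion.
#' @return A \code{SimConfig} object.
#' @export
simConfig <- function(seed = 1L,
                      nSamplesPerGroup = 3L,
                      nTargetRegions = 2000L,
                      nSpikeRegions = 500L,
                      depthRange = c(8e5L, 12e5L),
                      mixingRatioBase = 0.04,
                      mixingJitterCV = 0.1,
                      depletionFactor = 1,
                      dispersion = 0.05,
                      fractionResponsive = 1) {
  assertScalar(seed, "seed", integer = TRUE)
  assertScalar(nSamplesPerGroup, "n_samples_per_group", lower = 1, integer = TRUE)
  assertScalar(nTargetRegions, "n_target_regions", lower = 1, integer = TRUE)
  assertScalar(nSpikeRegions, "n_spike_regions", lower = 1, integer = TRUE)
  if (!is.numeric(depthRange) || length(depthRange) != 2L || any(is.na(depthRange)))
    stop("field 'depth_range' must be two positive integers", call. = FALSE)
  if (depthRange[1] < 1 || depthRange[2] < depthRange[1])
    stop("field 'depth_range' must satisfy 1 <= low <= high", call. = FALSE)
  assertScalar(mixingRatioBase, "mixing_ratio_base", lower = 0, strict_lower = TRUE)
  assertScalar(mixingJitterCV, "mixing_jitter_cv", lower = 0)
  assertScalar(depletionFactor, "depletion_factor", lower = 0, upper = 1,
               strict_lower = TRUE)
  assertScalar(dispersion, "dispersion", lower = 0, strict_lower = TRUE)
  assertScalar(fractionResponsive, "fraction_responsive", lower = 0, upper = 1)
  structure(list(seed = as.integer(seed),
                 nSamplesPerGroup = as.integer(nSamplesPerGroup),
                 nTargetRegions = as.integer(nTargetRegions),
                 nSpikeRegions = as.integer(nSpikeRegions),
                 depthRange = as.integer(round(depthRange)),
                 mixingRatioBase = mixingRatioBase,
                 mixingJitterCV = mixingJitterCV,
                 depletionFactor = depletionFactor,
                 dispersion = dispersion,
                 fractionResponsive = fractionResponsive),
            class = "SimConfig")
}

#' @export
print.SimConfig <- function(x, ...) {
  cat("SimConfig: ", x$nSamplesPerGroup, "v", x$nSamplesPerGroup, " samples, ",
      x$nTargetRegions, " target + ", x$nSpikeRegions, " spike regions, ",
      "delta = ", x$depletionFactor, ", alpha = ", x$dispersion,
      ", mixing = ", x$mixingRatioBase, " (CV ", x$mixingJitterCV, ")\n",
      sep = "")
  invisible(x)
}
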