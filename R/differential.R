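#' Median-of-ratios size factors
#'
#' The standard count-normalization estimator: per sample, the median across
#' regions (restricted to regions with strictly positive geometric mean) of
#' the ratio of the region's count to the across-sample geometric mean of
#' that region.
#'
#' @param counts numeric matrix, regions x samples (need not be integer).
#' @return numeric vector of size factors, one per sample.
#' @export
medianOfRatios <- function(counts) {
  counts <- as.matrix(counts)
  logGeo <- rowMeans(log(counts))
  use <- is.finite(logGeo)
  if (!any(use))
    stop("no region with all-positive counts; use larger spike windows",
         call. = FALSE)
  ref <- exp(logGeo[use])
  sf <- apply(counts[use, , drop = FALSE], 2, function(k) median(k / ref))
  if (any(!is.finite(sf) | sf <= 0))
    stop("non-positive size factor estimated", call. = FALSE)
  sf
}

#' Spike-in-anchored size factors
#'
#' Size factors for calibrated differential testing: spike-genome counts are
#' first pre-normalized by each sample's mixing ratio (divided by
#' r_i / geometric-mean(r), so only ratios of r matter and factors stay near
#' 1), then passed to the median-of-ratios estimator.  Because per-cell
#' spike-in signal does not respond to treatment, these factors anchor the
#' test to per-cell target signal and preserve global changes that
#' target-derived factors would normalize away.
#'
#' @param spikeCounts counts at spike-genome intervals, regions x samples.
#' @param mixingRatios per-sample mixing ratio r from matched input/gDNA
#'   (see \code{\link{computeMixingRatio}}).
#' @return numeric vector of size factors.
#' @export
spikeSizeFactors <- function(spikeCounts, mixingRatios) {
  stopifnot(ncol(spikeCounts) == length(mixingRatios))
  if (any(mixingRatios <= 0))
    stop("mixing ratios must be positive", call. = FALSE)
  pre <- sweep(as.matrix(spikeCounts), 2, mixingRatios / geomMean(mixingRatios),
               "/")
  medianOfRatios(pre)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, capped at 1.
#' Missing values are propagated (regions excluded from testing).
#'
#' @param p vector of p-values in [0, 1].
#' @return vector of adjusted p-values.
#' @export
adjustBH <- function(p) {
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) stop("p-values outside [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

# design-cell grouping: identical model-matrix rows share fitted means
.designCells <- function(X) {
  factor(apply(X, 1, paste, collapse = "\r"))
}

#' Per-region dispersion by moments with trend shrinkage
#'
#' Method-of-moments estimate of the negative-binomial dispersion alpha
#' (variance = mu + alpha mu^2) on normalized counts, using design-cell means
#' as fitted values with a residual-degrees-of-freedom correction, then
#' shrunk toward a mean-dispersion trend fitted across regions (binned means
#' of the raw estimates over the normalized-mean axis) and floored.
#'
#' @param counts integer matrix, regions x samples.
#' @param sizeFactors per-sample size factors.
#' @param design model matrix (samples x coefficients), or a factor of group
#'   labels.
#' @param priorDf weight of the trend in the shrinkage, in
#'   pseudo-degrees-of-freedom; the per-region estimate carries its residual
#'   df.
#' @param nbinsTrend number of normalized-mean bins for the trend fit.
#' @param floor lower bound on the returned dispersions.
#' @return numeric vector of dispersions (NA for all-zero regions), with the
#'   fitted trend in attribute \code{"trend"}.
#' @export
momentDispersions <- function(counts, sizeFactors, design,
                              priorDf = 20, nbinsTrend = 20L, floor = 1e-8) {
  counts <- as.matrix(counts)
  n <- ncol(counts)
  stopifnot(length(sizeFactors) == n)
  cells <- if (is.factor(design) || is.character(design)) factor(design)
           else .designCells(as.matrix(design))
  p <- nlevels(cells)
  if (n - p < 1)
    stop("no residual degrees of freedom to estimate dispersions",
         call. = FALSE)
  q <- sweep(counts, 2, sizeFactors, "/")
  mu <- matrix(0, nrow(counts), n)
  for (lv in levels(cells)) {
    j <- cells == lv
    mu[, j] <- rowMeans(q[, j, drop = FALSE])
  }
  resid2 <- rowSums((q - mu)^2) * n / (n - p)
  poisTerm <- rowSums(sweep(mu, 2, sizeFactors, "/"))
  M <- rowSums(mu^2)
  alphaRaw <- ifelse(M > 0, (resid2 - poisTerm) / M, NA_real_)
  muBar <- rowMeans(q)
  ok <- !is.na(alphaRaw)
  # trend: binned means of the (nonnegative-clamped) raw estimates
  trend <- rep(NA_real_, length(alphaRaw))
  if (sum(ok) >= 2) {
    brks <- unique(quantile(muBar[ok], probs = seq(0, 1, length.out = nbinsTrend + 1)))
    bin <- cut(muBar, brks, include.lowest = TRUE)
    binMean <- tapply(pmax(alphaRaw[ok], 0), bin[ok], mean)
    trend <- pmax(as.numeric(binMean[bin]), floor)
    trend[is.na(trend) & ok] <- max(mean(pmax(alphaRaw[ok], 0)), floor)
  } else trend[ok] <- floor
  d <- n - p
  alpha <- (d * pmax(alphaRaw, 0) + priorDf * trend) / (d + priorDf)
  alpha <- pmax(alpha, floor)
  alpha[!ok] <- NA_real_
  attr(alpha, "trend") <- trend
  alpha
}

# resolve a contrast specification to a numeric vector over coefficients
.resolveContrast <- function(contrast, coefNames) {
  if (is.numeric(contrast)) {
    if (length(contrast) != length(coefNames))
      stop("numeric contrast must have one entry per coefficient",
           call. = FALSE)
    return(as.numeric(contrast))
  }
  j <- match(contrast, coefNames)
  if (is.na(j))
    stop("contrast coefficient '", contrast, "' not in the design (",
         paste(coefNames, collapse = ", "), ")", call. = FALSE)
  cv <- numeric(length(coefNames)); cv[j] <- 1
  cv
}

#' Negative-binomial Wald test with externally supplied size factors
#'
#' Fits, per region, a negative-binomial log-linear model with the log size
#' factors as offset (size factors are supplied — typically spike-anchored —
#' and never re-estimated from the tested counts), using iteratively
#' reweighted least squares at the region's dispersion, and reports the Wald
#' statistic of the requested contrast against the normal reference with
#' Benjamini-Hochberg adjustment across regions.
#'
#' Regions where a design cell is all-zero (separation) get their fold change
#' recomputed from 0.5-pseudocounted counts (fitting itself never uses
#' pseudocounts) and are flagged in the \code{separation} column.
#'
#' @param counts integer matrix, regions x samples.
#' @param sizeFactors per-sample positive size factors.
#' @param colData data.frame of per-sample covariates for \code{design}.
#' @param design model formula over \code{colData} (default
#'   \code{~ condition}).
#' @param contrast coefficient name, or numeric contrast vector over the
#'   design coefficients.
#' @param dispersions optional per-region dispersions; estimated with
#'   \code{\link{momentDispersions}} when NULL.
#' @param ... passed to \code{\link{momentDispersions}}.
#' @return an \linkS4class{NBResult} with one row per region.
#' @export
nbWaldTest <- function(counts, sizeFactors, colData, design = ~ condition,
                       contrast, dispersions = NULL, ...) {
  counts <- as.matrix(counts)
  n <- ncol(counts)
  stopifnot(length(sizeFactors) == n, all(sizeFactors > 0))
  X <- model.matrix(design, data = as.data.frame(colData))
  if (qr(X)$rank < ncol(X)) {
    qrX <- qr(X)
    bad <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("design matrix not full rank; offending column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cv <- .resolveContrast(contrast, colnames(X))
  if (is.null(dispersions))
    dispersions <- momentDispersions(counts, sizeFactors, X, ...)
  off <- log(sizeFactors)
  cells <- .designCells(X)
  q <- sweep(counts, 2, sizeFactors, "/")
  m <- nrow(counts)
  est <- se <- rep(NA_real_, m)
  sep <- rep(FALSE, m)

  fitOne <- function(y, alpha) {
    fam <- MASS::negative.binomial(theta = 1 / max(alpha, 1e-8))
    fit <- suppressWarnings(glm.fit(X, y, offset = off, family = fam,
                                    control = list(maxit = 50)))
    if (anyNA(fit$coefficients)) return(NULL)
    XtWX <- crossprod(X * sqrt(fit$weights))
    cov <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(cov)) return(NULL)
    list(est = sum(cv * fit$coefficients),
         se = sqrt(max(drop(t(cv) %*% cov %*% cv), 0)))
  }

  for (i in seq_len(m)) {
    y <- counts[i, ]
    if (all(y == 0) || is.na(dispersions[i])) next
    ft <- fitOne(y, dispersions[i])
    if (is.null(ft)) next
    est[i] <- ft$est; se[i] <- ft$se
    if (any(tapply(y, cells, function(v) all(v == 0)))) {
      sep[i] <- TRUE
      ftp <- fitOne(y + 0.5, dispersions[i])      # reporting only
      if (!is.null(ftp)) est[i] <- ftp$est
    }
  }
  stat <- est / se
  pvalue <- 2 * pnorm(-abs(stat))
  res <- S4Vectors::DataFrame(
    baseMean = rowMeans(q),
    log2FoldChange = est / log(2),
    lfcSE = se / log(2),
    stat = stat,
    pvalue = pvalue,
    padj = adjustBH(pvalue),
    dispersion = as.numeric(dispersions),
    separation = sep,
    row.names = rownames(counts))
  out <- methods::new("NBResult", res)
  S4Vectors::metadata(out) <- list(design = design, contrast = contrast,
                                   sizeFactors = sizeFactors)
  out
}

#' Line-by-treatment interaction test
#'
#' Tests, per region, whether the treatment effect differs between two cell
#' lines, by fitting the full factorial model \code{~ line * treatment} and
#' reporting the interaction coefficient as the fold change.
#'
#' @param counts integer matrix, regions x samples.
#' @param sizeFactors per-sample size factors.
#' @param colData data.frame with factor columns \code{line} and
#'   \code{treatment} (reference levels first).
#' @param dispersions optional per-region dispersions.
#' @param ... passed on to \code{\link{nbWaldTest}}.
#' @return an \linkS4class{NBResult} for the interaction coefficient.
#' @export
interactionTest <- function(counts, sizeFactors, colData, dispersions = NULL,
                            ...) {
  cd <- as.data.frame(colData)
  stopifnot(all(c("line", "treatment") %in% colnames(cd)))
  cd$line <- factor(cd$line); cd$treatment <- factor(cd$treatment)
  tab <- table(cd$line, cd$treatment)
  if (any(tab == 0))
    stop("empty design cell(s): ",
         paste(apply(which(tab == 0, arr.ind = TRUE), 1, function(ij)
           paste(rownames(tab)[ij[1]], colnames(tab)[ij[2]], sep = ":")),
           collapse = ", "), call. = FALSE)
  design <- ~ line * treatment
  X <- model.matrix(design, cd)
  nbWaldTest(counts, sizeFactors, cd, design = design,
             contrast = colnames(X)[ncol(X)], dispersions = dispersions, ...)
}

#' Call significant regions
#'
#' Applies the study's significance convention: \code{up} iff
#' padj < alpha and log2 fold change > log2(fold); \code{down} symmetric;
#' otherwise \code{ns}.  A \code{fold = 2} variant is used for the
#' RING1B signal-loss peak filter.
#'
#' @param result an \linkS4class{NBResult} (or data.frame with
#'   \code{log2FoldChange} and \code{padj}).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param fold fold-change threshold (default 1.5).
#' @return factor of calls (\code{up}, \code{down}, \code{ns}) per region.
#' @export
callSignificant <- function(result, alpha = 0.05, fold = 1.5) {
  lfc <- result$log2FoldChange
  padj <- result$padj
  call <- rep("ns", length(lfc))
  sig <- !is.na(padj) & padj < alpha
  call[sig & lfc > log2(fold)] <- "up"
  call[sig & lfc < -log2(fold)] <- "down"
  factor(call, levels = c("up", "down", "ns"))
}
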