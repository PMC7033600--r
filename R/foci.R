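#' Rolling-ball background subtraction
#'
#' Per z-slice 2D rolling-ball background estimation implemented as grayscale
#' opening with a ball-profile (non-flat, spherical-cap height) structuring
#' element, following the convention of the classical 2D tool: the background
#' is the opening, the result is image minus background, clipped at 0.  A
#' flat image maps to 0; features narrower than the ball are preserved.
#'
#' @param stack 3D array (z, y, x) or a single 2D matrix.
#' @param radius ball radius in pixels (default 4).
#' @return array of the same shape, background subtracted.
#' @export
subtractBackground <- function(stack, radius = 4) {
  if (radius < 1) stop("radius must be >= 1", call. = FALSE)
  twoD <- is.matrix(stack)
  if (twoD) stack <- array(stack, c(1L, nrow(stack), ncol(stack)))
  d <- dim(stack)
  if (radius >= d[2] || radius >= d[3])
    stop("radius must be smaller than the image extent", call. = FALSE)
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2, ]
  h <- sqrt(radius^2 - offs$dy^2 - offs$dx^2)   # spherical-cap profile

  pad <- radius
  dp <- c(d[1], d[2] + 2 * pad, d[3] + 2 * pad)
  yIdx <- pmin(pmax(seq_len(dp[2]) - pad, 1L), d[2])
  xIdx <- pmin(pmax(seq_len(dp[3]) - pad, 1L), d[3])

  morph <- function(A, erode) {
    P <- A[, yIdx, xIdx, drop = FALSE]          # replicate-padded
    out <- NULL
    for (k in seq_len(nrow(offs))) {
      sub <- P[, pad + offs$dy[k] + seq_len(d[2]),
               pad + offs$dx[k] + seq_len(d[3]), drop = FALSE]
      v <- if (erode) sub - h[k] else sub + h[k]
      out <- if (is.null(out)) v else if (erode) pmin(out, v) else pmax(out, v)
    }
    out
  }
  bg <- morph(morph(stack, erode = TRUE), erode = FALSE)   # grayscale opening
  res <- pmax(stack - bg, 0)
  if (twoD) res[1, , ] else res
}

#' Otsu threshold
#'
#' Threshold maximizing the between-class variance over a 256-bin histogram
#' spanning the observed value range.  Returned as the upper edge of the
#' optimal cut bin; values strictly above it form the foreground class.
#'
#' @param values numeric vector (e.g. masked voxel intensities).
#' @param nbins number of histogram bins (default 256).
#' @return the threshold value.
#' @export
otsuThreshold <- function(values, nbins = 256L) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (length(values) < 2 || rng[1] == rng[2])
    stop("need at least two distinct values to threshold", call. = FALSE)
  brks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  cnt <- as.numeric(tabulate(findInterval(values, brks, rightmost.closed = TRUE,
                                          all.inside = TRUE), nbins))
  mids <- (brks[-1] + brks[-(nbins + 1L)]) / 2
  w0 <- cumsum(cnt)
  w1 <- sum(cnt) - w0
  s0 <- cumsum(cnt * mids)
  m0 <- s0 / w0
  m1 <- (sum(cnt * mids) - s0) / w1
  between <- w0 * w1 * (m0 - m1)^2
  between[w0 == 0 | w1 == 0] <- -Inf
  k <- which.max(between[-nbins])               # cut between bin k and k+1
  brks[k + 1L]
}

#' Label 3D connected components
#'
#' Connected-component labelling of a binary 3D array under 6- or
#' 26-connectivity, built on a voxel-adjacency graph.
#'
#' @param binary logical 3D array.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return integer array of the same shape: 0 background, 1..k component
#'   labels (labelled in order of first voxel).
#' @export
labelComponents3d <- function(binary, connectivity = 26) {
  stopifnot(connectivity %in% c(6, 26))
  d <- dim(binary)
  idx <- which(binary)
  lab <- array(0L, d)
  if (!length(idx)) return(lab)
  pos <- arrayInd(idx, d)
  key <- idx                                    # linear index as voxel key
  offsets <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offsets <- offsets[!(offsets$dz == 0 & offsets$dy == 0 & offsets$dx == 0), ]
  if (connectivity == 6)
    offsets <- offsets[abs(offsets$dz) + abs(offsets$dy) + abs(offsets$dx) == 1, ]
  edges <- list()
  for (k in seq_len(nrow(offsets))) {
    nz <- pos[, 1] + offsets$dz[k]; ny <- pos[, 2] + offsets$dy[k]
    nx <- pos[, 3] + offsets$dx[k]
    ok <- nz >= 1 & nz <= d[1] & ny >= 1 & ny <= d[2] & nx >= 1 & nx <= d[3]
    nkey <- (nx - 1) * (d[1] * d[2]) + (ny - 1) * d[1] + nz
    j <- match(nkey[ok], key)
    hit <- !is.na(j)
    if (any(hit))
      edges[[length(edges) + 1L]] <- cbind(which(ok)[hit], j[hit])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) {
    e <- do.call(rbind, edges)
    g <- igraph::add_edges(g, t(e))
  }
  comp <- igraph::components(g)$membership
  # relabel in order of first appearance for determinism
  first <- tapply(seq_along(comp), comp, min)
  relab <- integer(max(comp))
  relab[as.integer(names(sort(first)))] <- seq_along(first)
  lab[idx] <- relab[comp]
  lab
}

#' Segment nuclear foci in a 3D stack
#'
#' Per nucleus: background-subtract (rolling ball, per slice), Otsu-threshold
#' the voxels inside the nucleus mask, and label supra-threshold voxels as 3D
#' connected components; components smaller than \code{minVoxels} are
#' discarded.  Voxels outside the nucleus mask never influence the result:
#' they are replaced by the in-mask minimum before background subtraction and
#' are excluded from thresholding and labelling.
#'
#' @param stack 3D intensity array (z, y, x).
#' @param mask integer-labelled nucleus mask of the same shape (0 =
#'   background, 1..n = nuclei), or a logical array (single nucleus).
#' @param radius rolling-ball radius (default 4).
#' @param connectivity 26 (default) or 6.
#' @param minVoxels minimum focus size in voxels (default 2).
#' @return data.frame of foci: \code{nucleus}, \code{voxels}, \code{mean},
#'   \code{integrated}, centroid \code{z}, \code{y}, \code{x}.
#' @export
segmentFoci <- function(stack, mask, radius = 4, connectivity = 26,
                        minVoxels = 2L) {
  if (is.logical(mask)) mask <- array(as.integer(mask), dim(mask))
  stopifnot(identical(dim(stack), dim(mask)))
  if (!any(mask > 0)) stop("empty nucleus mask", call. = FALSE)
  out <- list()
  for (nuc in sort(unique(mask[mask > 0]))) {
    m <- mask == nuc
    s <- stack
    s[!m] <- min(stack[m])                      # mask-local: outside is inert
    bs <- subtractBackground(s, radius = radius)
    thr <- otsuThreshold(bs[m])
    lab <- labelComponents3d(bs > thr & m, connectivity = connectivity)
    ids <- setdiff(unique(as.integer(lab)), 0L)
    for (id in ids) {
      vox <- which(lab == id)
      if (length(vox) < minVoxels) next
      ints <- bs[vox]
      ctr <- colMeans(arrayInd(vox, dim(lab)))
      out[[length(out) + 1L]] <- data.frame(
        nucleus = nuc, voxels = length(vox),
        mean = mean(ints), integrated = sum(ints),
        z = ctr[1], y = ctr[2], x = ctr[3])
    }
  }
  if (!length(out))
    return(data.frame(nucleus = integer(0), voxels = integer(0),
                      mean = numeric(0), integrated = numeric(0),
                      z = numeric(0), y = numeric(0), x = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-nucleus focus summaries with brightest-quartile counts
#'
#' Summarizes segmented foci per nucleus: focus count, total and median focus
#' size, median intensity, and the number of foci whose intensity exceeds the
#' (1 - topFraction) quantile of focus intensities pooled across the whole
#' analyzed dataset (i.e. "top 25% highest intensity foci" by default;
#' \code{pool} switches to per-nucleus or per-group pooling).
#'
#' @param foci data.frame from \code{\link{segmentFoci}}; to compare
#'   conditions, rbind their foci tables with distinct nucleus ids and an
#'   optional \code{group} column.
#' @param topFraction fraction defining "bright" foci (default 0.25).
#' @param intensity \code{"mean"} (default) or \code{"integrated"}.
#' @param pool \code{"dataset"} (default), \code{"group"} or
#'   \code{"nucleus"}: which foci define the brightness quantile.
#' @param nuclei optional vector of nucleus ids to report (so empty nuclei
#'   appear with zero counts).
#' @return data.frame per nucleus: \code{nucleus}, \code{n_foci},
#'   \code{total_size}, \code{median_size}, \code{median_intensity},
#'   \code{n_bright}.
#' @export
summarizeFoci <- function(foci, topFraction = 0.25,
                          intensity = c("mean", "integrated"),
                          pool = c("dataset", "group", "nucleus"),
                          nuclei = NULL) {
  intensity <- match.arg(intensity)
  pool <- match.arg(pool)
  if (is.null(nuclei)) nuclei <- sort(unique(foci$nucleus))
  iv <- foci[[intensity]]
  cut <- function(v) quantile(v, probs = 1 - topFraction, type = 7, names = FALSE)
  thrFor <- function(i) {
    if (!nrow(foci)) return(Inf)
    switch(pool,
           dataset = cut(iv),
           group = {
             g <- foci$group[match(i, foci$nucleus)]
             cut(iv[foci$group == g])
           },
           nucleus = cut(iv[foci$nucleus == i]))
  }
  res <- lapply(nuclei, function(i) {
    fi <- foci[foci$nucleus == i, , drop = FALSE]
    if (!nrow(fi))
      return(data.frame(nucleus = i, n_foci = 0L, total_size = 0L,
                        median_size = 0, median_intensity = 0, n_bright = 0L))
    thr <- thrFor(i)
    data.frame(nucleus = i, n_foci = nrow(fi),
               total_size = sum(fi$voxels),
               median_size = median(fi$voxels),
               median_intensity = median(fi[[intensity]]),
               n_bright = sum(fi[[intensity]] > thr))
  })
  do.call(rbind, res)
}
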