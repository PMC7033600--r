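#' Simulate a 3D image stack with Gaussian foci in a nucleus mask
#'
#' Places \code{nFoci} isotropic 3D Gaussian foci at random positions inside
#' the nucleus mask (an ellipsoid by default), adds a flat background, and
#' applies Poisson shot noise.  Focus centres are rejected and resampled when
#' they fall outside the mask, too close to its boundary, or within
#' \code{minSep} voxels of an already placed focus; after \code{maxTries}
#' failed draws an error is raised.  The truth table records centres,
#' amplitudes and the integrated (noise-free) intensity added per focus.
#'
#' @param seed RNG seed.
#' @param dim stack dimensions \code{c(z, y, x)}.
#' @param nFoci number of foci.
#' @param focusSigma Gaussian sigma in voxels.
#' @param focusAmplitude peak amplitude above background; scalar or vector of
#'   length \code{nFoci}.
#' @param background flat background level (counts).
#' @param mask logical 3D array; \code{NULL} for the default ellipsoid with
#'   semi-axes 0.45 of each dimension.
#' @param minSep minimum centre-to-centre separation in voxels.
#' @param margin minimum distance of a centre from outside-mask voxels.
#' @param noise \code{"poisson"} or \code{"none"}.
#' @param maxTries total rejection-sampling budget.
#' @return list with \code{stack} (3D array, z y x), \code{mask} (logical
#'   array) and \code{truth} (data.frame: z, y, x, amplitude, integrated).
#' @export
simulateImageStack <- function(seed = 1L, dim = c(20L, 128L, 128L),
                               nFoci = 10L, focusSigma = 2,
                               focusAmplitude = 1000, background = 100,
                               mask = NULL, minSep = 8, margin = 3,
                               noise = c("poisson", "none"),
                               maxTries = 2000L) {
  noise <- match.arg(noise)
  stopifnot(length(dim) == 3L, all(dim >= 1L))
  amp <- rep_len(focusAmplitude, max(nFoci, 1L))
  withSeed(seed, {
    if (is.null(mask)) {
      ctr <- (dim + 1) / 2; rad <- 0.45 * dim
      zi <- slice.index(array(0, dim), 1); yi <- slice.index(array(0, dim), 2)
      xi <- slice.index(array(0, dim), 3)
      mask <- ((zi - ctr[1]) / rad[1])^2 + ((yi - ctr[2]) / rad[2])^2 +
        ((xi - ctr[3]) / rad[3])^2 <= 1
    }
    stopifnot(identical(base::dim(mask), as.integer(dim)))
    img <- array(background, dim)
    centers <- matrix(numeric(0), ncol = 3)
    tries <- 0L
    intg <- numeric(nFoci)
    okCenter <- function(p) {
      pi <- round(p)
      if (any(pi < 1) || any(pi > dim)) return(FALSE)
      if (!mask[pi[1], pi[2], pi[3]]) return(FALSE)
      for (d in 1:3) for (s in c(-1, 1)) {       # keep `margin` voxels inside
        q <- pi; q[d] <- q[d] + s * margin
        q[d] <- min(max(q[d], 1), dim[d])
        if (!mask[q[1], q[2], q[3]]) return(FALSE)
      }
      if (nrow(centers) &&
          any(sqrt(colSums((t(centers) - p)^2)) < minSep)) return(FALSE)
      TRUE
    }
    i <- 0L
    while (i < nFoci) {
      if (tries >= maxTries)
        stop("could not place all foci inside the mask after ", maxTries,
             " tries", call. = FALSE)
      tries <- tries + 1L
      p <- c(runif(1, 1, dim[1]), runif(1, 1, dim[2]), runif(1, 1, dim[3]))
      if (!okCenter(p)) next
      i <- i + 1L
      centers <- rbind(centers, p)
      ext <- ceiling(4 * focusSigma)
      zr <- max(1, floor(p[1] - ext)):min(dim[1], ceiling(p[1] + ext))
      yr <- max(1, floor(p[2] - ext)):min(dim[2], ceiling(p[2] + ext))
      xr <- max(1, floor(p[3] - ext)):min(dim[3], ceiling(p[3] + ext))
      gz <- exp(-(zr - p[1])^2 / (2 * focusSigma^2))
      gy <- exp(-(yr - p[2])^2 / (2 * focusSigma^2))
      gx <- exp(-(xr - p[3])^2 / (2 * focusSigma^2))
      blob <- amp[i] * outer(gz, outer(gy, gx))
      img[zr, yr, xr] <- img[zr, yr, xr] + blob
      intg[i] <- sum(blob)
    }
    if (noise == "poisson") {
      img <- array(rpois(length(img), img), dim)
    }
    truth <- if (nFoci > 0)
      data.frame(z = centers[, 1], y = centers[, 2], x = centers[, 3],
                 amplitude = amp[seq_len(nFoci)], integrated = intg)
    else data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                    amplitude = numeric(0), integrated = numeric(0))
    list(stack = img, mask = mask, truth = truth)
  })
}
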