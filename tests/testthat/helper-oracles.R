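# independent brute-force oracles shared across test files

# independent oracle: literal median-of-ratios recomputation
bruteMoR <- function(k) {
  geo <- apply(k, 1, function(row) if (all(row > 0)) prod(row)^(1 / length(row)) else NA)
  sapply(seq_len(ncol(k)), function(i) median(k[!is.na(geo), i] / geo[!is.na(geo)]))
}

# independent oracle: literal BH step-up with monotonicity enforcement
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# brute-force 1bp-overlap scan between two GRanges
bruteOverlap <- function(a, b) {
  ac <- as.character(GenomeInfoDb::seqnames(a))
  bc <- as.character(GenomeInfoDb::seqnames(b))
  sapply(seq_along(a), function(i)
    any(bc == ac[i] &
          GenomicRanges::start(b) <= GenomicRanges::end(a)[i] &
          GenomicRanges::end(b) >= GenomicRanges::start(a)[i]))
}

# brute-force flood fill oracle for 3D connected components
floodFill3d <- function(binary, connectivity = 26) {
  d <- dim(binary)
  lab <- array(0L, d)
  nxt <- 0L
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  if (connectivity == 6)
    offs <- offs[abs(offs$dz) + abs(offs$dy) + abs(offs$dx) == 1, ]
  for (i in which(binary)) {
    if (lab[i] != 0L) next
    nxt <- nxt + 1L
    queue <- list(arrayInd(i, d)[1, ])
    lab[i] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        q <- p + c(offs$dz[k], offs$dy[k], offs$dx[k])
        if (any(q < 1) || any(q > d)) next
        if (binary[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- nxt
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  lab
}

sameLabelling <- function(a, b) {
  # label arrays equal up to renaming
  fa <- as.integer(factor(a[a > 0], levels = unique(a[a > 0])))
  fb <- as.integer(factor(b[b > 0], levels = unique(b[b > 0])))
  identical(which(a > 0), which(b > 0)) && identical(fa, fb)
}
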