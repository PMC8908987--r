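#' Per-axis partial derivative volumes
#'
#' Central differences in the interior, one-sided at the faces, in voxel
#' units. Output shapes equal the input shape.
#'
#' @param volume a [VoxelVolume-class] or 3D array.
#' @return List of arrays `x`, `y`, `z`.
#' @export
partialDerivativeVolumes <- function(volume) {
  a <- if (methods::is(volume, "VoxelVolume")) volume@data else volume
  d <- dim(a)
  stopIfNot(all(d >= 3), "volume must be at least 3 voxels per axis")
  diffAxis <- function(a, ax) {
    n <- dim(a)[ax]
    pick <- function(i) {
      idx <- rep(list(quote(expr = )), 3)
      idx[[ax]] <- i
      do.call(`[`, c(list(a), idx, list(drop = FALSE)))
    }
    out <- (pick(clampIndex(seq_len(n) + 1L, n)) -
              pick(clampIndex(seq_len(n) - 1L, n)))
    # interior: /2 (central); faces: one-sided, already a single difference
    sc <- rep(0.5, n); sc[1] <- 1; sc[n] <- 1
    idx <- rep(list(quote(expr = )), 3)
    sweepDims <- array(rep(sc, each = prod(dim(a)[seq_len(ax - 1)])),
                       dim(a))
    out * sweepDims
  }
  list(x = diffAxis(a, 1), y = diffAxis(a, 2), z = diffAxis(a, 3))
}

#' Integral gradient volume
#'
#' Cumulative triple sum of a derivative volume: entry (x,y,z) equals the
#' sum of the derivative over the box `[1..x] x [1..y] x [1..z]`. This is
#' the single-pass row/plane/volume accumulation scheme (each axis is a
#' running sum of the previous accumulator, with zero initial values),
#' realized here as three nested cumulative sums. It makes the mean
#' gradient of any sub-volume an O(1) eight-corner query.
#'
#' @param Vd a 3D derivative array.
#' @return Array of the same shape with the cumulative sums.
#' @export
integralGradientVolume <- function(Vd) {
  cumAxis <- function(a, ax) {
    d <- dim(a)
    if (d[ax] == 1) return(a)
    o <- setdiff(1:3, ax)
    r <- array(apply(a, o, cumsum), c(d[ax], d[o]))
    aperm(r, match(1:3, c(ax, o)))
  }
  cumAxis(cumAxis(cumAxis(Vd, 1), 2), 3)
}

# All three integral gradient volumes of a scalar volume.
hogIntegralVolumes <- function(volume) {
  pd <- partialDerivativeVolumes(volume)
  lapply(pd, integralGradientVolume)
}

# Sum of array values over boxes [lo, hi] (inclusive, 1-based), from a
# padded cumulative array; vectorized over rows of lo/hi.
boxSumFromIntegral <- function(S, lo, hi) {
  d <- dim(S)
  P <- array(0, d + 1L)
  P[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- S
  l <- lo; h <- hi + 1L
  P[cbind(h[, 1], h[, 2], h[, 3])] -
    P[cbind(l[, 1], h[, 2], h[, 3])] -
    P[cbind(h[, 1], l[, 2], h[, 3])] -
    P[cbind(h[, 1], h[, 2], l[, 3])] +
    P[cbind(l[, 1], l[, 2], h[, 3])] +
    P[cbind(l[, 1], h[, 2], l[, 3])] +
    P[cbind(h[, 1], l[, 2], l[, 3])] -
    P[cbind(l[, 1], l[, 2], l[, 3])]
}

#' Mean gradient of a sub-volume from integral volumes
#'
#' Eight-corner inclusion-exclusion read of the three integral gradient
#' volumes, divided by the sub-volume voxel count.
#'
#' @param igv list of three cumulative arrays (`x`, `y`, `z`), as built by
#'   [integralGradientVolume()] from the partial derivative volumes.
#' @param base voxel 3-point, the sub-volume's lowest corner (1-based).
#' @param W,H,L sub-volume extents along x, y, z (>= 1).
#' @return Numeric 3-vector, the mean gradient.
#' @export
meanGradient <- function(igv, base, W, H, L) {
  stopIfNot(all(c(W, H, L) >= 1), "W, H, L must be >= 1")
  d <- dim(igv$x)
  hi <- base + c(W, H, L) - 1L
  if (any(base < 1) || any(hi > d))
    stop("sub-volume out of bounds", call. = FALSE)
  lo <- matrix(base, 1); hi <- matrix(hi, 1)
  n <- W * H * L
  c(boxSumFromIntegral(igv$x, lo, hi),
    boxSumFromIntegral(igv$y, lo, hi),
    boxSumFromIntegral(igv$z, lo, hi)) / n
}

#' Platonic-solid direction bins
#'
#' Bin directions are the vertex direction vectors of a platonic solid
#' (tetrahedron 4, octahedron 6, cube 8, icosahedron 12, dodecahedron 20;
#' the icosahedron and dodecahedron coordinates involve the golden ratio
#' `phi = (1 + sqrt(5)) / 2`). The adjacency threshold is the maximum dot
#' product over distinct direction pairs. Half binning folds each
#' antipodal vertex pair into one bin (the tetrahedron has no antipodal
#' pairs, so only full binning is supported there).
#'
#' @param solid one of `"tetrahedron"`, `"octahedron"`, `"cube"`,
#'   `"icosahedron"`, `"dodecahedron"`.
#' @param binning `"full"` or `"half"`.
#' @return List with `solid`, `directions` (unit row vectors, the full
#'   set), `binning`, `threshold`, `nBins` and (for half binning) `fold`,
#'   the full-to-half bin map.
#' @export
platonicDirections <- function(solid = c("dodecahedron", "icosahedron",
                                         "cube", "octahedron", "tetrahedron"),
                               binning = c("full", "half")) {
  solid <- match.arg(solid)
  binning <- match.arg(binning)
  phi <- (1 + sqrt(5)) / 2
  cyc <- function(v) rbind(v, v[c(2, 3, 1)], v[c(3, 1, 2)])
  signs2 <- function(gen) {
    # all sign combinations of the nonzero pattern, over cyclic shifts
    out <- NULL
    for (row in seq_len(nrow(gen))) {
      v <- gen[row, ]
      nz <- which(v != 0)
      sg <- as.matrix(expand.grid(rep(list(c(-1, 1)), length(nz))))
      for (r in seq_len(nrow(sg))) {
        w <- v; w[nz] <- abs(v[nz]) * sg[r, ]
        out <- rbind(out, w)
      }
    }
    unique(out)
  }
  V <- switch(solid,
    tetrahedron = rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)),
    octahedron = signs2(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))),
    cube = signs2(rbind(c(1, 1, 1))),
    icosahedron = signs2(cyc(c(0, 1, phi))),
    dodecahedron = rbind(signs2(rbind(c(1, 1, 1))),
                         signs2(cyc(c(0, 1 / phi, phi)))))
  V <- V / sqrt(rowSums(V^2))
  dimnames(V) <- NULL
  G <- V %*% t(V); diag(G) <- -Inf
  thr <- max(G)
  if (binning == "half") {
    anti <- apply(V, 1, function(v) {
      hit <- which(rowSums(abs(V + rep(v, each = nrow(V)))) < 1e-8)
      if (length(hit)) hit[1] else NA_integer_
    })
    if (any(is.na(anti)))
      stop("half binning requires a centrally symmetric solid", call. = FALSE)
    keep <- which(seq_len(nrow(V)) < anti)
    fold <- integer(nrow(V))
    fold[keep] <- seq_along(keep)
    fold[anti[keep]] <- seq_along(keep)
    list(solid = solid, directions = V, binning = binning, threshold = thr,
         nBins = length(keep), fold = fold)
  } else {
    list(solid = solid, directions = V, binning = binning, threshold = thr,
         nBins = nrow(V))
  }
}

#' Weighted direction vote of a mean gradient
#'
#' Projects the mean gradient onto all bin directions
#' (`C = V . N / |N|`), subtracts the adjacency threshold, clamps
#' negative components to zero and keeps only the three largest remaining
#' components (the scheme's constraint that a vector contributes to at
#' most the three nearest axes; near face centres plain thresholding
#' alone can leave more). The surviving components are rescaled so their
#' Euclidean norm equals the gradient magnitude
#' (`Ctilde = |N| C / |C|`). A zero gradient votes zero. For half
#' binning, antipodal bins are summed afterwards.
#'
#' @param N numeric 3-vector, the mean gradient.
#' @param bins a [platonicDirections()] bin set.
#' @return Per-bin vote weights, length `bins$nBins`.
#' @export
vote <- function(N, bins) {
  nb <- bins$nBins
  mag <- sqrt(sum(N^2))
  if (mag == 0) return(numeric(nb))
  C <- as.numeric(bins$directions %*% N) / mag
  C <- C - bins$threshold
  C[C < 0] <- 0
  if (sum(C > 0) > 3) {
    ord <- order(C, decreasing = TRUE)
    C[ord[-(1:3)]] <- 0
  }
  nc <- sqrt(sum(C^2))
  if (nc == 0) return(numeric(nb))
  Ct <- mag * C / nc
  if (bins$binning == "half") {
    out <- numeric(nb)
    for (b in seq_along(Ct)) out[bins$fold[b]] <- out[bins$fold[b]] + Ct[b]
    out
  } else Ct
}

# Vectorized voting for a matrix of gradients (rows); returns nGrad x nBins.
voteMatrix <- function(Nmat, bins) {
  mag <- sqrt(rowSums(Nmat^2))
  C <- Nmat %*% t(bins$directions)
  C <- C / pmax(mag, 1e-300)
  C <- C - bins$threshold
  C[C < 0] <- 0
  # keep top 3 per row
  if (ncol(C) > 3) {
    rk <- t(apply(C, 1, function(r) rank(-r, ties.method = "first")))
    C[rk > 3] <- 0
  }
  nc <- sqrt(rowSums(C^2))
  keep <- mag > 0 & nc > 0
  C[keep, ] <- C[keep, , drop = FALSE] * (mag[keep] / nc[keep])
  C[!keep, ] <- 0
  if (bins$binning == "half") {
    out <- matrix(0, nrow(C), bins$nBins)
    for (b in seq_len(ncol(C)))
      out[, bins$fold[b]] <- out[, bins$fold[b]] + C[, b]
    out
  } else C
}

#' Fast 3D histogram-of-oriented-gradients descriptor
#'
#' The VOI is padded with edge values so that it divides into
#' `nBlocks^3` blocks, each tiled by `cellSize^3`-voxel cells. Each
#' cell's mean gradient (an eight-corner integral-volume query) casts one
#' weighted vote into the platonic direction bins; cell histograms are
#' summed per block and each block histogram is L2-normalized (epsilon
#' guard `1e-12`). The concatenation over blocks is the descriptor; with
#' the defaults (5 blocks, 3-voxel cells, dodecahedron, full binning) the
#' length is `125 * 20 = 2500`.
#'
#' @param volume a [VoxelVolume-class] VOI or 3D array.
#' @param nBlocks blocks per axis (default 5).
#' @param cellSize cell side in voxels (default 3).
#' @param solid,binning see [platonicDirections()].
#' @return Named numeric descriptor, names `hog_<block>_<bin>`.
#' @export
hog3dDescriptor <- function(volume, nBlocks = 5, cellSize = 3,
                            solid = "dodecahedron", binning = "full") {
  a <- if (methods::is(volume, "VoxelVolume")) volume@data else volume
  d <- dim(a)
  stopIfNot(nBlocks >= 1 && cellSize >= 1, "nBlocks and cellSize must be >= 1")
  if (any(cellSize > ceiling(d / nBlocks)))
    stop("cell larger than block", call. = FALSE)
  bins <- platonicDirections(solid, binning)
  cellsPerBlock <- pmax(1L, as.integer(ceiling(d / (nBlocks * cellSize))))
  target <- nBlocks * cellSize * cellsPerBlock
  if (any(target != d)) {
    padded <- array(0, target)
    ix <- clampIndex(seq_len(target[1]), d[1])
    iy <- clampIndex(seq_len(target[2]), d[2])
    iz <- clampIndex(seq_len(target[3]), d[3])
    padded[, , ] <- a[ix, iy, iz]
    a <- padded
  }
  igv <- hogIntegralVolumes(a)
  nCells <- nBlocks * cellsPerBlock
  starts <- lapply(1:3, function(ax)
    (seq_len(nCells[ax]) - 1L) * cellSize + 1L)
  g <- as.matrix(expand.grid(x = starts[[1]], y = starts[[2]],
                             z = starts[[3]]))
  hi <- g + cellSize - 1L
  nvox <- cellSize^3
  Nmat <- cbind(boxSumFromIntegral(igv$x, g, hi),
                boxSumFromIntegral(igv$y, g, hi),
                boxSumFromIntegral(igv$z, g, hi)) / nvox
  votes <- voteMatrix(Nmat, bins)
  # cell -> block assignment (array order, x fastest)
  bix <- (g[, 1] - 1L) %/% (cellSize * cellsPerBlock[1])
  biy <- (g[, 2] - 1L) %/% (cellSize * cellsPerBlock[2])
  biz <- (g[, 3] - 1L) %/% (cellSize * cellsPerBlock[3])
  blockId <- bix + nBlocks * (biy + nBlocks * biz) + 1L
  desc <- numeric(nBlocks^3 * bins$nBins)
  for (b in seq_len(nBlocks^3)) {
    h <- colSums(votes[blockId == b, , drop = FALSE])
    h <- h / sqrt(sum(h^2) + 1e-12^2)
    desc[((b - 1) * bins$nBins + 1):(b * bins$nBins)] <- h
  }
  names(desc) <- sprintf("hog_%d_%d",
                         rep(seq_len(nBlocks^3) - 1L, each = bins$nBins),
                         rep(seq_len(bins$nBins) - 1L, nBlocks^3))
  desc
}
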