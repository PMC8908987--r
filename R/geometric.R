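#' Morphological descriptor of a nodule mask
#'
#' Seven fundamental geometric features of the segmented nodule:
#' \describe{
#'   \item{volume}{foreground voxel count.}
#'   \item{convex_volume}{voxel count inside the 3D convex hull of the
#'     foreground voxel centres.}
#'   \item{equivalent_diameter}{diameter (mm) of the sphere with the same
#'     physical volume, `(6 V vox / pi)^(1/3)`.}
#'   \item{surface_area}{area (mm^2) of the triangulated iso-surface
#'     (less digitization bias than voxel-face counting).}
#'   \item{solidity}{volume / convex_volume.}
#'   \item{principal_axis_length}{`4 * sqrt(largest eigenvalue)` of the
#'     second-central-moment tensor of the foreground coordinates,
#'     in mm (the same-normalized-second-moments ellipsoid convention).}
#'   \item{extent}{volume / axis-aligned bounding-box voxel count.}
#' }
#'
#' @param mask a [NoduleMask-class].
#' @return Named numeric of length 7, names `geom_<feature>`.
#' @export
geometricDescriptor <- function(mask) {
  m <- mask@data
  idx <- which(m > 0, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty mask", call. = FALSE)
  sp <- mask@spacing
  voxVol <- prod(sp)
  vol <- nrow(idx)

  convexVol <- convexVoxelCount(idx, dim(m))
  eqDiam <- (6 * vol * voxVol / pi)^(1 / 3)

  surf <- meshArea(meshFromMask(mask))

  mm <- sweep(idx, 2, sp, `*`)
  if (vol > 1) {
    ctr <- colMeans(mm)
    C <- crossprod(sweep(mm, 2, ctr)) / vol
    pal <- 4 * sqrt(max(eigen(C, symmetric = TRUE, only.values = TRUE)$values))
  } else pal <- 0

  bbox <- apply(idx, 2, range)
  extent <- vol / prod(bbox[2, ] - bbox[1, ] + 1)

  c(geom_volume = vol,
    geom_convex_volume = convexVol,
    geom_equivalent_diameter = eqDiam,
    geom_surface_area = surf,
    geom_solidity = vol / convexVol,
    geom_principal_axis_length = pal,
    geom_extent = extent)
}

# Number of voxel centres inside the convex hull of the foreground voxel
# centres. The hull is built from the boundary voxels only (quickhull on
# deterministically jittered points to break lattice degeneracy) and
# membership is a half-space test over the bounding-box voxels.
convexVoxelCount <- function(idx, dims) {
  n <- nrow(idx)
  if (n < 4) return(n)
  # boundary foreground voxels: at least one 6-neighbour outside the mask
  inMask <- array(FALSE, dims)
  inMask[idx] <- TRUE
  onBoundary <- rep(FALSE, n)
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
    nb <- sweep(idx, 2, -o)
    outside <- nb[, 1] < 1 | nb[, 1] > dims[1] |
      nb[, 2] < 1 | nb[, 2] > dims[2] |
      nb[, 3] < 1 | nb[, 3] > dims[3]
    inside <- !outside
    hit <- outside
    if (any(inside))
      hit[inside] <- !inMask[nb[inside, , drop = FALSE]]
    onBoundary <- onBoundary | hit
  }
  pts <- idx[onBoundary, , drop = FALSE]
  if (nrow(pts) < 4) return(n)
  # deterministic sub-voxel jitter against coplanar degeneracies
  h <- (pts[, 1] * 73856093 + pts[, 2] * 19349663 + pts[, 3] * 83492791) %%
    1000
  jit <- cbind((h %% 10), (h %/% 10) %% 10, (h %/% 100) %% 10)
  pts <- pts + (jit - 4.5) * 1e-5
  hull <- tryCatch(cpp_quickhull(pts), error = function(e) NULL)
  if (is.null(hull)) return(n)
  # candidate voxels: the hull's bounding box
  rngs <- lapply(1:3, function(ax)
    seq(max(1, floor(min(pts[, ax]))), min(dims[ax], ceiling(max(pts[, ax])))))
  cand <- as.matrix(expand.grid(x = rngs[[1]], y = rngs[[2]], z = rngs[[3]]))
  D <- cand %*% t(hull$normals)
  ok <- rowSums(D > matrix(hull$offsets, nrow(D), ncol(D), byrow = TRUE) +
                  1e-3) == 0
  max(sum(ok), n)
}
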