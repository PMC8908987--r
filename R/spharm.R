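#' Triangular surface mesh of a nodule mask
#'
#' Extracts the 0.5 iso-surface of the (optionally lightly smoothed)
#' binary mask with a marching-tetrahedra scheme; vertices are
#' deduplicated on grid edges so the surface is watertight. The mild
#' default smoothing suppresses voxel staircase bias in the surface
#' geometry while leaving spiculations in place; very small masks
#' (< 27 voxels) are meshed unsmoothed so they are not erased. If the
#' surface has several connected components the largest is kept with a
#' warning.
#'
#' @param mask a [NoduleMask-class].
#' @param smoothSigma pre-smoothing Gaussian sigma in voxels.
#' @return A [SurfaceMesh-class] with vertices in physical mm.
#' @export
meshFromMask <- function(mask, smoothSigma = 0.7) {
  m <- mask@data
  if (sum(m) < 1) stop("empty mask", call. = FALSE)
  if (sum(m) < 27) smoothSigma <- 0
  d <- dim(m)
  pad <- array(0, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  if (smoothSigma > 0) pad <- gaussianSmooth(pad, smoothSigma)
  res <- cpp_marching_tets(pad, 0.5)
  V <- res$vertices; F <- res$faces
  if (!nrow(F)) stop("mask produced no iso-surface", call. = FALSE)
  # largest face-connected component
  comp <- meshComponents(nrow(V), F)
  if (max(comp$id) > 1) {
    warning("mask surface has ", max(comp$id),
            " components; keeping the largest")
    keepC <- which.max(tabulate(comp$faceId))
    F <- F[comp$faceId == keepC, , drop = FALSE]
    used <- sort(unique(as.vector(F)))
    remap <- integer(nrow(V)); remap[used] <- seq_along(used)
    V <- V[used, , drop = FALSE]
    F <- matrix(remap[F], ncol = 3)
  }
  # padded 0-based voxel coords -> physical mm (origin-free)
  V <- sweep(V - 1, 2, mask@spacing, `*`)
  methods::new("SurfaceMesh", vertices = V, faces = F)
}

# Connected components of a mesh (union-find over face edges).
meshComponents <- function(nV, F) {
  parent <- seq_len(nV)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(F))) {
    a <- find(F[r, 1]); b <- find(F[r, 2]); c <- find(F[r, 3])
    parent[b] <- a; parent[find(c)] <- find(a)
  }
  root <- vapply(seq_len(nV), find, 1L)
  ids <- match(root, unique(root))
  list(id = ids, faceId = ids[F[, 1]])
}

#' Mesh surface area
#'
#' @param mesh a [SurfaceMesh-class].
#' @return Total triangle area (mm^2).
#' @export
meshArea <- function(mesh) {
  V <- mesh@vertices; F <- mesh@faces
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Attraction-repulsion mapping of a mesh to the unit sphere
#'
#' Vertices are centred, projected radially to the unit sphere, and
#' relaxed: each vertex moves toward the centroid of its mesh neighbours
#' (attraction, weight `attract`) and away from nearby non-neighbours
#' (repulsion, weight `repulse`, inverse-square falloff truncated at
#' twice the mean edge length), re-normalized to unit norm after every
#' synchronous step. Iteration stops at `iters` or when the maximum
#' displacement falls below `tol`. The relaxation keeps every node at
#' distance one from the centre while evening out the distances between
#' neighbouring nodes. If any spherical face flips orientation a
#' mapping-quality warning is raised.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param attract,repulse step weights (defaults 0.3 and 0.01; kept
#'   gentle so the relaxation evens vertex spacing without jittering the
#'   parametrization at the mesh scale).
#' @param iters iteration cap (default 100).
#' @param tol displacement tolerance (default 1e-6).
#' @return List with `xyz` (n x 3 unit vectors aligned with the mesh
#'   vertices), `theta` (colatitude), `phi` (azimuth).
#' @export
attractionRepulsionMap <- function(mesh, attract = 0.3, repulse = 0.01,
                                   iters = 100, tol = 1e-6) {
  V <- mesh@vertices
  ctr <- colMeans(V)
  X <- sweep(V, 2, ctr)
  r <- sqrt(rowSums(X^2))
  X <- X / pmax(r, 1e-12)
  adj <- meshAdjacency(nrow(V), mesh@faces)
  Y <- cpp_attraction_repulsion(X, adj$idx, adj$start, attract, repulse,
                                as.integer(iters), tol)
  # fold-over check: orientation of spherical faces vs mesh faces
  sgn <- function(P) {
    F <- mesh@faces
    a <- P[F[, 1], , drop = FALSE]
    b <- P[F[, 2], , drop = FALSE]
    c <- P[F[, 3], , drop = FALSE]
    # signed volume of (a, b, c) spanning from origin
    a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
      a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
  }
  s <- sgn(Y)
  if (length(s) && min(sign(s)) != max(sign(s)))
    warning("attraction-repulsion map has folded faces; parametrization quality reduced")
  list(xyz = Y, theta = acos(pmin(pmax(Y[, 3], -1), 1)),
       phi = atan2(Y[, 2], Y[, 1]))
}

# 0-based CSR adjacency (sorted neighbour lists) from faces.
meshAdjacency <- function(nV, F) {
  ed <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(1, 3)])
  ed <- rbind(ed, ed[, c(2, 1)])
  ed <- unique(ed)
  o <- order(ed[, 1], ed[, 2])
  ed <- ed[o, , drop = FALSE]
  cnt <- tabulate(ed[, 1], nbins = nV)
  list(idx = as.integer(ed[, 2] - 1L),
       start = as.integer(c(0, cumsum(cnt))))
}

#' Spherical-harmonic fit of a surface by iterative residual fitting
#'
#' The three coordinate functions x, y, z (centred at the vertex
#' centroid) are expanded on the real orthonormal spherical harmonics of
#' the unit-sphere parametrization, fitted order by order: order l is fit
#' by least squares to the residual left by orders 0..l-1. The
#' reconstruction error recorded after each order is the RMS Euclidean
#' vertex distance divided by the mean vertex radius (dimensionless);
#' nested least squares makes the curve non-increasing. If the vertex
#' count cannot support some order, fitting stops at the largest
#' well-posed order (with a warning) and the curve is capped there.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param param result of [attractionRepulsionMap()].
#' @param maxOrder highest SH order to fit (default 70).
#' @return An [SHFit-class].
#' @export
shFit <- function(mesh, param, maxOrder = 70) {
  stopIfNot(maxOrder >= 0, "maxOrder must be >= 0")
  V <- mesh@vertices
  ctr <- colMeans(V)
  X <- sweep(V, 2, ctr)
  n <- nrow(X)
  meanR <- mean(sqrt(rowSums(X^2)))
  Lcap <- maxOrder
  while (Lcap > 0 && n < (2 * Lcap + 1)) Lcap <- Lcap - 1L
  if (Lcap < maxOrder)
    warning("only ", n, " vertices; capping SH order at ", Lcap)
  Y <- cpp_sh_basis(pmin(pmax(param$xyz[, 3], -1), 1), param$phi,
                    as.integer(Lcap))
  coef <- matrix(0, (Lcap + 1)^2, 3)
  resid <- X
  err <- numeric(Lcap + 1)
  for (l in 0:Lcap) {
    cols <- (l^2 + 1):((l + 1)^2)
    B <- Y[, cols, drop = FALSE]
    # normal equations (bases are near-orthogonal, so well conditioned);
    # QR fallback for safety
    G <- crossprod(B)
    cf <- tryCatch(solve(G, crossprod(B, resid)),
                   error = function(e) {
                     f <- stats::lm.fit(B, resid)$coefficients
                     f[is.na(f)] <- 0
                     f
                   })
    coef[cols, ] <- cf
    resid <- resid - B %*% cf
    err[l + 1] <- sqrt(mean(rowSums(resid^2))) / meanR
  }
  names(err) <- 0:Lcap
  methods::new("SHFit", maxOrder = as.integer(Lcap), coefficients = coef,
               errorCurve = err, meanRadius = meanR)
}

#' Reconstruction-error curve descriptor
#'
#' The per-order normalized reconstruction errors for orders
#' `1..maxOrder` (length `maxOrder`, default 70). Simple shapes are
#' captured by low orders, so their error collapses early; spiculated
#' shapes need higher orders, which is what the descriptor encodes. If
#' the fit was capped below `maxOrder` the last available error is
#' carried forward.
#'
#' @param fit an [SHFit-class].
#' @param maxOrder descriptor length (default 70).
#' @return Named numeric, names `spharm_order<l>`.
#' @export
reconstructionErrorCurve <- function(fit, maxOrder = 70) {
  e <- fit@errorCurve[-1] # drop order 0
  if (length(e) < maxOrder)
    e <- c(e, rep(e[length(e)] %||% 1, maxOrder - length(e)))
  e <- e[seq_len(maxOrder)]
  names(e) <- sprintf("spharm_order%d", seq_len(maxOrder))
  e
}

#' Spherical-harmonic shape descriptor of a mask
#'
#' Convenience wrapper: mesh, spherical parametrization, iterative
#' residual fit and error curve.
#'
#' @param mask a [NoduleMask-class].
#' @param maxOrder highest order (default 70).
#' @param ... passed to [attractionRepulsionMap()].
#' @return Named numeric of length `maxOrder`.
#' @export
spharmDescriptor <- function(mask, maxOrder = 70, ...) {
  mesh <- meshFromMask(mask)
  par <- attractionRepulsionMap(mesh, ...)
  fit <- shFit(mesh, par, maxOrder = maxOrder)
  reconstructionErrorCurve(fit, maxOrder = maxOrder)
}

#' Smallest SH order reaching a target reconstruction error
#'
#' @param fit an [SHFit-class] (or a descriptor from
#'   [reconstructionErrorCurve()]).
#' @param threshold target normalized error (default 0.1).
#' @return The smallest order whose error is <= `threshold`, or
#'   `maxOrder + 1` if never reached.
#' @export
orderToReachError <- function(fit, threshold = 0.1) {
  e <- if (methods::is(fit, "SHFit")) fit@errorCurve[-1] else fit
  hit <- which(e <= threshold)
  if (length(hit)) hit[1] else length(e) + 1L
}

#' Write a mesh as an OFF file
#'
#' @param mesh a [SurfaceMesh-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMeshOFF <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh@vertices), nrow(mesh@faces)), con)
  utils::write.table(mesh@vertices, con, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(cbind(3L, mesh@faces - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
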