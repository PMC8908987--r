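# Crop a mask to its foreground bounding box plus a margin, so the view
# slices cover the nodule rather than the whole VOI.
cropToMask <- function(mask, padVox = 4) {
  idx <- which(mask@data > 0, arr.ind = TRUE)
  d <- dim(mask@data)
  lo <- pmax(apply(idx, 2, min) - padVox, 1)
  hi <- pmin(apply(idx, 2, max) + padVox, d)
  NoduleMask(mask@data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
             mask@spacing, mask@origin + (lo - 1) * mask@spacing)
}

# Multi-view peripheral sum curvature scale space.
#
# Shape is read from the binary mask's cross-sections (intensity edges
# would confound texture with shape). At each Gaussian scale the section
# is smoothed and its outline recovered as the 0.5 iso-level contour —
# for a smoothed binary object this ridge of maximal gradient is where an
# edge detector localizes the boundary, and the iso-contour arrives
# already traced and ordered. Curvature along the closed contour is
# estimated by symmetric finite differences at a pixel gap; sign
# reversals of the curvature count the boundary's lobes, and smoothing
# drives the count to zero as the section rounds off.

#' Extract the outline contour of a mask cross-section at a Gaussian scale
#'
#' Smooths the binary view with an isotropic Gaussian of standard
#' deviation `sigma` pixels, traces the 0.5 iso-level contour, keeps the
#' longest closed one, resamples it to unit-pixel arc steps and orients
#' it counter-clockwise.
#'
#' @param view a [ViewSlice-class] of a mask (or a 0/1 matrix).
#' @param sigma Gaussian scale in pixels.
#' @return n x 2 matrix of contour points (columns x, y), or `NULL` when
#'   the smoothed section has no closed outline (fully smoothed away or
#'   empty).
#' @export
detectEdges <- function(view, sigma) {
  m <- if (methods::is(view, "ViewSlice")) view@pixels else view
  if (!any(m > 0)) return(NULL)
  sm <- gaussianSmooth(m, sigma)
  cl <- grDevices::contourLines(x = seq_len(nrow(m)), y = seq_len(ncol(m)),
                                z = sm, levels = 0.5)
  if (!length(cl)) return(NULL)
  best <- NULL; bestLen <- -1
  for (cc in cl) {
    x <- cc$x; y <- cc$y
    n <- length(x)
    closed <- n > 3 && abs(x[1] - x[n]) < 1e-9 && abs(y[1] - y[n]) < 1e-9
    if (!closed) next
    x <- x[-n]; y <- y[-n]
    len <- sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
    if (len > bestLen) { bestLen <- len; best <- cbind(x, y) }
  }
  if (is.null(best)) return(NULL)
  ct <- resampleContour(best, step = 1)
  if (is.null(ct) || nrow(ct) < 3) return(NULL)
  # counter-clockwise orientation (positive shoelace area)
  x <- ct[, 1]; y <- ct[, 2]
  area <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
  if (area < 0) ct <- ct[rev(seq_len(nrow(ct))), , drop = FALSE]
  ct
}

# Resample a closed polygon to (approximately) uniform arc-length steps.
resampleContour <- function(pts, step = 1) {
  x <- pts[, 1]; y <- pts[, 2]
  dx <- diff(c(x, x[1])); dy <- diff(c(y, y[1]))
  seg <- sqrt(dx^2 + dy^2)
  L <- sum(seg)
  if (L < 3 * step) return(NULL)
  n <- max(3L, round(L / step))
  s <- cumsum(c(0, seg))
  target <- seq(0, L, length.out = n + 1)[-(n + 1)]
  xi <- stats::approx(s, c(x, x[1]), xout = target)$y
  yi <- stats::approx(s, c(y, y[1]), xout = target)$y
  cbind(xi, yi)
}

# Curvature at every contour point: symmetric differences at offset `gap`
# with wrap-around indexing, k = (x' y'' - x'' y') / (x'^2 + y'^2)^(3/2).
contourCurvature <- function(contour, gap) {
  n <- nrow(contour)
  stopIfNot(n > 2 * gap, "contour length must exceed 2 * gap")
  ip <- ((seq_len(n) - 1 + gap) %% n) + 1
  im <- ((seq_len(n) - 1 - gap) %% n) + 1
  x <- contour[, 1]; y <- contour[, 2]
  xp <- (x[ip] - x[im]) / (2 * gap)
  yp <- (y[ip] - y[im]) / (2 * gap)
  xpp <- (x[ip] - 2 * x + x[im]) / gap^2
  ypp <- (y[ip] - 2 * y + y[im]) / gap^2
  den <- (xp^2 + yp^2)^1.5
  k <- numeric(n)
  ok <- den > 1e-12
  k[ok] <- (xp[ok] * ypp[ok] - xpp[ok] * yp[ok]) / den[ok]
  k
}

#' Curvature at one point of a closed contour
#'
#' @param contour n x 2 matrix of ordered closed contour points.
#' @param t 1-based point index.
#' @param gap pixel gap for the symmetric finite differences.
#' @return Signed curvature `k(t)`; 0 where the derivative degenerates.
#' @export
curvatureAt <- function(contour, t, gap) {
  contourCurvature(contour, gap)[t]
}

#' Count curvature sign reversals along a closed contour
#'
#' Points where the curvature sign changes over the closed traversal are
#' reversal points; zero-curvature points are ignored (the previous sign
#' is carried through them).
#'
#' @inheritParams curvatureAt
#' @return Non-negative integer reversal count.
#' @export
reversalCount <- function(contour, gap) {
  k <- contourCurvature(contour, gap)
  s <- sign(k)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(s != c(s[-1], s[1]))
}

#' Multi-view peripheral sum curvature scale-space descriptor
#'
#' For each Gaussian scale in `sigmas`, the reversal counts of the
#' `nViews` cross-section contours are summed; the per-scale sums are the
#' descriptor (length `length(sigmas)`). Views whose contour disappears
#' or is shorter than `2 * gap + 1` points contribute zero. The defaults
#' (gap 15 px, 5 views) are the descriptor's operating point.
#'
#' @param mask a [NoduleMask-class].
#' @param nViews number of views (default 5).
#' @param gap curvature pixel gap (default 15).
#' @param sigmas increasing Gaussian scales in pixels (default
#'   `c(1, 2, 4, 8, 16)`).
#' @param sliceSpacing in-plane sampling step of the views, mm (default
#'   0.25). The gap and sigmas are pixel quantities, so the views are
#'   sampled at sub-millimetre pixels to put nodule contours on the
#'   pixel scale these parameters presume.
#' @param preSmoothVox 3D Gaussian pre-smoothing of the binary mask, in
#'   voxels (default 0.7): suppresses voxel staircase wiggles so the
#'   per-scale counts respond to the boundary's lobes rather than to the
#'   digitization, which also steadies the descriptor under rotation.
#'   The smoothed field is sectioned as continuous values and contoured
#'   at 0.5.
#' @return Named numeric descriptor, names `pscss_sigma<sigma>`.
#' @export
pscssDescriptor <- function(mask, nViews = 5, gap = 15,
                            sigmas = c(1, 2, 4, 8, 16),
                            sliceSpacing = 0.25, preSmoothVox = 0.7) {
  stopIfNot(nViews >= 1, "nViews must be >= 1")
  stopIfNot(all(diff(sigmas) > 0), "sigmas must be increasing")
  mask <- cropToMask(mask, padVox = 6)
  ctr <- maskCentroid(mask)
  dat <- if (preSmoothVox > 0) gaussianSmooth(mask@data, preSmoothVox)
    else mask@data
  fl <- VoxelVolume(dat, mask@spacing, mask@origin)
  views <- extractViews(fl, nViews, center = ctr, fill = 0,
                        sliceSpacing = sliceSpacing)
  out <- numeric(length(sigmas))
  for (si in seq_along(sigmas)) {
    tot <- 0L
    for (v in views) {
      ct <- detectEdges(v, sigmas[si])
      if (is.null(ct) || nrow(ct) <= 2 * gap) next
      tot <- tot + reversalCount(ct, gap)
    }
    out[si] <- tot
  }
  names(out) <- sprintf("pscss_sigma%g", sigmas)
  out
}
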