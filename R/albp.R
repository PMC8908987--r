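#' Traditional local binary pattern histogram of a 2D view
#'
#' Per-pixel code `sum(2^(i-1) * f(g_i - c))` over `N` neighbours evenly
#' spaced on a circle of radius `R` around each pixel, where `f(x) = 1`
#' iff `x >= 0`. Neighbour `i` sits at offset
#' `(-R sin(2 pi i / N), R cos(2 pi i / N))` and off-grid positions are
#' resampled by bilinear interpolation.
#'
#' @param view a [ViewSlice-class] (or a plain numeric matrix).
#' @param N neighbour count (>= 1).
#' @param R circle radius in pixels (>= 1).
#' @param support optional logical/0-1 matrix restricting which pixels
#'   contribute (e.g. the nodule cross-section).
#' @return Normalized histogram of length `2^N` (sums to 1, or all zero
#'   when no pixel is valid).
#' @export
traditionalLBP <- function(view, N = 8, R = 1, support = NULL) {
  m <- if (methods::is(view, "ViewSlice")) view@pixels else view
  stopIfNot(N >= 1 && R >= 1, "N and R must be >= 1")
  marg <- ceiling(R)
  if (nrow(m) < 2 * marg + 1 || ncol(m) < 2 * marg + 1)
    stop("view too small for radius ", R, call. = FALSE)
  codes <- lbpCodeMatrix(m, N, R)
  valid <- !is.na(codes)
  if (!is.null(support)) valid <- valid & (support > 0)
  h <- tabulate(codes[valid] + 1L, nbins = 2^N)
  if (sum(h) > 0) h / sum(h) else as.numeric(h)
}

# Per-pixel traditional LBP codes; NA where the circle leaves the grid.
lbpCodeMatrix <- function(m, N, R) {
  marg <- ceiling(R)
  xi <- (marg + 1):(nrow(m) - marg)
  yi <- (marg + 1):(ncol(m) - marg)
  cx <- rep(xi, times = length(yi))
  cy <- rep(yi, each = length(xi))
  ctr <- m[cbind(cx, cy)]
  code <- numeric(length(ctr))
  # f(0) = 1 must survive interpolation round-off on flat regions
  eps <- 1e-9 * (1 + abs(ctr))
  for (i in seq_len(N)) {
    a <- 2 * pi * i / N
    gi <- bilinearSample(m, cx - R * sin(a), cy + R * cos(a))
    code <- code + 2^(i - 1) * (gi - ctr >= -eps)
  }
  out <- matrix(NA_real_, nrow(m), ncol(m))
  out[cbind(cx, cy)] <- code
  out
}

#' Resample the circular neighbourhood of one pixel at a given level
#'
#' Level `R` uses the circle of radius `R` pixels. `full_n` takes `8 R`
#' equally spaced samples; `single_n` always takes 8; `average_n` takes
#' the `8 R` full samples and averages 8 contiguous arcs of `R` samples
#' each. Off-grid points are bilinearly interpolated.
#'
#' @param view a [ViewSlice-class] or matrix.
#' @param center pixel position `c(x, y)` (1-based).
#' @param R level / circle radius (>= 1).
#' @param scheme `"full_n"`, `"single_n"` or `"average_n"`.
#' @return List with `level` and the sampled `values`.
#' @export
resampleLevel <- function(view, center, R,
                          scheme = c("average_n", "full_n", "single_n")) {
  scheme <- match.arg(scheme)
  m <- if (methods::is(view, "ViewSlice")) view@pixels else view
  if (center[1] - R < 1 || center[1] + R > nrow(m) ||
      center[2] - R < 1 || center[2] + R > ncol(m))
    stop("circle of radius ", R, " leaves the view", call. = FALSE)
  nS <- if (scheme == "single_n") 8L else 8L * R
  a <- 2 * pi * seq_len(nS) / nS
  vals <- bilinearSample(m, center[1] - R * sin(a), center[2] + R * cos(a))
  if (scheme == "average_n")
    vals <- colMeans(matrix(vals, nrow = R))
  list(level = R, values = vals)
}

#' Five-number summary of level samples
#'
#' Median, mean, population standard deviation, minimum and maximum of
#' the gray values sampled on one level, reducing any neighbourhood size
#' to five real numbers.
#'
#' @param samples result of [resampleLevel()] (or a numeric vector).
#' @return Named numeric: `median`, `mean`, `sd`, `min`, `max`.
#' @export
levelStats <- function(samples) {
  v <- if (is.list(samples)) samples$values else samples
  stopIfNot(length(v) >= 1, "samples must be non-empty")
  c(median = stats::median(v), mean = mean(v),
    sd = sqrt(mean((v - mean(v))^2)), min = min(v), max = max(v))
}

statNames <- c("median", "mean", "sd", "min", "max")

#' Analytical LBP code maps of a 2D view
#'
#' For each pixel and each level `R = 1..RMax`, the circular
#' neighbourhood is resampled and summarized by its five statistics;
#' each statistic is then thresholded against its own mean over levels,
#' giving one `RMax`-bit code per statistic:
#' `code = sum_l 2^(l-1) * f(stat_l - mu_stat)` with `f(x) = 1` iff
#' `x >= 0`. Codes therefore lie in `[0, 2^RMax - 1]` and are invariant
#' to adding a constant to the view.
#'
#' @param view a [ViewSlice-class] or matrix.
#' @param RMax number of levels (default 3, the descriptor optimum).
#' @param scheme resampling scheme, see [resampleLevel()].
#' @param support optional 0/1 matrix restricting the evaluated pixels.
#' @return List with `maps` (five integer matrices named by statistic,
#'   `NA` outside the valid region), `RMax` and `scheme`.
#' @export
albpCodes <- function(view, RMax = 3,
                      scheme = c("average_n", "full_n", "single_n"),
                      support = NULL) {
  scheme <- match.arg(scheme)
  stopIfNot(RMax >= 1, "RMax must be >= 1")
  m <- if (methods::is(view, "ViewSlice")) view@pixels else view
  marg <- RMax
  if (nrow(m) < 2 * marg + 1 || ncol(m) < 2 * marg + 1)
    stop("view too small for ", RMax, " levels", call. = FALSE)
  xi <- (marg + 1):(nrow(m) - marg)
  yi <- (marg + 1):(ncol(m) - marg)
  cx <- rep(xi, times = length(yi))
  cy <- rep(yi, each = length(xi))
  keep <- rep(TRUE, length(cx))
  if (!is.null(support)) keep <- support[cbind(cx, cy)] > 0
  cx <- cx[keep]; cy <- cy[keep]
  maps <- lapply(statNames, function(s) matrix(NA_real_, nrow(m), ncol(m)))
  names(maps) <- statNames
  if (!length(cx))
    return(list(maps = maps, RMax = RMax, scheme = scheme))
  # stat[pixel, level, statistic]
  stats <- array(NA_real_, c(length(cx), RMax, 5L))
  for (R in seq_len(RMax)) {
    nS <- if (scheme == "single_n") 8L else 8L * R
    a <- 2 * pi * seq_len(nS) / nS
    smp <- matrix(NA_real_, length(cx), nS)
    for (t in seq_len(nS))
      smp[, t] <- bilinearSample(m, cx - R * sin(a[t]), cy + R * cos(a[t]))
    if (scheme == "average_n" && R > 1) {
      arcs <- matrix(NA_real_, length(cx), 8L)
      for (b in seq_len(8L))
        arcs[, b] <- rowMeans(smp[, ((b - 1) * R + 1):(b * R), drop = FALSE])
      smp <- arcs
    }
    mu <- rowMeans(smp)
    stats[, R, 1] <- matrixStats::rowMedians(smp)
    stats[, R, 2] <- mu
    stats[, R, 3] <- sqrt(rowMeans(smp^2) - mu^2)
    stats[, R, 4] <- matrixStats::rowMins(smp)
    stats[, R, 5] <- matrixStats::rowMaxs(smp)
  }
  for (s in seq_len(5L)) {
    st <- stats[, , s, drop = FALSE]
    dim(st) <- c(length(cx), RMax)
    muS <- rowMeans(st)
    eps <- 1e-9 * (1 + abs(muS)) # f(0) = 1, robust to round-off
    code <- numeric(length(cx))
    for (l in seq_len(RMax))
      code <- code + 2^(l - 1) * (st[, l] - muS >= -eps)
    maps[[s]][cbind(cx, cy)] <- code
  }
  list(maps = maps, RMax = RMax, scheme = scheme)
}

# Binary erosion by a (2r+1)-square: keep pixels whose whole
# neighbourhood is foreground.
erodeSupport <- function(s, r) {
  out <- s > 0
  n1 <- nrow(s); n2 <- ncol(s)
  for (dx in -r:r) for (dy in -r:r) {
    if (dx == 0 && dy == 0) next
    sh <- matrix(FALSE, n1, n2)
    xs <- seq_len(n1) + dx; ys <- seq_len(n2) + dy
    okx <- xs >= 1 & xs <= n1; oky <- ys >= 1 & ys <= n2
    sh[okx, oky] <- s[xs[okx], ys[oky]] > 0
    out <- out & sh
  }
  1 * out
}

codeHistogram <- function(codeMatrix, nbins) {
  v <- codeMatrix[!is.na(codeMatrix)]
  h <- tabulate(v + 1L, nbins = nbins)
  if (sum(h) > 0) h / sum(h) else as.numeric(h)
}

#' Multi-view analytical LBP descriptor
#'
#' Extracts `nViews` equally distributed 2D views of the VOI (planes
#' through the mask centroid sharing the z axis), computes the five ALBP
#' code maps per view restricted to the nodule cross-section (eroded by
#' `RMax + 1` pixels so every sampled neighbourhood lies inside the
#' nodule, not the background), histograms each map into `2^RMax` bins,
#' normalizes each histogram to sum 1 (all zero for an empty view) and
#' concatenates across statistics and views.
#' With the defaults (5 views, 3 levels, average resampling) the
#' descriptor has length `5 * 5 * 8 = 200`.
#'
#' @param volume a [VoxelVolume-class] VOI.
#' @param mask the aligned [NoduleMask-class].
#' @param nViews number of views (default 5).
#' @param RMax number of levels (default 3).
#' @param scheme resampling scheme (default `"average_n"`).
#' @return Named numeric descriptor, names `albp_<view>_<stat>_<bin>`.
#' @export
multiviewALBP <- function(volume, mask, nViews = 5, RMax = 3,
                          scheme = c("average_n", "full_n", "single_n")) {
  scheme <- match.arg(scheme)
  ctr <- maskCentroid(mask)
  vv <- extractViews(volume, nViews, center = ctr)
  mv <- extractViews(mask, nViews, center = ctr)
  nb <- 2^RMax
  out <- numeric(0)
  for (k in seq_len(nViews)) {
    sup <- erodeSupport(mv[[k]]@pixels, RMax + 1L)
    cm <- albpCodes(vv[[k]], RMax = RMax, scheme = scheme, support = sup)
    for (s in statNames) {
      h <- codeHistogram(cm$maps[[s]], nb)
      names(h) <- sprintf("albp_%d_%s_%d", k - 1L, s, seq_len(nb) - 1L)
      out <- c(out, h)
    }
  }
  out
}

#' Multi-view traditional LBP descriptor (baseline)
#'
#' The traditional-LBP counterpart of [multiviewALBP()]: per view, the
#' normalized `2^N`-bin histogram of traditional LBP codes over the
#' nodule cross-section, concatenated across views. Used as the
#' noise-robustness baseline.
#'
#' @inheritParams multiviewALBP
#' @param N,R traditional LBP neighbour count and radius.
#' @return Named numeric descriptor of length `nViews * 2^N`.
#' @export
multiviewLBP <- function(volume, mask, nViews = 5, N = 8, R = 1) {
  ctr <- maskCentroid(mask)
  vv <- extractViews(volume, nViews, center = ctr)
  mv <- extractViews(mask, nViews, center = ctr)
  out <- numeric(0)
  for (k in seq_len(nViews)) {
    h <- traditionalLBP(vv[[k]], N = N, R = R,
                        support = erodeSupport(mv[[k]]@pixels,
                                               ceiling(R) + 1L))
    names(h) <- sprintf("lbp_%d_%d", k - 1L, seq_along(h) - 1L)
    out <- c(out, h)
  }
  out
}
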