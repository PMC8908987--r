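# Internal numeric helpers: interpolation, separable Gaussian smoothing,
# seeded RNG scoping. Index conventions: 1-based voxel indices; sampling
# positions are fractional 1-based indices, clamped to the grid at the
# borders (nearest-value extension).

`%||%` <- function(a, b) if (is.null(a)) b else a

clampIndex <- function(i, n) pmin(pmax(i, 1), n)

# Bilinear sampling of matrix `m` at fractional 1-based positions (x, y).
bilinearSample <- function(m, x, y) {
  nx <- nrow(m); ny <- ncol(m)
  x <- pmin(pmax(x, 1), nx); y <- pmin(pmax(y, 1), ny)
  x0 <- pmin(floor(x), nx - 1L); y0 <- pmin(floor(y), ny - 1L)
  if (nx == 1L) x0 <- rep(1, length(x))
  if (ny == 1L) y0 <- rep(1, length(y))
  fx <- x - x0; fy <- y - y0
  x1 <- clampIndex(x0 + 1, nx); y1 <- clampIndex(y0 + 1, ny)
  m[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    m[cbind(x1, y0)] * fx * (1 - fy) +
    m[cbind(x0, y1)] * (1 - fx) * fy +
    m[cbind(x1, y1)] * fx * fy
}

# Trilinear sampling of 3D array `a` at fractional 1-based positions.
# Out-of-grid positions return `fill`.
trilinearSample <- function(a, x, y, z, fill = NA_real_) {
  d <- dim(a)
  inside <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  out <- rep(fill, length(x))
  if (!any(inside)) return(out)
  x <- x[inside]; y <- y[inside]; z <- z[inside]
  x0 <- pmin(pmax(floor(x), 1L), max(d[1] - 1L, 1L))
  y0 <- pmin(pmax(floor(y), 1L), max(d[2] - 1L, 1L))
  z0 <- pmin(pmax(floor(z), 1L), max(d[3] - 1L, 1L))
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  x1 <- clampIndex(x0 + 1, d[1]); y1 <- clampIndex(y0 + 1, d[2])
  z1 <- clampIndex(z0 + 1, d[3])
  c000 <- a[cbind(x0, y0, z0)]; c100 <- a[cbind(x1, y0, z0)]
  c010 <- a[cbind(x0, y1, z0)]; c001 <- a[cbind(x0, y0, z1)]
  c110 <- a[cbind(x1, y1, z0)]; c101 <- a[cbind(x1, y0, z1)]
  c011 <- a[cbind(x0, y1, z1)]; c111 <- a[cbind(x1, y1, z1)]
  v <- c000 * (1 - fx) * (1 - fy) * (1 - fz) +
    c100 * fx * (1 - fy) * (1 - fz) +
    c010 * (1 - fx) * fy * (1 - fz) +
    c001 * (1 - fx) * (1 - fy) * fz +
    c110 * fx * fy * (1 - fz) +
    c101 * fx * (1 - fy) * fz +
    c011 * (1 - fx) * fy * fz +
    c111 * fx * fy * fz
  # locally constant cells interpolate to the constant exactly
  lo <- pmin(c000, c100, c010, c001, c110, c101, c011, c111)
  hi <- pmax(c000, c100, c010, c001, c110, c101, c011, c111)
  flat <- lo == hi
  v[flat] <- lo[flat]
  out[inside] <- v
  out
}

gaussKernel1D <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian smoothing of a 2D matrix or 3D array with
# nearest-value border extension. `sigma` is in pixel/voxel units and may
# be a scalar or one value per axis.
gaussianSmooth <- function(a, sigma) {
  d <- dim(a)
  nd <- length(d)
  sigma <- rep(sigma, length.out = nd)
  for (ax in seq_len(nd)) {
    if (sigma[ax] <= 0) next
    k <- gaussKernel1D(sigma[ax])
    r <- (length(k) - 1L) / 2L
    n <- d[ax]
    acc <- array(0, d)
    for (t in seq_along(k)) {
      off <- t - r - 1L
      src <- clampIndex(seq_len(n) + off, n)
      idx <- rep(list(quote(expr = )), nd)
      idx[[ax]] <- src
      acc <- acc + k[t] * do.call(`[`, c(list(a), idx, list(drop = FALSE)))
    }
    a <- acc
  }
  a
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so package internals never disturb user randomness.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-record 32-bit sub-seed from a master seed (splitmix-style
# integer hash, kept below 2^31).
deriveSeed <- function(master, k) {
  x <- (as.double(master) * 2654435761 + as.double(k) * 40503) %% 2147483647
  as.integer(x)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
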