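# Translation-invariant Markov-Gibbs random field appearance model.
#
# The model quantizes HU values to Q levels and carries one potential
# table per clique family: the 13 pairwise offset families of the
# 26-neighbourhood (an offset and its negation form one family) plus a
# 7-voxel star family (centre + 6 face neighbours) whose configuration is
# the number of face neighbours sharing the centre's level. Potentials
# are centred empirical frequencies, the analytic first-order
# approximation of the maximum-likelihood estimate for an exponential
# family: potential(cfg) = lambda * (F_emp(cfg) - F_iid(cfg)). The
# partition function is never evaluated; the feature is the histogram of
# per-voxel Gibbs energies.

defaultOffsets <- function() {
  g <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  # one representative per {o, -o} pair: lexicographically positive
  keep <- g[, 3] > 0 | (g[, 3] == 0 & (g[, 2] > 0 | (g[, 2] == 0 & g[, 1] > 0)))
  lapply(seq_len(sum(keep)), function(i) as.integer(g[keep, , drop = FALSE][i, ]))
}

quantizeVolume <- function(a, range, Q) {
  lo <- range[1]; hi <- range[2]
  if (hi <= lo) return(array(1L, dim(a)))
  q <- floor((a - lo) / (hi - lo) * Q) + 1L
  q[q < 1L] <- 1L; q[q > Q] <- Q
  storage.mode(q) <- "integer"
  q
}

# Shift a 3D array by integer offset o, filling with `fill`.
shiftArray <- function(a, o, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    if (o[ax] >= 0) {
      dst[[ax]] <- seq_len(d[ax] - o[ax]) + o[ax]
      src[[ax]] <- seq_len(d[ax] - o[ax])
    } else {
      dst[[ax]] <- seq_len(d[ax] + o[ax])
      src[[ax]] <- seq_len(d[ax] + o[ax]) - o[ax]
    }
    if (!length(dst[[ax]])) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Count of the 6 face neighbours at the centre's level; NA outside the
# set of voxels whose full star lies in the mask.
starConfig <- function(q, m) {
  d <- dim(q)
  cnt <- array(0L, d)
  ok <- m > 0
  for (o in list(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                 c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))) {
    qs <- shiftArray(q, -o, fill = -1L)
    ms <- shiftArray(m, -o, fill = 0)
    ok <- ok & ms > 0
    cnt <- cnt + (qs == q)
  }
  cnt[!ok] <- NA_integer_
  cnt
}

#' Train a Markov-Gibbs random field on benign nodules
#'
#' Quantizes the training VOIs to `Q` levels over the pooled in-mask
#' 1st-99th HU percentile range and sets each clique family's potentials
#' to the centred empirical configuration frequencies
#' `lambda * (F_emp - F_iid)`, where `F_iid` is the frequency expected
#' from independent voxels with the same marginal level distribution.
#' Deterministic given the training set.
#'
#' @param records list of [NoduleRecord-class] (or of
#'   `list(voi =, mask =)` pairs); typically the benign training nodules.
#' @param Q quantization levels (default 32).
#' @param offsets list of integer 3-vector pairwise clique offsets;
#'   default the 13 families of the 26-neighbourhood.
#' @param lambda potential scale (default 1).
#' @return An [MGRFModel-class].
#' @export
trainMGRF <- function(records, Q = 32, offsets = defaultOffsets(),
                      lambda = 1) {
  stopIfNot(length(records) >= 1, "need at least one training nodule")
  Q <- as.integer(Q)
  getVoi <- function(r) if (methods::is(r, "NoduleRecord")) r@voi@data else r$voi@data
  getMask <- function(r) if (methods::is(r, "NoduleRecord")) r@mask@data else r$mask@data
  pooled <- unlist(lapply(records, function(r) getVoi(r)[getMask(r) > 0]))
  rng <- as.numeric(stats::quantile(pooled, c(0.01, 0.99), names = FALSE))
  if (diff(rng) <= 0) rng <- rng + c(-0.5, 0.5)
  qs <- lapply(records, function(r) quantizeVolume(getVoi(r), rng, Q))
  ms <- lapply(records, getMask)
  # marginal level distribution (in-mask)
  margCount <- numeric(Q)
  for (i in seq_along(qs))
    margCount <- margCount + tabulate(qs[[i]][ms[[i]] > 0], nbins = Q)
  p <- margCount / sum(margCount)
  pairPotentials <- vector("list", length(offsets))
  for (f in seq_along(offsets)) {
    o <- offsets[[f]]
    cnt <- matrix(0, Q, Q)
    for (i in seq_along(qs)) {
      q <- qs[[i]]; m <- ms[[i]]
      q2 <- shiftArray(q, -o, fill = -1L)
      m2 <- shiftArray(m, -o, fill = 0)
      ok <- m > 0 & m2 > 0
      if (!any(ok)) next
      code <- (q[ok] - 1L) * Q + q2[ok]
      cnt <- cnt + matrix(tabulate(code, nbins = Q * Q), Q, Q, byrow = TRUE)
    }
    tot <- sum(cnt)
    Femp <- if (tot > 0) (cnt + t(cnt)) / (2 * tot) else matrix(0, Q, Q)
    pairPotentials[[f]] <- lambda * (Femp - outer(p, p))
  }
  starCount <- numeric(7)
  for (i in seq_along(qs)) {
    k <- starConfig(qs[[i]], ms[[i]])
    k <- k[!is.na(k)]
    if (length(k)) starCount <- starCount + tabulate(k + 1L, nbins = 7)
  }
  FempS <- if (sum(starCount) > 0) starCount / sum(starCount) else numeric(7)
  kk <- 0:6
  FiidS <- vapply(kk, function(k)
    sum(p * choose(6, k) * p^k * (1 - p)^(6 - k)), 1)
  starPotential <- lambda * (FempS - FiidS)
  model <- methods::new("MGRFModel", Q = Q, range = rng, offsets = offsets,
                        pairPotentials = pairPotentials,
                        starPotential = starPotential,
                        energyRange = c(0, 0))
  # reference energy range for histogram binning: training percentiles
  en <- unlist(lapply(records, function(r) {
    e <- gibbsEnergyImage(if (methods::is(r, "NoduleRecord")) r@voi else r$voi,
                          if (methods::is(r, "NoduleRecord")) r@mask else r$mask,
                          model)
    e@data[getMask(r) > 0]
  }))
  er <- as.numeric(stats::quantile(en, c(0.005, 0.995), names = FALSE))
  if (diff(er) <= 0) er <- er + c(-1e-6, 1e-6)
  model@energyRange <- er
  model
}

#' Per-voxel Gibbs energy image
#'
#' For each in-mask voxel, the energy is minus the sum of the potentials
#' of all cliques containing it (pairwise cliques whose two voxels both
#' lie in the mask, and star cliques fully inside the mask). Voxels
#' outside the mask are set to 0.
#'
#' @param voi a [VoxelVolume-class].
#' @param mask the aligned [NoduleMask-class].
#' @param model a trained [MGRFModel-class].
#' @return A [VoxelVolume-class] holding the energy image.
#' @export
gibbsEnergyImage <- function(voi, mask, model) {
  if (!identical(dim(voi@data), dim(mask@data)))
    stop("voi and mask shapes differ", call. = FALSE)
  q <- quantizeVolume(voi@data, model@range, model@Q)
  m <- mask@data
  acc <- array(0, dim(q))
  Q <- model@Q
  for (f in seq_along(model@offsets)) {
    o <- model@offsets[[f]]
    P <- model@pairPotentials[[f]]
    q2 <- shiftArray(q, -o, fill = -1L)
    m2 <- shiftArray(m, -o, fill = 0)
    ok <- m > 0 & m2 > 0
    pot <- array(0, dim(q))
    pot[ok] <- P[cbind(q[ok], q2[ok])]
    acc <- acc + pot + shiftArray(pot, o, fill = 0)
  }
  k <- starConfig(q, m)
  okS <- !is.na(k)
  potS <- array(0, dim(q))
  potS[okS] <- model@starPotential[k[okS] + 1L]
  acc <- acc + potS
  for (o in list(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                 c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L)))
    acc <- acc + shiftArray(potS, o, fill = 0)
  e <- -acc
  e[m <= 0] <- 0
  VoxelVolume(e, voi@spacing, voi@origin)
}

#' Gibbs-energy histogram descriptor
#'
#' Normalized histogram of the in-mask Gibbs energies over a fixed global
#' range (by default the model's training-set 0.5-99.5 energy percentile
#' range; energies outside it are clipped into the end bins).
#'
#' @param energy the energy image from [gibbsEnergyImage()].
#' @param mask the aligned [NoduleMask-class].
#' @param nBins number of bins (>= 2; default 1000, the configuration
#'   carried through the classification stage).
#' @param range numeric(2) global bin range; defaults to the model's
#'   stored `energyRange` and must be supplied when calling without a
#'   model.
#' @return Named numeric histogram summing to 1, names `mgrf_<bin>`.
#' @export
energyHistogram <- function(energy, mask, nBins = 1000, range) {
  stopIfNot(nBins >= 2, "nBins must be >= 2")
  v <- energy@data[mask@data > 0]
  lo <- range[1]; hi <- range[2]
  b <- floor((v - lo) / (hi - lo) * nBins) + 1L
  b[b < 1L] <- 1L; b[b > nBins] <- nBins
  h <- tabulate(b, nbins = nBins)
  h <- if (sum(h) > 0) h / sum(h) else as.numeric(h)
  names(h) <- sprintf("mgrf_%d", seq_len(nBins) - 1L)
  h
}

#' Serialize / restore an MGRF model as JSON
#'
#' @param model an [MGRFModel-class].
#' @param path JSON file path.
#' @return `writeMGRFModel()` returns `path` invisibly; `readMGRFModel()`
#'   the restored model.
#' @export
writeMGRFModel <- function(model, path) {
  obj <- list(Q = model@Q, range = model@range,
              offsets = do.call(rbind, model@offsets),
              pairPotentials = lapply(model@pairPotentials, as.vector),
              starPotential = model@starPotential,
              energyRange = model@energyRange)
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname writeMGRFModel
#' @export
readMGRFModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  Q <- as.integer(obj$Q)
  pp <- obj$pairPotentials
  if (is.matrix(pp)) pp <- lapply(seq_len(nrow(pp)), function(i) pp[i, ])
  methods::new("MGRFModel", Q = Q, range = as.numeric(obj$range),
               offsets = lapply(seq_len(nrow(obj$offsets)),
                                function(i) as.integer(obj$offsets[i, ])),
               pairPotentials = lapply(pp, matrix, nrow = Q, ncol = Q),
               starPotential = as.numeric(obj$starPotential),
               energyRange = as.numeric(obj$energyRange))
}
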