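#' Synthetic nodule phantoms
#'
#' Labelled benign/malignant phantoms emulating the shape and texture
#' contrasts the descriptors are designed to detect: benign nodules are
#' near-spherical, smooth-boundary and homogeneous; malignant nodules are
#' spiculated, irregular and textured. Each phantom is a 40 mm cubic VOI
#' with a binary mask, on an isotropic 1 mm grid by default, deterministic
#' given its seed.
#'
#' Spikes are smooth von Mises-Fisher-shaped radial bumps (not hard
#' cones), so the curvature scale-space descriptor sees graded reversals
#' across Gaussian scales. Spike centres are a Fibonacci-sphere
#' arrangement under a random rotation: random in orientation but
#' guaranteed well separated, so `spikeCount` bumps yield `spikeCount`
#' distinct boundary lobes. Malignant interior texture is white noise
#' smoothed to the requested correlation length and rescaled to the
#' requested standard deviation.
#'
#' @name phantoms
NULL

phantomGrid <- function(sideMM = 40, spacingMM = 1) {
  n <- as.integer(round(sideMM / spacingMM))
  ctr <- (n + 1) / 2
  ax <- (seq_len(n) - ctr) * spacingMM
  list(n = n, ctr = ctr, ax = ax)
}

# Quasi-uniform directions on the sphere (Fibonacci lattice).
fibonacciSphere <- function(k) {
  i <- seq_len(k) - 0.5
  z <- 1 - 2 * i / k
  r <- sqrt(pmax(0, 1 - z^2))
  th <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(th), r * sin(th), z)
}

#' @rdname phantoms
#' @param radiusMM mean nodule radius, mm.
#' @param textureSigmaHU interior HU noise standard deviation.
#' @param noduleMeanHU,backgroundMeanHU mean HU inside/outside the nodule.
#' @param eccentricity maximal relative axis distortion of the benign
#'   ellipsoid (volume-preserving), in `[0, 0.1]`.
#' @param correlationMM benign interior texture correlation length, mm
#'   (default 0.8). Real benign CT texture is mildly smooth (partial
#'   volume, reconstruction kernel); perfectly white noise would leave a
#'   benign-trained Markov-Gibbs field with nothing to learn. Set to 0
#'   for white noise. The interior sd equals `textureSigmaHU` either
#'   way.
#' @param seed integer RNG seed; two calls with the same seed return
#'   identical records.
#' @param sideMM,spacingMM VOI side and isotropic spacing, mm.
#' @return A [NoduleRecord-class].
#' @export
makeBenignPhantom <- function(radiusMM = 8, textureSigmaHU = 20,
                              noduleMeanHU = -50, backgroundMeanHU = -850,
                              eccentricity = 0.08, correlationMM = 0.8,
                              seed = 1, sideMM = 40, spacingMM = 1) {
  stopIfNot(radiusMM > 0, "radiusMM must be > 0")
  stopIfNot(textureSigmaHU >= 0, "textureSigmaHU must be >= 0")
  stopIfNot(eccentricity >= 0 && eccentricity <= 0.1,
            "eccentricity must be in [0, 0.1]")
  g <- phantomGrid(sideMM, spacingMM)
  withSeed(seed, {
    # volume-preserving axis scales, each within +/- eccentricity
    e <- stats::runif(2, -eccentricity / 2, eccentricity / 2)
    s <- c(exp(e), exp(-sum(e)))
    rot <- randomRotation()
    gr <- as.matrix(expand.grid(x = g$ax, y = g$ax, z = g$ax))
    p <- gr %*% rot
    inside <- (p[, 1] / s[1])^2 + (p[, 2] / s[2])^2 + (p[, 3] / s[3])^2 <=
      radiusMM^2
    mask <- array(1 * inside, rep(g$n, 3))
    hu <- array(backgroundMeanHU, rep(g$n, 3)) + stats::rnorm(g$n^3, sd = 20)
    w <- array(stats::rnorm(g$n^3), rep(g$n, 3))
    if (correlationMM > 0 && textureSigmaHU > 0) {
      # mild CT-like smoothness; in-mask sd pinned to the target
      w <- gaussianSmooth(w, correlationMM / spacingMM)
      w <- w / stats::sd(w[inside])
    }
    hu[inside] <- noduleMeanHU + textureSigmaHU * w[inside]
    rec <- methods::new("NoduleRecord",
      voi = VoxelVolume(hu, rep(spacingMM, 3)),
      mask = NoduleMask(mask, rep(spacingMM, 3)),
      label = "benign",
      params = list(radiusMM = radiusMM, spikeCount = 0L,
                    spikeAmplitude = 0, textureSigmaHU = textureSigmaHU,
                    correlationMM = correlationMM,
                    noduleMeanHU = noduleMeanHU,
                    backgroundMeanHU = backgroundMeanHU,
                    eccentricity = eccentricity, seed = seed))
    rec
  })
}

#' @rdname phantoms
#' @param spikeCount number of radial spikes (>= 3).
#' @param spikeAmplitude relative spike height as a fraction of the
#'   radius, in `(0, 1)`.
#' @param correlationMM texture correlation length (Gaussian smoothing
#'   scale of the interior random field), mm.
#' @param orientation 3 x 3 rotation applied to the spike and lobe
#'   directions after their random placement (default identity). Setting
#'   it produces the exactly rotated twin of a phantom — the same shape
#'   in a different pose, without resampling loss — which is how the
#'   shape descriptors' rotation invariance is probed.
#' @param spikeSharpness von Mises-Fisher concentration of the radial
#'   bumps; larger is narrower.
#' @param lobeCount,lobeSharpness,lobeFactor the lobulation component:
#'   `lobeCount` wide zero-mean radial lobes (concentration
#'   `lobeSharpness`) of relative amplitude `lobeFactor * spikeAmplitude`.
#'   Narrow spikes alone barely move the convex hull, so lobulation is
#'   what drives the malignant solidity contrast (like real malignant
#'   nodules, which are lobulated as well as spiculated). The total
#'   relative perturbation is clamped at 0.9 so every mask stays inside
#'   the VOI.
#' @export
makeMalignantPhantom <- function(radiusMM = 8, spikeCount = 8,
                                 spikeAmplitude = 0.4, textureSigmaHU = 70,
                                 correlationMM = 3, noduleMeanHU = -50,
                                 backgroundMeanHU = -850, seed = 1,
                                 spikeSharpness = 50, lobeCount = 6,
                                 lobeSharpness = 8, lobeFactor = 1.8,
                                 sideMM = 40, spacingMM = 1,
                                 orientation = diag(3)) {
  stopIfNot(radiusMM > 0, "radiusMM must be > 0")
  stopIfNot(spikeCount >= 3, "spikeCount must be >= 3")
  stopIfNot(spikeAmplitude > 0 && spikeAmplitude < 1,
            "spikeAmplitude must be in (0, 1)")
  stopIfNot(textureSigmaHU >= 0, "textureSigmaHU must be >= 0")
  g <- phantomGrid(sideMM, spacingMM)
  withSeed(seed, {
    dirs <- fibonacciSphere(spikeCount) %*% randomRotation() %*% orientation
    lobeDirs <- fibonacciSphere(lobeCount) %*% randomRotation() %*%
      orientation
    gr <- as.matrix(expand.grid(x = g$ax, y = g$ax, z = g$ax))
    rho <- sqrt(rowSums(gr^2))
    u <- gr / pmax(rho, 1e-9)
    bump <- rep(0, nrow(gr))
    for (k in seq_len(spikeCount)) {
      ca <- u %*% dirs[k, ]
      bump <- bump + exp(spikeSharpness * (ca - 1))
    }
    lobe <- rep(0, nrow(gr))
    for (k in seq_len(lobeCount)) {
      ca <- u %*% lobeDirs[k, ]
      lobe <- lobe + exp(lobeSharpness * (ca - 1))
    }
    lobe <- lobe - mean(lobe)
    pert <- pmin(spikeAmplitude * (bump + lobeFactor * lobe), 0.9)
    rFun <- radiusMM * (1 + pert)
    inside <- rho <= rFun
    mask <- array(1 * inside, rep(g$n, 3))
    # correlated interior texture: smoothed white noise rescaled to the
    # requested marginal sd
    w <- array(stats::rnorm(g$n^3), rep(g$n, 3))
    if (correlationMM > 0) {
      w <- gaussianSmooth(w, correlationMM / spacingMM)
      # normalize on the interior so the in-mask sd hits the target even
      # though a correlated field has less local than global variance
      w <- w / stats::sd(w[inside])
    }
    hu <- array(backgroundMeanHU, rep(g$n, 3)) +
      stats::rnorm(g$n^3, sd = 20)
    hu[inside] <- noduleMeanHU + textureSigmaHU * w[inside]
    rec <- methods::new("NoduleRecord",
      voi = VoxelVolume(hu, rep(spacingMM, 3)),
      mask = NoduleMask(mask, rep(spacingMM, 3)),
      label = "malignant",
      params = list(radiusMM = radiusMM, spikeCount = spikeCount,
                    spikeAmplitude = spikeAmplitude,
                    textureSigmaHU = textureSigmaHU,
                    correlationMM = correlationMM,
                    noduleMeanHU = noduleMeanHU,
                    backgroundMeanHU = backgroundMeanHU,
                    spikeSharpness = spikeSharpness,
                    lobeCount = lobeCount, lobeSharpness = lobeSharpness,
                    lobeFactor = lobeFactor, seed = seed,
                    spikeDirections = dirs, lobeDirections = lobeDirs))
    rec
  })
}

#' Generate a labelled phantom cohort
#'
#' Draws per-record parameters uniformly from `paramRanges` and builds the
#' requested numbers of benign and malignant phantoms. Per-record seeds
#' are derived deterministically from the master seed, so the same seed
#' always yields the identical cohort.
#'
#' @param nBenign,nMalignant class counts (>= 0).
#' @param seed master seed.
#' @param paramRanges named list of `c(lo, hi)` ranges; defaults:
#'   radius 5-9 mm for both classes, benign texture sd 15-25 HU,
#'   malignant texture sd 50-90 HU, 6-12 spikes of relative amplitude
#'   0.3-0.5, correlation length 2-4 mm.
#' @return List of [NoduleRecord-class], benign first.
#' @export
makeCohort <- function(nBenign, nMalignant, seed = 1,
                       paramRanges = list()) {
  stopIfNot(nBenign >= 0 && nMalignant >= 0, "counts must be >= 0")
  pr <- utils::modifyList(list(
    radiusMM = c(5, 9),
    benignTextureSigmaHU = c(15, 25),
    malignantTextureSigmaHU = c(50, 90),
    spikeCount = c(6, 12),
    spikeAmplitude = c(0.3, 0.5),
    correlationMM = c(2, 4)), paramRanges)
  runifIn <- function(rng) stats::runif(1, rng[1], rng[2])
  recs <- vector("list", nBenign + nMalignant)
  for (i in seq_len(nBenign)) {
    si <- deriveSeed(seed, i)
    recs[[i]] <- withSeed(si + 1L, makeBenignPhantom(
      radiusMM = runifIn(pr$radiusMM),
      textureSigmaHU = runifIn(pr$benignTextureSigmaHU),
      seed = si))
  }
  for (j in seq_len(nMalignant)) {
    sj <- deriveSeed(seed, nBenign + j)
    recs[[nBenign + j]] <- withSeed(sj + 1L, makeMalignantPhantom(
      radiusMM = runifIn(pr$radiusMM),
      spikeCount = sample(seq(pr$spikeCount[1], pr$spikeCount[2]), 1),
      spikeAmplitude = runifIn(pr$spikeAmplitude),
      textureSigmaHU = runifIn(pr$malignantTextureSigmaHU),
      correlationMM = runifIn(pr$correlationMM),
      seed = sj))
  }
  recs
}
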