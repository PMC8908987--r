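test_that("benign phantom mask matches the lattice ball oracle", {
  r <- makeBenignPhantom(radiusMM = 8, seed = 1)
  count <- sum(noduleMask(r)@data)
  expect_lt(abs(count - 4 / 3 * pi * 8^3) / (4 / 3 * pi * 8^3), 0.10)
  expect_equal(noduleLabel(r), "benign")
  expect_identical(dim(noduleVOI(r)@data), dim(noduleMask(r)@data))
})

test_that("zero texture sigma gives an exactly constant interior", {
  r <- makeBenignPhantom(textureSigmaHU = 0, seed = 2)
  inside <- noduleVOI(r)@data[noduleMask(r)@data > 0]
  expect_true(all(inside == inside[1]))
})

test_that("phantom generation is deterministic given the seed", {
  a <- makeBenignPhantom(seed = 11); b <- makeBenignPhantom(seed = 11)
  expect_equal(noduleVOI(a)@data, noduleVOI(b)@data)
  expect_equal(noduleMask(a)@data, noduleMask(b)@data)
  m1 <- makeMalignantPhantom(seed = 12); m2 <- makeMalignantPhantom(seed = 12)
  expect_equal(noduleVOI(m1)@data, noduleVOI(m2)@data)
})

test_that("malignant boundary has at least spikeCount radial maxima", {
  # oracle: evaluate the generator's radial function on a fine spherical
  # grid and count its strict local maxima; each spike is sharp enough
  # (its peak slope exceeds the worst-case lobulation slope) to
  # contribute one, so the count is >= spikeCount
  radial <- function(u, p) {
    bump <- rowSums(exp(p$spikeSharpness *
                          (u %*% t(p$spikeDirections) - 1)))
    lobe <- rowSums(exp(p$lobeSharpness *
                          (u %*% t(p$lobeDirections) - 1)))
    # centring constant and the rare tip clamp are monotone shifts,
    # irrelevant for locating maxima; omitted
    p$radiusMM * (1 + p$spikeAmplitude * (bump + p$lobeFactor * lobe))
  }
  grid <- icosphereMesh(4)
  adj <- noduleCAD:::meshAdjacency(nrow(grid@vertices), grid@faces)
  for (s in 1:3) {
    r <- makeMalignantPhantom(spikeCount = 8, spikeAmplitude = 0.4, seed = s)
    p <- r@params
    expect_equal(nrow(p$spikeDirections), 8)
    rv <- radial(grid@vertices, p)
    nMax <- 0
    for (k in seq_along(rv)) {
      nbk <- adj$idx[(adj$start[k] + 1):adj$start[k + 1]] + 1
      if (rv[k] > max(rv[nbk])) nMax <- nMax + 1
    }
    expect_gte(nMax, 8)
  }
})

test_that("malignant interior is at least 3x noisier than benign", {
  b <- makeBenignPhantom(seed = 5)
  m <- makeMalignantPhantom(seed = 5)
  sdB <- sd(noduleVOI(b)@data[noduleMask(b)@data > 0])
  sdM <- sd(noduleVOI(m)@data[noduleMask(m)@data > 0])
  expect_gte(sdM, 3 * sdB)
})

test_that("interior variance separates classes across seeds", {
  vb <- sapply(1:20, function(s) {
    r <- makeBenignPhantom(seed = s)
    var(noduleVOI(r)@data[noduleMask(r)@data > 0])
  })
  vm <- sapply(1:20, function(s) {
    r <- makeMalignantPhantom(seed = s)
    var(noduleVOI(r)@data[noduleMask(r)@data > 0])
  })
  expect_lt(wilcox.test(vm, vb, alternative = "greater",
                        exact = FALSE)$p.value, 0.01)
})

test_that("shape statistics are separable and masks fit in the VOI", {
  solB <- sapply(1:5, function(s)
    geometricDescriptor(noduleMask(makeBenignPhantom(seed = s)))["geom_solidity"])
  solM <- sapply(1:5, function(s)
    geometricDescriptor(noduleMask(makeMalignantPhantom(
      spikeAmplitude = 0.35, seed = s)))["geom_solidity"])
  expect_true(all(solB >= 0.95))
  expect_true(all(solM <= 0.90))
  for (s in 1:5) {
    m <- noduleMask(makeMalignantPhantom(seed = s))@data
    expect_equal(sum(m[c(1, 40), , ]) + sum(m[, c(1, 40), ]) +
                   sum(m[, , c(1, 40)]), 0)
  }
})

test_that("makeCohort respects counts, balance and determinism", {
  co <- makeCohort(6, 4, seed = 7)
  expect_length(co, 10)
  labs <- vapply(co, noduleLabel, "")
  expect_equal(sum(labs == "benign"), 6)
  expect_equal(sum(labs == "malignant"), 4)
  expect_length(makeCohort(0, 0), 0)
  co2 <- makeCohort(6, 4, seed = 7)
  expect_equal(noduleVOI(co[[3]])@data, noduleVOI(co2[[3]])@data)
  expect_equal(noduleVOI(co[[9]])@data, noduleVOI(co2[[9]])@data)
})

test_that("invalid phantom parameters are rejected", {
  expect_error(makeBenignPhantom(radiusMM = -1), "radiusMM")
  expect_error(makeMalignantPhantom(spikeCount = 2), "spikeCount")
  expect_error(makeMalignantPhantom(spikeAmplitude = 0), "spikeAmplitude")
})
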