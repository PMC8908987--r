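smallRecord <- function(data, maskData = NULL, spacing = c(1, 1, 1)) {
  if (is.null(maskData)) maskData <- array(1, dim(data))
  list(voi = VoxelVolume(data, spacing), mask = NoduleMask(maskData, spacing))
}

test_that("constant training volumes concentrate potential on equal levels", {
  cube <- smallRecord(array(-50, c(5, 5, 5)))
  model <- trainMGRF(list(cube), Q = 4)
  # all mass on one level; for every pairwise family the observed
  # configuration gets the positive centred potential and everything
  # else is (weakly negative) centred iid mass
  q <- noduleCAD:::quantizeVolume(cube$voi@data, model@range, 4L)
  lev <- q[1]
  for (P in model@pairPotentials) {
    expect_equal(P[lev, lev], 1 - 1, tolerance = 1e-12) # F_emp = F_iid = 1
    expect_true(all(P[-lev, ] == 0) && all(P[, -lev] == 0))
  }
  # hand-computable star table: every configuration is 6 matches
  expect_equal(model@starPotential[7], 0) # 1 - 1 after centring
  expect_equal(sum(abs(model@starPotential[1:6])), 0)
})

test_that("training is deterministic and Q = 1 collapses to zero potentials", {
  recs <- lapply(1:3, function(s) makeBenignPhantom(seed = 60 + s))
  m1 <- trainMGRF(recs, Q = 16)
  m2 <- trainMGRF(recs, Q = 16)
  expect_equal(m1@pairPotentials, m2@pairPotentials)
  expect_equal(m1@starPotential, m2@starPotential)
  expect_equal(m1@energyRange, m2@energyRange)
  m0 <- trainMGRF(recs, Q = 1)
  for (P in m0@pairPotentials) expect_equal(P[1, 1], 0)
  expect_equal(m0@starPotential[7], 0)
  expect_error(trainMGRF(list()), "at least one")
})

test_that("energy images are finite, masked and shape-checked", {
  recs <- lapply(1:3, function(s) makeBenignPhantom(seed = 70 + s))
  model <- trainMGRF(recs, Q = 16)
  r <- makeBenignPhantom(seed = 80)
  e <- gibbsEnergyImage(noduleVOI(r), noduleMask(r), model)
  expect_true(all(is.finite(e@data)))
  expect_true(all(e@data[noduleMask(r)@data == 0] == 0))
  # all-background mask -> all-zero energy image
  bg <- NoduleMask(array(c(1, rep(0, 39999)), c(40, 40, 40)))
  e0 <- gibbsEnergyImage(noduleVOI(r), bg, model)
  expect_true(all(e0@data[-1] == 0))
  wrong <- NoduleMask(array(1, c(10, 10, 10)))
  expect_error(gibbsEnergyImage(noduleVOI(r), wrong, model), "shapes differ")
})

test_that("the model learns structure: shuffled voxels get higher energy", {
  recs <- lapply(1:5, function(s) makeBenignPhantom(seed = 90 + s))
  model <- trainMGRF(recs, Q = 16)
  r <- recs[[1]]
  e <- gibbsEnergyImage(noduleVOI(r), noduleMask(r), model)
  inMask <- noduleMask(r)@data > 0
  shuffled <- noduleVOI(r)@data
  shuffled[inMask] <- noduleCAD:::withSeed(1, sample(shuffled[inMask]))
  eS <- gibbsEnergyImage(VoxelVolume(shuffled), noduleMask(r), model)
  expect_lt(mean(e@data[inMask]), mean(eS@data[inMask]))
})

test_that("energy histograms are normalized across the bin grid", {
  recs <- lapply(1:3, function(s) makeBenignPhantom(seed = 40 + s))
  model <- trainMGRF(recs, Q = 16)
  r <- makeMalignantPhantom(seed = 41)
  e <- gibbsEnergyImage(noduleVOI(r), noduleMask(r), model)
  for (nb in c(400, 600, 800, 1000)) {
    h <- energyHistogram(e, noduleMask(r), nb, range = model@energyRange)
    expect_length(h, nb)
    expect_equal(sum(h), 1)
  }
  expect_error(energyHistogram(e, noduleMask(r), 1,
                               range = model@energyRange), "nBins")
})

test_that("model JSON round-trip preserves potentials", {
  recs <- lapply(1:2, function(s) makeBenignPhantom(seed = 50 + s))
  model <- trainMGRF(recs, Q = 8)
  f <- tempfile(fileext = ".json")
  writeMGRFModel(model, f)
  m2 <- readMGRFModel(f)
  expect_equal(m2@Q, model@Q)
  expect_equal(m2@range, model@range)
  expect_equal(m2@offsets, model@offsets)
  expect_equal(m2@pairPotentials, model@pairPotentials, tolerance = 1e-12)
  expect_equal(m2@starPotential, model@starPotential, tolerance = 1e-12)
})
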