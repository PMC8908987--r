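test_that("partial derivatives recover analytic gradients", {
  d <- c(8, 9, 10)
  gx <- array(rep(seq_len(d[1]), times = prod(d[2:3])), d)
  gy <- aperm(array(rep(seq_len(d[2]), times = d[1] * d[3]),
                    c(d[2], d[1], d[3])), c(2, 1, 3))
  gz <- aperm(array(rep(seq_len(d[3]), times = d[1] * d[2]),
                    c(d[3], d[1], d[2])), c(2, 3, 1))
  pd <- partialDerivativeVolumes(gx + 2 * gy + 3 * gz)
  inner <- function(a) a[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)]
  expect_true(all(abs(inner(pd$x) - 1) < 1e-12))
  expect_true(all(abs(inner(pd$y) - 2) < 1e-12))
  expect_true(all(abs(inner(pd$z) - 3) < 1e-12))
  pd0 <- partialDerivativeVolumes(array(5, c(4, 4, 4)))
  expect_true(all(pd0$x == 0) && all(pd0$y == 0) && all(pd0$z == 0))
})

test_that("integral gradient volume equals brute-force triple sums", {
  # all-ones derivative: closed form (x)(y)(z) in 1-based indices
  ones <- array(1, c(3, 3, 3))
  iv <- integralGradientVolume(ones)
  for (x in 1:3) for (y in 1:3) for (z in 1:3)
    expect_equal(iv[x, y, z], x * y * z)
  # random volumes up to 8^3, exhaustive brute force
  set.seed(13)
  for (dd in list(c(1, 1, 1), c(2, 3, 4), c(8, 8, 8))) {
    a <- array(rnorm(prod(dd)), dd)
    iv <- integralGradientVolume(a)
    bf <- array(0, dd)
    for (x in seq_len(dd[1])) for (y in seq_len(dd[2]))
      for (z in seq_len(dd[3]))
        bf[x, y, z] <- sum(a[1:x, 1:y, 1:z])
    expect_equal(iv, bf, tolerance = 1e-9)
  }
})

test_that("eight-corner mean gradient matches the voxel-loop oracle", {
  set.seed(17)
  a <- array(rnorm(32^3), c(32, 32, 32))
  igv <- noduleCAD:::hogIntegralVolumes(a)
  pd <- partialDerivativeVolumes(a)
  for (t in 1:100) {
    base <- sample(1:28, 3, replace = TRUE)
    w <- sample(1:4, 3, replace = TRUE)
    mg <- meanGradient(igv, base, w[1], w[2], w[3])
    sel <- function(q) mean(q[base[1]:(base[1] + w[1] - 1),
                              base[2]:(base[2] + w[2] - 1),
                              base[3]:(base[3] + w[3] - 1)])
    bf <- c(sel(pd$x), sel(pd$y), sel(pd$z))
    expect_equal(mg, bf, tolerance = 1e-9)
  }
  expect_error(meanGradient(igv, c(31, 31, 31), 5, 5, 5), "out of bounds")
  # whole-volume query on a ramp
  ramp <- array(rep(1:16, times = 256), c(16, 16, 16))
  igr <- noduleCAD:::hogIntegralVolumes(ramp)
  expect_equal(meanGradient(igr, c(1, 1, 1), 16, 16, 16),
               c(mean(partialDerivativeVolumes(ramp)$x), 0, 0))
})

test_that("platonic direction sets have the catalogued sizes", {
  expect_equal(platonicDirections("tetrahedron")$nBins, 4)
  expect_equal(platonicDirections("octahedron")$nBins, 6)
  expect_equal(platonicDirections("cube")$nBins, 8)
  expect_equal(platonicDirections("icosahedron")$nBins, 12)
  expect_equal(platonicDirections("dodecahedron")$nBins, 20)
  expect_equal(platonicDirections("dodecahedron", "half")$nBins, 10)
  expect_equal(platonicDirections("icosahedron", "half")$nBins, 6)
  expect_error(platonicDirections("tetrahedron", "half"),
               "centrally symmetric")
  # all direction rows are unit norm
  V <- platonicDirections("dodecahedron")$directions
  expect_equal(sqrt(rowSums(V^2)), rep(1, 20))
  # adjacency threshold: tetrahedron pairs all at dot -1/3
  expect_equal(platonicDirections("tetrahedron")$threshold, -1 / 3)
})

test_that("votes obey the nearest-3-axes constraints", {
  bins <- platonicDirections("dodecahedron", "full")
  # along a bin direction: exactly one nonzero component with the full
  # gradient magnitude
  v <- vote(3.7 * bins$directions[11, ], bins)
  expect_equal(sum(v > 0), 1)
  expect_equal(max(v), 3.7)
  expect_equal(vote(c(0, 0, 0), bins), numeric(20))
  set.seed(23)
  for (t in 1:1000) {
    g <- rnorm(3)
    w <- vote(g, bins)
    expect_lte(sum(w > 0), 3)
    # vote magnitude preserves |N|
    expect_equal(sqrt(sum(w^2)), sqrt(sum(g^2)), tolerance = 1e-9)
  }
  # vectorized voting agrees with the scalar path
  G <- matrix(rnorm(300), 100, 3)
  VM <- noduleCAD:::voteMatrix(G, bins)
  for (i in seq_len(100))
    expect_equal(VM[i, ], vote(G[i, ], bins), tolerance = 1e-12)
})

test_that("half binning folds antipodal votes", {
  binsF <- platonicDirections("icosahedron", "full")
  binsH <- platonicDirections("icosahedron", "half")
  set.seed(3)
  g <- rnorm(3)
  wF <- vote(g, binsF); wH <- vote(g, binsH)
  folded <- numeric(binsH$nBins)
  for (b in seq_along(wF))
    folded[binsH$fold[b]] <- folded[binsH$fold[b]] + wF[b]
  expect_equal(wH, folded)
})

test_that("descriptor has composed length, unit blocks and invariances", {
  set.seed(29)
  # integer-valued volume: derivative and integral arithmetic is exact,
  # so the constant-offset invariance holds to the bit
  a <- array(sample(0:50, 40^3, replace = TRUE), c(40, 40, 40))
  d <- hog3dDescriptor(a)
  expect_length(d, 125 * 20)
  blocks <- matrix(d, nrow = 20)
  n2 <- sqrt(colSums(blocks^2))
  expect_true(all(abs(n2 - 1) < 1e-6 | n2 == 0))
  # gradient invariance to constant offsets
  expect_equal(hog3dDescriptor(a + 100), d)
  expect_error(hog3dDescriptor(a, nBlocks = 5, cellSize = 9),
               "cell larger than block")
})

test_that("axis permutation permutes the cube-solid descriptor", {
  set.seed(33)
  # integers keep both evaluation orders exact (see above)
  a <- array(sample(0:50, 27^3, replace = TRUE), c(27, 27, 27))
  bins <- platonicDirections("cube")
  d1 <- hog3dDescriptor(a, nBlocks = 3, cellSize = 3, solid = "cube")
  ap <- aperm(a, c(2, 1, 3)) # swap x and y
  d2 <- hog3dDescriptor(ap, nBlocks = 3, cellSize = 3, solid = "cube")
  # block (i,j,k) -> (j,i,k); cube directions map to themselves with
  # x/y swapped
  V <- bins$directions
  dirMap <- apply(V[, c(2, 1, 3)], 1, function(v)
    which(colSums(abs(t(V) - v)) < 1e-9))
  blockOf <- function(i) arrayInd(i, c(3, 3, 3))
  m1 <- matrix(d1, nrow = bins$nBins); m2 <- matrix(d2, nrow = bins$nBins)
  for (b in 1:27) {
    ijk <- blockOf(b)
    b2 <- ijk[2] + 3 * (ijk[1] - 1) + 9 * (ijk[3] - 1)
    expect_equal(m2[dirMap, b2], m1[, b], tolerance = 1e-9)
  }
})
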