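# Brute-force per-pixel LBP oracle, independent of the vectorized path.
bruteLBP <- function(m, N, R, px, py) {
  code <- 0
  for (i in seq_len(N)) {
    a <- 2 * pi * i / N
    x <- px - R * sin(a); y <- py + R * cos(a)
    x0 <- floor(x); y0 <- floor(y); fx <- x - x0; fy <- y - y0
    g <- m[x0, y0] * (1 - fx) * (1 - fy) + m[x0 + 1, y0] * fx * (1 - fy) +
      m[x0, y0 + 1] * (1 - fx) * fy + m[x0 + 1, y0 + 1] * fx * fy
    code <- code + 2^(i - 1) * (g - m[px, py] >= 0)
  }
  code
}

test_that("traditional LBP codes match direct enumeration on a ramp", {
  m <- outer(1:9, 1:9, function(i, j) 2 * i + 0.5 * j)
  codes <- noduleCAD:::lbpCodeMatrix(m, 8, 1)
  for (px in 3:7) for (py in 3:7)
    expect_equal(codes[px, py], bruteLBP(m, 8, 1, px, py))
  # constant view: every code is 2^N - 1 (f(0) = 1)
  h <- traditionalLBP(matrix(7, 9, 9), 8, 1)
  expect_equal(h[256], 1)
  expect_equal(sum(h), 1)
})

test_that("neighbour i = N sits at (0, R) from the centre", {
  # a view where only the pixel directly 'above' (y + R) differs
  m <- matrix(0, 9, 9)
  m[5, 5] <- 1  # centre above the background
  m[5, 7] <- 10 # (x = 5, y = 5 + R) with R = 2
  codes <- noduleCAD:::lbpCodeMatrix(m, 4, 2)
  # only neighbour i = N = 4 (angle 2 pi), at offset (0, R), exceeds the
  # centre, so exactly bit 4 fires
  expect_equal(codes[5, 5], 2^3)
})

test_that("resampleLevel sample counts follow the scheme", {
  m <- matrix(rnorm(441), 21, 21)
  expect_length(resampleLevel(m, c(11, 11), 3, "full_n")$values, 24)
  expect_length(resampleLevel(m, c(11, 11), 5, "single_n")$values, 8)
  avg <- resampleLevel(m, c(11, 11), 2, "average_n")$values
  expect_length(avg, 8)
  # average_n equals full_n followed by arc averaging, exactly
  full <- resampleLevel(m, c(11, 11), 2, "full_n")$values
  expect_equal(avg, colMeans(matrix(full, nrow = 2)))
  expect_error(resampleLevel(m, c(2, 2), 5), "leaves the view")
})

test_that("levelStats reduces samples to the five exact statistics", {
  s <- levelStats(1:8)
  expect_equal(unname(s), c(4.5, 4.5, sqrt(mean((1:8 - 4.5)^2)), 1, 8))
  expect_equal(s[["sd"]], 2.2913, tolerance = 1e-4)
  expect_equal(unname(levelStats(rep(3, 5))), c(3, 3, 0, 3, 3))
  expect_equal(unname(levelStats(42)), c(42, 42, 0, 42, 42))
})

test_that("albpCodes: constant views, code range and brute-force oracle", {
  cm <- albpCodes(matrix(5, 15, 15), RMax = 3)
  for (s in names(cm$maps)) {
    v <- cm$maps[[s]][!is.na(cm$maps[[s]])]
    expect_true(all(v == 7)) # all statistics equal their mu, f(0) = 1
  }
  set.seed(31)
  m <- matrix(rnorm(625, sd = 10), 25, 25)
  cm <- albpCodes(m, RMax = 3, scheme = "average_n")
  codes <- cm$maps$mean[!is.na(cm$maps$mean)]
  expect_true(all(codes >= 0 & codes <= 7))
  # straight-line oracle for the mean map at a few pixels
  for (px in c(5, 12, 20)) for (py in c(6, 13, 19)) {
    means <- sapply(1:3, function(R)
      mean(resampleLevel(m, c(px, py), R, "average_n")$values))
    mu <- mean(means)
    expect_equal(cm$maps$mean[px, py],
                 sum(2^(0:2) * (means - mu >= 0)))
  }
})

test_that("ALBP codes are invariant to gray-level shifts", {
  set.seed(8)
  m <- matrix(rnorm(400), 20, 20)
  c1 <- albpCodes(m, 3)
  c2 <- albpCodes(m + 123.4, 3)
  expect_identical(c1$maps, c2$maps)
})

test_that("multiview descriptor has the composed length and unit sums", {
  r <- makeBenignPhantom(seed = 21)
  d <- multiviewALBP(noduleVOI(r), noduleMask(r), nViews = 5, RMax = 3)
  expect_length(d, 5 * 5 * 2^3)
  # each per-view-per-statistic histogram sums to 1 (or 0 if empty)
  blocks <- split(d, rep(seq_len(25), each = 8))
  for (b in blocks) expect_true(abs(sum(b) - 1) < 1e-9 || sum(b) == 0)
  # constant-intensity nodule: every histogram is a point mass at 2^R - 1
  rc <- makeBenignPhantom(textureSigmaHU = 0, seed = 3)
  dc <- multiviewALBP(noduleVOI(rc), noduleMask(rc))
  m <- matrix(dc, nrow = 8)
  expect_true(all(m[8, ] == 1))
})

test_that("ALBP resists additive noise better than traditional LBP", {
  shifts <- sapply(1:20, function(s) {
    r <- makeBenignPhantom(seed = 500 + s)
    voi <- noduleVOI(r); msk <- noduleMask(r)
    rng <- diff(range(voi@data))
    noisy <- VoxelVolume(
      voi@data + noduleCAD:::withSeed(s, rnorm(length(voi@data),
                                               sd = 0.01 * rng)),
      voi@spacing)
    a0 <- multiviewALBP(voi, msk); a1 <- multiviewALBP(noisy, msk)
    mi <- grep("_mean_", names(a0))
    l0 <- multiviewLBP(voi, msk); l1 <- multiviewLBP(noisy, msk)
    c(albp = sum(abs(a0[mi] - a1[mi])), lbp = sum(abs(l0 - l1)))
  })
  expect_lt(mean(shifts["albp", ]), mean(shifts["lbp", ]))
})
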