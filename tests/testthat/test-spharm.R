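test_that("mask meshing yields a watertight genus-0 surface with the right area", {
  ball <- digitalBall(10, 40)
  mesh <- meshFromMask(ball)
  expect_equal(meshEuler(mesh), 2)
  expect_lt(abs(meshArea(mesh) - 4 * pi * 100) / (4 * pi * 100), 0.05)
  expect_error(meshFromMask(NoduleMask(array(c(1, rep(0, 7)), c(2, 2, 2)))),
               NA) # single voxel still meshes
  # two components: largest kept with a warning
  two <- array(0, c(30, 30, 30))
  ax <- (1:30) - 15.5
  d2 <- outer(ax^2, outer(ax^2, ax^2, `+`), `+`)
  two[d2 <= 36] <- 1
  two[2:4, 2:4, 2:4] <- 1
  expect_warning(m2 <- meshFromMask(NoduleMask(two)), "components")
  expect_equal(meshEuler(m2), 2)
})

test_that("real SH basis is orthonormal in quadrature", {
  # dense uniform grid on the sphere: discrete inner products approximate
  # the continuous orthonormality relations
  n <- 6000
  set.seed(1)
  z <- runif(n, -1, 1); ph <- runif(n, -pi, pi)
  Y <- noduleCAD:::cpp_sh_basis(z, ph, 6L)
  G <- crossprod(Y) / n * (4 * pi)
  expect_equal(diag(G), rep(1, 49), tolerance = 0.15)
  offdiag <- G - diag(diag(G))
  expect_lt(max(abs(offdiag)), 0.12)
})

test_that("a symmetric unit-sphere triangulation is a fixed point", {
  ico <- icosahedronMesh()
  par <- attractionRepulsionMap(ico, iters = 100)
  expect_lt(max(abs(par$xyz - ico@vertices)), 1e-6)
  expect_equal(sqrt(rowSums(par$xyz^2)), rep(1, 12), tolerance = 1e-12)
})

test_that("unit-sphere mesh reconstructs almost exactly by order 2", {
  sph <- icosphereMesh(4)
  par <- attractionRepulsionMap(sph)
  expect_equal(sqrt(rowSums(par$xyz^2)), rep(1, nrow(sph@vertices)),
               tolerance = 1e-12)
  fit <- shFit(sph, par, maxOrder = 4)
  expect_lt(fit@errorCurve[["2"]], 0.01)
  expect_lt(fit@errorCurve[["1"]], 0.01) # sphere coords are pure order 1
  # order 0 of a centred mesh collapses to the centroid: normalized RMS
  # radius
  rms <- sqrt(mean(rowSums(sph@vertices^2)))
  expect_equal(fit@errorCurve[["0"]],
               rms / mean(sqrt(rowSums(sph@vertices^2))), tolerance = 1e-6)
})

test_that("relaxation evens neighbour distances on a spiculated mesh", {
  m <- makeMalignantPhantom(seed = 52)
  mesh <- meshFromMask(noduleMask(m))
  cv <- function(xyz) {
    F <- mesh@faces
    ed <- unique(rbind(F[, 1:2], F[, 2:3], F[, c(1, 3)]))
    dd <- sqrt(rowSums((xyz[ed[, 1], ] - xyz[ed[, 2], ])^2))
    sd(dd) / mean(dd)
  }
  p0 <- suppressWarnings(attractionRepulsionMap(mesh, iters = 0))
  p1 <- suppressWarnings(attractionRepulsionMap(mesh, iters = 100))
  expect_lt(cv(p1$xyz), cv(p0$xyz))
})

test_that("IRF coefficients agree with a full least-squares fit at low order", {
  b <- makeBenignPhantom(seed = 53)
  mesh <- meshFromMask(noduleMask(b))
  par <- suppressWarnings(attractionRepulsionMap(mesh))
  fit <- shFit(mesh, par, maxOrder = 3)
  # oracle: one joint least squares on the full order-0..3 design
  Y <- noduleCAD:::cpp_sh_basis(pmin(pmax(par$xyz[, 3], -1), 1), par$phi, 3L)
  X <- sweep(mesh@vertices, 2, colMeans(mesh@vertices))
  full <- qr.coef(qr(Y), X)
  recIRF <- Y %*% fit@coefficients
  recFull <- Y %*% full
  relDiff <- sqrt(mean((recIRF - recFull)^2)) /
    sqrt(mean(recFull^2))
  expect_lt(relDiff, 0.05)
})

test_that("error curves are monotone and translation invariant", {
  for (s in 55:57) {
    r <- if (s %% 2) makeBenignPhantom(seed = s) else
      makeMalignantPhantom(seed = s)
    d <- spharmDescriptor(noduleMask(r), maxOrder = 30)
    expect_true(all(diff(d) <= 1e-9))
  }
  # translate the mask: normalized curve unchanged (meshes are centred)
  m <- makeBenignPhantom(seed = 58)
  msk <- noduleMask(m)@data
  shifted <- array(0, dim(msk))
  shifted[4:40, 2:38, 3:39] <- msk[1:37, 3:39, 2:38]
  d1 <- spharmDescriptor(NoduleMask(msk), maxOrder = 12)
  d2 <- spharmDescriptor(NoduleMask(shifted), maxOrder = 12)
  expect_equal(d1, d2, tolerance = 1e-6)
})

test_that("spiculated shapes need higher orders than smooth shapes", {
  ords <- sapply(1:8, function(s) {
    ob <- orderToReachError(spharmDescriptor(
      noduleMask(makeBenignPhantom(seed = 700 + s)), maxOrder = 20))
    om <- orderToReachError(spharmDescriptor(
      noduleMask(makeMalignantPhantom(seed = 700 + s)), maxOrder = 20))
    c(ob, om)
  })
  expect_gt(median(ords[2, ]), median(ords[1, ]))
})

test_that("too few vertices caps the order with a warning", {
  tiny <- icosahedronMesh() # 12 vertices
  par <- attractionRepulsionMap(tiny, iters = 0)
  expect_warning(fit <- shFit(tiny, par, maxOrder = 10), "capping")
  expect_lt(fit@maxOrder, 10)
  d <- reconstructionErrorCurve(fit, maxOrder = 10)
  expect_length(d, 10)
})
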