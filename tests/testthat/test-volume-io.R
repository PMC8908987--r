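test_that("NIfTI round-trip preserves data, spacing and shape", {
  a <- array(rnorm(64^3), c(64, 64, 64))
  v <- VoxelVolume(a, spacing = c(1, 1, 1))
  f <- tempfile(fileext = ".nii.gz")
  writeVolume(v, f)
  v2 <- readVolume(f)
  expect_equal(dim(v2@data), c(64L, 64L, 64L))
  expect_equal(v2@spacing, c(1, 1, 1))
  expect_equal(v2@data, a, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("MetaImage round-trip preserves data and metadata", {
  a <- array(seq_len(4 * 5 * 6), c(4, 5, 6)) * 1.5
  v <- VoxelVolume(a, spacing = c(0.7, 0.7, 2.5), origin = c(-10, 5, 2))
  f <- tempfile(fileext = ".mhd")
  writeVolume(v, f)
  v2 <- readVolume(f)
  expect_equal(v2@data, a, ignore_attr = TRUE)
  expect_equal(v2@spacing, c(0.7, 0.7, 2.5))
  expect_equal(v2@origin, c(-10, 5, 2))
})

test_that("DICOM series reader recovers geometry and HU rescale", {
  dir <- tempfile()
  dir.create(dir)
  set.seed(42)
  nz <- 4
  slices <- lapply(seq_len(nz), function(k)
    matrix(sample(0:2000, 16 * 12, replace = TRUE), nrow = 16))
  for (k in seq_len(nz))
    writeDicomSlice(file.path(dir, sprintf("s%02d.dcm", k)), slices[[k]],
                    pixelSpacing = c(0.7, 0.6), thickness = 2.5,
                    position = c(0, 0, (k - 1) * 2.5))
  v <- readVolume(dir, format = "dicom_dir")
  expect_equal(dim(v@data), c(16L, 12L, 4L))
  # PixelSpacing is (row, column); axis 1 is columns
  expect_equal(v@spacing, c(0.6, 0.7, 2.5))
  expect_equal(v@data[, , 2], slices[[2]] - 1024, ignore_attr = TRUE)
  expect_error(readVolume(tempfile(), format = "dicom_dir"), "not found")
  empt <- tempfile(); dir.create(empt)
  expect_error(readVolume(empt, format = "dicom_dir"), "empty")
})

test_that("extractVOI produces the standard cube and pads out of bounds", {
  a <- array(rnorm(128^3), c(128, 128, 128))
  v <- VoxelVolume(a, spacing = c(1, 1, 1))
  ctr <- c(63.5, 63.5, 63.5) # physical centre of the grid
  voi <- extractVOI(v, ctr, sideMM = 40)
  expect_equal(dim(voi@data), c(40L, 40L, 40L))
  corner <- extractVOI(v, c(0, 0, 0), sideMM = 40, fill = -1000)
  expect_equal(dim(corner@data), c(40L, 40L, 40L))
  expect_true(any(corner@data == -1000))
  expect_error(extractVOI(v, ctr, sideMM = 0), "sideMM")
})

test_that("extractVOI is translation-consistent", {
  set.seed(7)
  a <- array(rnorm(48^3), c(48, 48, 48))
  v1 <- VoxelVolume(a, origin = c(0, 0, 0))
  v2 <- VoxelVolume(a, origin = c(13, -4, 2.5)) # same data, shifted frame
  voi1 <- extractVOI(v1, c(20, 22, 25), sideMM = 20)
  voi2 <- extractVOI(v2, c(20, 22, 25) + c(13, -4, 2.5), sideMM = 20)
  expect_equal(voi1@data, voi2@data)
})

test_that("resampleIsotropic hits the expected shape and preserves extent", {
  a <- array(rnorm(64 * 64 * 20), c(64, 64, 20))
  v <- VoxelVolume(a, spacing = c(0.7, 0.7, 2.5))
  iso <- resampleIsotropic(v, 1.0)
  expect_equal(dim(iso@data), c(45L, 45L, 50L)) # round(extent / target)
  expect_equal(iso@spacing, c(1, 1, 1))
  # identity when already isotropic at the target
  vi <- VoxelVolume(array(rnorm(20^3), c(20, 20, 20)))
  expect_equal(resampleIsotropic(vi, 1)@data, vi@data, tolerance = 1e-12)
  # constants are preserved exactly, in both directions
  vc <- VoxelVolume(array(3.5, c(10, 12, 8)), spacing = c(0.9, 1.1, 2))
  iso2 <- resampleIsotropic(vc, 1)
  expect_true(all(iso2@data == 3.5))
  back <- resampleIsotropic(iso2, 0.9) # any spacing: still constant
  expect_true(all(back@data == 3.5))
})

test_that("extractViews geometry follows the k*180/V pencil", {
  a <- array(rnorm(20^3), c(20, 20, 20))
  v <- VoxelVolume(a)
  one <- extractViews(v, 1)
  expect_length(one, 1)
  # single view at angle 0: normal is +y (the x-z plane)
  expect_equal(one[[1]]@planeNormal, c(0, 1, 0))
  five <- extractViews(v, 5)
  angles <- sapply(five, function(s) {
    n <- s@planeNormal
    (atan2(-n[1], n[2]) * 180 / pi) %% 180
  })
  expect_equal(angles, c(0, 36, 72, 108, 144), tolerance = 1e-8)
  expect_error(extractViews(v, 0), "nViews")
})

test_that("views of a z-rotationally-symmetric volume are identical", {
  ax <- (1:30) - 15.5
  r2 <- outer(ax^2, ax^2, `+`)
  a <- array(0, c(30, 30, 30))
  for (z in 1:30) a[, , z] <- exp(-r2 / 40) * exp(-(z - 15.5)^2 / 30)
  v <- VoxelVolume(a)
  views <- extractViews(v, 4, center = c(15.5, 15.5, 15.5))
  px <- lapply(views, function(s) s@pixels)
  for (k in 2:4)
    expect_equal(px[[k]], px[[1]], tolerance = 0.02)
})

test_that("mask views are binary and centred on the centroid", {
  m <- digitalBall(8, 40)
  views <- extractViews(m, 3)
  for (v in views) {
    expect_true(all(v@pixels %in% c(0, 1)))
    expect_gt(sum(v@pixels), 0)
  }
})
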