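#' Read a CT volume or mask from disk
#'
#' Supports NIfTI (`.nii`/`.nii.gz`, via RNifti), MetaImage
#' (`.mhd`/`.mha`) and directories holding an uncompressed single-frame
#' DICOM series (explicit VR little endian). Spacing and origin are taken
#' from the file metadata; volumes are treated as axis-aligned (direction
#' cosines are not interpreted).
#'
#' @param path file (NIfTI, MetaImage) or directory (DICOM series).
#' @param format one of `"auto"`, `"nifti"`, `"metaimage"`, `"dicom_dir"`.
#' @param mask logical; if `TRUE` return a [NoduleMask-class] (values are
#'   thresholded at 0.5).
#' @return A [VoxelVolume-class] (or [NoduleMask-class]).
#' @export
readVolume <- function(path, format = c("auto", "nifti", "metaimage", "dicom_dir"),
                       mask = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "dicom_dir"
      else if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
      else if (grepl("\\.(mhd|mha)$", path)) "metaimage"
      else stop("cannot infer format of ", path, call. = FALSE)
  }
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  v <- switch(format,
    nifti = readNiftiVolume(path),
    metaimage = readMetaImage(path),
    dicom_dir = readDicomSeries(path))
  if (mask) NoduleMask(1 * (v@data >= 0.5), v@spacing, v@origin) else v
}

readNiftiVolume <- function(path) {
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim(img))
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
  if (length(dim(a)) > 3L) a <- a[, , , 1, drop = TRUE]
  pd <- attr(img, "pixdim") %||% RNifti::pixdim(img)
  sp <- abs(as.numeric(pd[seq_len(3)]))
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("NIfTI file lacks usable spacing metadata", call. = FALSE)
  xf <- try(RNifti::xform(img), silent = TRUE)
  org <- if (inherits(xf, "try-error")) c(0, 0, 0) else as.numeric(xf[1:3, 4])
  VoxelVolume(a, sp, org)
}

#' Write a volume to NIfTI or MetaImage
#'
#' @param volume a [VoxelVolume-class].
#' @param path output path; extension selects the format (`.nii`,
#'   `.nii.gz`, `.mhd`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(volume, path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(volume@data)
    RNifti::pixdim(img) <- volume@spacing
    xf <- diag(c(volume@spacing, 1))
    xf[1:3, 4] <- volume@origin
    RNifti::sform(img) <- structure(xf, code = 2L)
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.mhd$", path)) {
    writeMetaImage(volume, path)
  } else stop("unsupported output format: ", path, call. = FALSE)
  invisible(path)
}

# --- MetaImage ---------------------------------------------------------

metTypes <- c(MET_UCHAR = "integer", MET_CHAR = "integer",
              MET_SHORT = "integer", MET_USHORT = "integer",
              MET_INT = "integer", MET_UINT = "integer",
              MET_FLOAT = "double", MET_DOUBLE = "double")
metSizes <- c(MET_UCHAR = 1L, MET_CHAR = 1L, MET_SHORT = 2L, MET_USHORT = 2L,
              MET_INT = 4L, MET_UINT = 4L, MET_FLOAT = 4L, MET_DOUBLE = 8L)

readMetaImage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list(); dataAt <- NULL
  repeat {
    ln <- readLines(con, n = 1L, warn = FALSE)
    if (!length(ln)) stop("MetaImage header has no ElementDataFile", call. = FALSE)
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed MetaImage header line: ", ln, call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") { dataAt <- val; break }
  }
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  if (length(dims) != 3L) stop("only 3D MetaImage supported", call. = FALSE)
  sp <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else
      stop("MetaImage header lacks ElementSpacing", call. = FALSE)
  org <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  type <- hdr$ElementType %||% "MET_FLOAT"
  if (!type %in% names(metTypes))
    stop("unsupported MetaImage ElementType: ", type, call. = FALSE)
  endian <- if (identical(hdr$ElementByteOrderMSB, "True") ||
                identical(hdr$BinaryDataByteOrderMSB, "True")) "big" else "little"
  n <- prod(dims)
  signed <- !type %in% c("MET_UCHAR", "MET_USHORT", "MET_UINT")
  if (identical(dataAt, "LOCAL")) {
    raw <- readBin(con, metTypes[[type]], n = n, size = metSizes[[type]],
                   signed = signed, endian = endian)
  } else {
    rawPath <- file.path(dirname(path), dataAt)
    con2 <- file(rawPath, "rb"); on.exit(close(con2), add = TRUE)
    raw <- readBin(con2, metTypes[[type]], n = n, size = metSizes[[type]],
                   signed = signed, endian = endian)
  }
  if (length(raw) < n) stop("MetaImage data shorter than DimSize", call. = FALSE)
  VoxelVolume(array(as.double(raw), dims), sp, org)
}

writeMetaImage <- function(volume, path) {
  rawName <- sub("\\.mhd$", ".raw", basename(path))
  d <- dim(volume@data)
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(d, collapse = " ")),
           paste("ElementSpacing =", paste(volume@spacing, collapse = " ")),
           paste("Offset =", paste(volume@origin, collapse = " ")),
           "ElementType = MET_DOUBLE",
           paste("ElementDataFile =", rawName))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), rawName), "wb")
  on.exit(close(con))
  writeBin(as.double(volume@data), con, size = 8, endian = "little")
  invisible(path)
}

# --- minimal DICOM series reader --------------------------------------
# Uncompressed, explicit VR little endian, single-frame slices. Enough
# for axial CT series; anything fancier should be converted to NIfTI.

readDicomSeries <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files)) stop("empty DICOM directory: ", dir, call. = FALSE)
  slices <- lapply(files, readDicomSlice)
  rows <- unique(vapply(slices, function(s) s$rows, 1L))
  cols <- unique(vapply(slices, function(s) s$cols, 1L))
  if (length(rows) != 1L || length(cols) != 1L)
    stop("DICOM slices disagree on matrix size", call. = FALSE)
  zpos <- vapply(slices, function(s) s$ipp[3] %||% NA_real_, 1)
  ord <- if (all(is.finite(zpos))) order(zpos) else seq_along(slices)
  slices <- slices[ord]; zpos <- zpos[ord]
  nz <- length(slices)
  zsp <- if (nz > 1 && all(is.finite(zpos))) {
    dz <- diff(zpos)
    if (max(dz) - min(dz) > 1e-3)
      warning("non-uniform DICOM slice positions; using mean spacing")
    mean(dz)
  } else slices[[1]]$thickness
  if (!is.finite(zsp) || zsp <= 0)
    stop("cannot determine DICOM z spacing (no positions or thickness)",
         call. = FALSE)
  psp <- slices[[1]]$pixelSpacing
  if (is.null(psp)) stop("DICOM series lacks PixelSpacing", call. = FALSE)
  a <- array(0, c(cols, rows, nz))
  for (k in seq_len(nz))
    a[, , k] <- slices[[k]]$slope * slices[[k]]$pixels + slices[[k]]$intercept
  org <- slices[[1]]$ipp %||% c(0, 0, 0)
  # PixelSpacing is (row spacing, column spacing); axis 1 here is columns
  VoxelVolume(a, c(psp[2], psp[1], zsp), org)
}

readDicomSlice <- function(path) {
  buf <- readBin(path, "raw", n = file.size(path))
  if (length(buf) < 140 || rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path, call. = FALSE)
  pos <- 133L
  u16 <- function(p) as.integer(buf[p]) + 256L * as.integer(buf[p + 1L])
  u32 <- function(p) as.integer(buf[p]) + 256 * as.integer(buf[p + 1L]) +
    65536 * as.integer(buf[p + 2L]) + 16777216 * as.integer(buf[p + 3L])
  out <- list(slope = 1, intercept = 0, thickness = NA_real_,
              ipp = NULL, pixelSpacing = NULL, bits = 16L, signed = TRUE)
  long32 <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7 <= length(buf)) {
    grp <- u16(pos); ele <- u16(pos + 2L)
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (grepl("^[A-Z]{2}$", vr)) {
      if (vr %in% long32) { len <- u32(pos + 8L); hp <- 12L }
      else { len <- u16(pos + 6L); hp <- 8L }
    } else { # implicit VR fallback
      vr <- "UN"; len <- u32(pos + 4L); hp <- 8L
    }
    if (len < 0 || !is.finite(len)) stop("bad DICOM element length", call. = FALSE)
    valPos <- pos + hp
    val <- if (len > 0) buf[valPos:(valPos + len - 1L)] else raw(0)
    key <- sprintf("%04x,%04x", grp, ele)
    num <- function() as.numeric(strsplit(trimws(rawToChar(val)), "\\\\")[[1]])
    if (key == "0028,0010") out$rows <- u16(valPos)
    else if (key == "0028,0011") out$cols <- u16(valPos)
    else if (key == "0028,0100") out$bits <- u16(valPos)
    else if (key == "0028,0103") out$signed <- u16(valPos) == 1L
    else if (key == "0028,0030") out$pixelSpacing <- num()
    else if (key == "0018,0050") out$thickness <- num()[1]
    else if (key == "0020,0032") out$ipp <- num()
    else if (key == "0028,1052") out$intercept <- num()[1]
    else if (key == "0028,1053") out$slope <- num()[1]
    else if (key == "7fe0,0010") {
      px <- readBin(val, "integer", n = len / 2L, size = 2L,
                    signed = out$signed, endian = "little")
      out$pixels <- matrix(px, nrow = out$cols)
      return(out)
    }
    pos <- valPos + len
  }
  stop("DICOM file has no PixelData: ", path, call. = FALSE)
}

# --- VOI extraction and resampling ------------------------------------

#' Extract the standardized cubic volume of interest
#'
#' Cuts a cube of physical side `sideMM` (default 40 mm, the standard
#' nodule window) centred at a physical point, resampling trilinearly onto
#' a grid with the parent's spacing. Regions outside the parent volume are
#' padded with `fill` (default -1000 HU, air).
#'
#' @param volume a [VoxelVolume-class].
#' @param centerMM physical 3-point (same frame as the volume origin).
#' @param sideMM cube side, mm.
#' @param fill pad value for out-of-volume samples.
#' @return A [VoxelVolume-class] whose grid is centred on `centerMM`.
#' @export
extractVOI <- function(volume, centerMM, sideMM = 40, fill = -1000) {
  stopIfNot(sideMM > 0, "sideMM must be > 0")
  sp <- volume@spacing
  n <- pmax(1L, as.integer(round(sideMM / sp)))
  start <- centerMM - sideMM / 2
  coords <- lapply(1:3, function(ax)
    start[ax] + (seq_len(n[ax]) - 0.5) * sp[ax])
  g <- expand.grid(x = coords[[1]], y = coords[[2]], z = coords[[3]])
  ix <- (g$x - volume@origin[1]) / sp[1] + 1
  iy <- (g$y - volume@origin[2]) / sp[2] + 1
  iz <- (g$z - volume@origin[3]) / sp[3] + 1
  vals <- trilinearSample(volume@data, ix, iy, iz, fill = fill)
  VoxelVolume(array(vals, n), sp,
              origin = vapply(coords, `[`, 1, 1))
}

#' Resample a volume to isotropic voxels
#'
#' Trilinear resampling onto a grid of spacing `targetMM` in all three
#' directions; the physical extent is preserved to within one voxel per
#' axis.
#'
#' @param volume a [VoxelVolume-class] (or [NoduleMask-class], which is
#'   re-thresholded at 0.5 after interpolation).
#' @param targetMM target isotropic spacing, mm.
#' @return A resampled volume of the same class.
#' @export
resampleIsotropic <- function(volume, targetMM = 1.0) {
  stopIfNot(targetMM > 0, "targetMM must be > 0")
  sp <- volume@spacing
  d <- dim(volume@data)
  extent <- d * sp
  n <- pmax(1L, as.integer(round(extent / targetMM)))
  start <- volume@origin - sp / 2
  coords <- lapply(1:3, function(ax)
    start[ax] + (seq_len(n[ax]) - 0.5) * targetMM)
  g <- expand.grid(x = coords[[1]], y = coords[[2]], z = coords[[3]])
  ix <- pmin(pmax((g$x - volume@origin[1]) / sp[1] + 1, 1), d[1])
  iy <- pmin(pmax((g$y - volume@origin[2]) / sp[2] + 1, 1), d[2])
  iz <- pmin(pmax((g$z - volume@origin[3]) / sp[3] + 1, 1), d[3])
  vals <- trilinearSample(volume@data, ix, iy, iz, fill = 0)
  a <- array(vals, n)
  org <- vapply(coords, `[`, 1, 1)
  if (methods::is(volume, "NoduleMask"))
    NoduleMask(1 * (a >= 0.5), rep(targetMM, 3), org)
  else VoxelVolume(a, rep(targetMM, 3), org)
}

#' Extract equally distributed 2D views through the nodule
#'
#' Returns `nViews` planar cross-sections, each containing the given
#' centre and the scanner z axis; plane k (0-based) is rotated about z by
#' k * 180 / nViews degrees (antipodal planes coincide, hence 180 not
#' 360). Slices are resampled bilinearly at the smallest voxel spacing;
#' masks are re-thresholded at 0.5.
#'
#' @param x a [VoxelVolume-class] or [NoduleMask-class].
#' @param nViews number of views (>= 1).
#' @param center voxel 3-point (1-based, fractional allowed); defaults to
#'   the mask centroid for masks and the grid centre otherwise.
#' @param fill value for samples outside the grid (0 for masks, else the
#'   volume minimum).
#' @param sliceSpacing in-plane sampling step in mm; defaults to the
#'   smallest voxel spacing (finer steps oversample, which the contour
#'   descriptors use to work in sub-millimetre pixel units).
#' @return A list of [ViewSlice-class] objects.
#' @export
extractViews <- function(x, nViews, center = NULL, fill = NULL,
                         sliceSpacing = NULL) {
  stopIfNot(nViews >= 1, "nViews must be >= 1")
  isMask <- methods::is(x, "NoduleMask")
  if (is.null(center))
    center <- if (isMask) maskCentroid(x) else (dim(x@data) + 1) / 2
  if (is.null(fill)) fill <- if (isMask) 0 else min(x@data)
  d <- dim(x@data); sp <- x@spacing
  s <- sliceSpacing %||% min(sp)
  stopIfNot(s > 0, "sliceSpacing must be > 0")
  halfW <- ceiling(sqrt((d[1] * sp[1])^2 + (d[2] * sp[2])^2) / (2 * s))
  nU <- 2L * halfW + 1L
  nZ <- max(3L, ceiling(d[3] * sp[3] / s))
  cz <- (nZ + 1) / 2
  lapply(seq_len(nViews) - 1L, function(k) {
    a <- k * pi / nViews
    u <- c(cos(a), sin(a), 0)
    iu <- rep(seq_len(nU) - (halfW + 1L), times = nZ)
    jz <- rep(seq_len(nZ) - cz, each = nU)
    ix <- center[1] + (iu * s * u[1]) / sp[1]
    iy <- center[2] + (iu * s * u[2]) / sp[2]
    iz <- center[3] + (jz * s) / sp[3]
    vals <- trilinearSample(x@data, ix, iy, iz, fill = fill)
    m <- matrix(vals, nrow = nU)
    if (isMask) m <- 1 * (m >= 0.5)
    methods::new("ViewSlice", pixels = m,
                 planeNormal = c(-sin(a), cos(a), 0),
                 inPlaneSpacing = s, viewIndex = as.integer(k))
  })
}

#' Rotate a volume or mask about its centre
#'
#' Resamples the volume under a rigid rotation (inverse mapping with
#' trilinear interpolation). Used mostly to probe rotation invariance of
#' the shape descriptors.
#'
#' @param x a [VoxelVolume-class] or [NoduleMask-class].
#' @param rotation 3 x 3 rotation matrix.
#' @param center voxel 3-point to rotate about; defaults to the grid centre.
#' @param fill out-of-grid fill value (0 for masks, else volume minimum).
#' @return Rotated object of the same class.
#' @export
rotateVolume <- function(x, rotation, center = NULL, fill = NULL) {
  d <- dim(x@data)
  isMask <- methods::is(x, "NoduleMask")
  if (is.null(center)) center <- (d + 1) / 2
  if (is.null(fill)) fill <- if (isMask) 0 else min(x@data)
  g <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                             z = seq_len(d[3])))
  rel <- sweep(g, 2, center)
  src <- rel %*% rotation + rep(center, each = nrow(rel)) # inverse map: R^T
  vals <- trilinearSample(x@data, src[, 1], src[, 2], src[, 3], fill = fill)
  a <- array(vals, d)
  if (isMask) NoduleMask(1 * (a >= 0.5), x@spacing, x@origin)
  else VoxelVolume(a, x@spacing, x@origin)
}

#' Random 3D rotation matrix
#'
#' Uniform over SO(3) (via quaternion sampling), reproducible under the
#' caller's RNG state.
#'
#' @return A 3 x 3 rotation matrix.
#' @export
randomRotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Export a view slice as a PNG image for inspection
#'
#' @param view a [ViewSlice-class].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
writeSlicePNG <- function(view, path) {
  m <- view@pixels
  rng <- range(m)
  if (diff(rng) == 0) rng <- rng + c(0, 1)
  grDevices::png(path, width = ncol(m), height = nrow(m))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  graphics::image(t(m), col = grDevices::gray.colors(256), axes = FALSE,
                  useRaster = TRUE)
  graphics::par(op)
  grDevices::dev.off()
  invisible(path)
}
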