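# Programmatic fixtures shared across the suite.

# Digital ball: voxel centres within `radius` of the grid centre. With an
# even side the centre falls between voxels, which keeps the lattice
# statistics close to the continuous ball.
digitalBall <- function(radius = 10, side = 40, spacing = 1) {
  ctr <- (side + 1) / 2
  ax <- ((seq_len(side)) - ctr) * spacing
  d2 <- outer(ax^2, outer(ax^2, ax^2, `+`), `+`)
  NoduleMask(array(1 * (d2 <= radius^2), rep(side, 3)),
             spacing = rep(spacing, 3))
}

# Icosahedron and subdivided icospheres (exact unit-sphere meshes).
icosahedronMesh <- function() {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  methods::new("SurfaceMesh", vertices = V, faces = F)
}

icosphereMesh <- function(subdivisions = 3, radius = 1) {
  base <- icosahedronMesh()
  V <- base@vertices; F <- base@faces
  for (s in seq_len(subdivisions)) {
    mid <- new.env()
    getmid <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      if (!is.null(mid[[k]])) return(mid[[k]])
      p <- (V[a, ] + V[b, ]) / 2
      p <- p / sqrt(sum(p^2))
      V <<- rbind(V, p)
      mid[[k]] <- nrow(V)
      nrow(V)
    }
    nf <- matrix(0L, 4 * nrow(F), 3)
    for (r in seq_len(nrow(F))) {
      a <- F[r, 1]; b <- F[r, 2]; c <- F[r, 3]
      ab <- getmid(a, b); bc <- getmid(b, c); ca <- getmid(c, a)
      nf[(4 * r - 3):(4 * r), ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c, ca, bc), c(ab, bc, ca))
    }
    F <- nf
  }
  methods::new("SurfaceMesh", vertices = V * radius, faces = F)
}

# Analytic closed contours sampled at uniform parameter steps.
circleContour <- function(R = 30, n = 720) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(R * cos(th), R * sin(th))
}

starContour <- function(R = 100, lobes = 8, amp = 0.3, n = 1200) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- R * (1 + amp * sin(lobes * th))
  cbind(r * cos(th), r * sin(th))
}

# Euler characteristic V - E + F of a triangle mesh.
meshEuler <- function(mesh) {
  F <- mesh@faces
  ed <- rbind(F[, 1:2], F[, 2:3], F[, c(1, 3)])
  ed <- unique(t(apply(ed, 1, sort)))
  nrow(mesh@vertices) - nrow(ed) + nrow(F)
}

# Minimal explicit-VR little-endian part-10 DICOM writer for fixtures.
writeDicomSlice <- function(path, pixels, pixelSpacing = c(0.7, 0.7),
                            thickness = 2.5, position = c(0, 0, 0),
                            slope = 1, intercept = -1024) {
  u16raw <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                 endian = "little")
  u32raw <- function(x) writeBin(as.integer(x), raw(), size = 4,
                                 endian = "little")
  elemShort <- function(grp, ele, vr, value) {
    if (length(value) %% 2 == 1 && is.raw(value)) value <- c(value, as.raw(0))
    c(u16raw(grp), u16raw(ele), charToRaw(vr), u16raw(length(value)), value)
  }
  elemLong <- function(grp, ele, vr, value) {
    c(u16raw(grp), u16raw(ele), charToRaw(vr), as.raw(c(0, 0)),
      u32raw(length(value)), value)
  }
  ds <- function(v) {
    s <- paste(format(v, trim = TRUE), collapse = "\\")
    if (nchar(s) %% 2 == 1) s <- paste0(s, " ")
    charToRaw(s)
  }
  ui <- function(s) {
    r <- charToRaw(s)
    if (length(r) %% 2 == 1) r <- c(r, as.raw(0))
    r
  }
  meta <- elemShort(0x0002, 0x0010, "UI", ui("1.2.840.10008.1.2.1"))
  metaLen <- elemShort(0x0002, 0x0000, "UL", u32raw(length(meta)))
  # pixels is cols x rows in our convention; column-major order matches
  # the reader's reconstruction
  px <- writeBin(as.integer(as.vector(pixels)), raw(), size = 2,
                 endian = "little")
  body <- c(
    elemShort(0x0018, 0x0050, "DS", ds(thickness)),
    elemShort(0x0020, 0x0032, "DS", ds(position)),
    elemShort(0x0028, 0x0010, "US", u16raw(ncol(pixels))), # rows
    elemShort(0x0028, 0x0011, "US", u16raw(nrow(pixels))), # cols
    elemShort(0x0028, 0x0030, "DS", ds(pixelSpacing)),
    elemShort(0x0028, 0x0100, "US", u16raw(16)),
    elemShort(0x0028, 0x0103, "US", u16raw(1)),
    elemShort(0x0028, 0x1052, "DS", ds(intercept)),
    elemShort(0x0028, 0x1053, "DS", ds(slope)),
    elemLong(0x7fe0, 0x0010, "OW", px))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(metaLen, meta, body), con)
  invisible(path)
}
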