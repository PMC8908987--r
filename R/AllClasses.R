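#' @title Core data classes
#'
#' @description S4 containers used throughout the package: scalar CT
#'   volumes, binary nodule masks, 2D view slices, labelled phantom
#'   records, surface meshes, trained texture models and evaluation
#'   reports.
#'
#' @name noduleCAD-classes
#' @keywords internal
NULL

#' VoxelVolume: a 3D scalar grid with physical metadata
#'
#' Holds a 3D array of Hounsfield-unit (or other scalar) values together
#' with the per-axis voxel spacing in millimetres and the physical
#' coordinate of voxel (1,1,1). Volumes are assumed axis-aligned: the
#' physical position of voxel (i,j,k) is `origin + (c(i,j,k) - 1) * spacing`.
#'
#' @slot data 3D numeric array.
#' @slot spacing numeric(3), mm per voxel along each axis; all > 0.
#' @slot origin numeric(3), physical coordinate of the first voxel.
#' @export
setClass("VoxelVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  prototype(data = array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
            origin = c(0, 0, 0)))

setValidity("VoxelVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite numbers")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite numbers")
  if (any(!is.finite(object@data)))
    msg <- c(msg, "volume data must be finite everywhere")
  if (length(msg)) msg else TRUE
})

#' NoduleMask: a binary segmentation aligned to a VoxelVolume grid
#'
#' Same geometry slots as [VoxelVolume-class]; `data` holds 0/1 values and
#' at least one voxel must be foreground.
#'
#' @export
setClass("NoduleMask", contains = "VoxelVolume")

setValidity("NoduleMask", function(object) {
  d <- object@data
  if (!all(d %in% c(0, 1)))
    return("mask data must be 0/1")
  if (sum(d) < 1)
    return("mask must contain at least one foreground voxel")
  TRUE
})

#' ViewSlice: a 2D cross-section of a volume
#'
#' A planar resampling of a 3D volume on one of a pencil of equally
#' distributed planes through the nodule centroid. All planes contain the
#' scanner z axis direction; plane k (0-based) is rotated about z by
#' k * 180 / V degrees.
#'
#' @slot pixels 2D numeric matrix sampled on the plane.
#' @slot planeNormal unit 3-vector normal to the plane.
#' @slot inPlaneSpacing sampling step on the plane, mm.
#' @slot viewIndex integer view id, 0-based.
#' @export
setClass("ViewSlice",
  representation(pixels = "matrix", planeNormal = "numeric",
                 inPlaneSpacing = "numeric", viewIndex = "integer"),
  prototype(pixels = matrix(0, 1, 1), planeNormal = c(0, 1, 0),
            inPlaneSpacing = 1, viewIndex = 0L))

setValidity("ViewSlice", function(object) {
  if (abs(sqrt(sum(object@planeNormal^2)) - 1) > 1e-8)
    return("planeNormal must be a unit vector")
  if (object@inPlaneSpacing <= 0)
    return("inPlaneSpacing must be > 0")
  TRUE
})

#' NoduleRecord: the unit flowing through the pipeline
#'
#' Bundles a VOI, its mask, a class label and the generator parameters
#' (provenance, including the seed) for one nodule.
#'
#' @slot voi [VoxelVolume-class].
#' @slot mask [NoduleMask-class] on the same grid.
#' @slot label `"benign"` or `"malignant"`.
#' @slot params named list of generator parameters (may be empty for
#'   nodules read from files).
#' @export
setClass("NoduleRecord",
  representation(voi = "VoxelVolume", mask = "NoduleMask",
                 label = "character", params = "list"))

setValidity("NoduleRecord", function(object) {
  if (!identical(dim(object@voi@data), dim(object@mask@data)))
    return("voi and mask must share the same grid")
  if (!object@label %in% c("benign", "malignant"))
    return("label must be 'benign' or 'malignant'")
  TRUE
})

#' SurfaceMesh: a triangulated surface
#'
#' @slot vertices n x 3 numeric matrix, physical coordinates (mm).
#' @slot faces m x 3 integer matrix of 1-based vertex indices.
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix"))

setValidity("SurfaceMesh", function(object) {
  if (ncol(object@vertices) != 3L) return("vertices must be n x 3")
  if (ncol(object@faces) != 3L) return("faces must be m x 3")
  f <- object@faces
  if (nrow(f) && (min(f) < 1 || max(f) > nrow(object@vertices)))
    return("face indices out of range")
  TRUE
})

#' MGRFModel: a trained translation-invariant Markov-Gibbs random field
#'
#' Pairwise clique families over a quantized signal plus one 7-voxel star
#' family (centre and its 6 face neighbours). Potentials are the centred
#' empirical frequencies (analytic approximation of the maximum-likelihood
#' estimate); the partition function is never computed because only Gibbs
#' energies are used.
#'
#' @slot Q integer, number of quantization levels.
#' @slot range numeric(2), HU range mapped onto the Q levels.
#' @slot offsets list of integer 3-vectors, one pairwise clique family per
#'   offset (the negated offset belongs to the same family).
#' @slot pairPotentials list of Q x Q matrices, one per offset family.
#' @slot starPotential numeric(7), potential of the star-clique
#'   configuration "number of face neighbours at the centre's level" (0..6).
#' @slot energyRange numeric(2), reference range of in-mask energies on the
#'   training set (0.5 and 99.5 percentiles), used to bin energy histograms.
#' @export
setClass("MGRFModel",
  representation(Q = "integer", range = "numeric", offsets = "list",
                 pairPotentials = "list", starPotential = "numeric",
                 energyRange = "numeric"))

#' SHFit: spherical-harmonic coefficients and reconstruction errors
#'
#' @slot maxOrder highest fitted SH order L.
#' @slot coefficients (L+1)^2 x 3 matrix; row blocks are orders 0..L, the
#'   columns are the three coordinate functions x, y, z on the sphere.
#' @slot errorCurve numeric(L+1), normalized RMS reconstruction error after
#'   including orders 0..l (named by order).
#' @slot meanRadius mean vertex distance to the centroid (mm), the error
#'   normalizer.
#' @export
setClass("SHFit",
  representation(maxOrder = "integer", coefficients = "matrix",
                 errorCurve = "numeric", meanRadius = "numeric"))

#' EvalReport: binary classification metrics
#'
#' @slot confusion named numeric(4): TP, FP, TN, FN at the decision
#'   threshold (malignant is the positive class).
#' @slot accuracy,sensitivity,specificity,precision percentages.
#' @slot auc area under the ROC curve in `[0, 1]`.
#' @export
setClass("EvalReport",
  representation(confusion = "numeric", accuracy = "numeric",
                 sensitivity = "numeric", specificity = "numeric",
                 precision = "numeric", auc = "numeric"))
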