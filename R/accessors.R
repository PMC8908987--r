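#' Accessors for the core classes
#'
#' `voxelData()` returns the raw array, `voxelSpacing()` the per-axis mm
#' spacing, `voxelOrigin()` the physical coordinate of the first voxel and
#' `maskCentroid()` the foreground centre of mass in voxel coordinates
#' (1-based, fractional).
#'
#' @param x a [VoxelVolume-class] or [NoduleMask-class].
#' @return See individual descriptions.
#' @name accessors
#' @examples
#' v <- VoxelVolume(array(0, c(4, 4, 4)))
#' voxelSpacing(v)
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname accessors
#' @export
setMethod("voxelData", "VoxelVolume", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname accessors
#' @export
setMethod("voxelSpacing", "VoxelVolume", function(x) x@spacing)

#' @rdname accessors
#' @export
setGeneric("voxelOrigin", function(x) standardGeneric("voxelOrigin"))

#' @rdname accessors
#' @export
setMethod("voxelOrigin", "VoxelVolume", function(x) x@origin)

#' @rdname accessors
#' @export
setGeneric("maskCentroid", function(x) standardGeneric("maskCentroid"))

#' @rdname accessors
#' @export
setMethod("maskCentroid", "NoduleMask", function(x) {
  idx <- which(x@data > 0, arr.ind = TRUE)
  colMeans(idx)
})

#' Construct a VoxelVolume
#'
#' @param data 3D numeric array.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param origin numeric(3) physical coordinate of voxel (1,1,1).
#' @return A [VoxelVolume-class].
#' @export
VoxelVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  methods::new("VoxelVolume", data = data, spacing = as.numeric(spacing),
               origin = as.numeric(origin))
}

#' Construct a NoduleMask
#'
#' @param data 3D array of 0/1 (logical is coerced).
#' @inheritParams VoxelVolume
#' @return A [NoduleMask-class].
#' @export
NoduleMask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  storage.mode(data) <- "double"
  methods::new("NoduleMask", data = data, spacing = as.numeric(spacing),
               origin = as.numeric(origin))
}

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s %d x %d x %d, spacing %.3g x %.3g x %.3g mm\n",
              class(object), d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  value range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
  if (methods::is(object, "NoduleMask"))
    cat(sprintf("  foreground voxels: %d\n", sum(object@data > 0)))
})

setMethod("show", "NoduleRecord", function(object) {
  cat(sprintf("NoduleRecord (%s)\n", object@label))
  show(object@voi)
  cat(sprintf("  mask foreground: %d voxels\n", sum(object@mask@data > 0)))
})

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d faces\n",
              nrow(object@vertices), nrow(object@faces)))
})

setMethod("show", "MGRFModel", function(object) {
  cat(sprintf("MGRFModel: Q = %d levels over [%.1f, %.1f] HU, %d pairwise families + star clique\n",
              object@Q, object@range[1], object@range[2],
              length(object@offsets)))
})

setMethod("show", "SHFit", function(object) {
  cat(sprintf("SHFit: orders 0..%d, final normalized error %.4g\n",
              object@maxOrder,
              object@errorCurve[length(object@errorCurve)]))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: AC %.2f%%  SN %.2f%%  SP %.2f%%  PR %.2f%%  AUC %.4f\n",
              object@accuracy, object@sensitivity, object@specificity,
              object@precision, object@auc))
})

#' Extract a NoduleRecord's pieces
#'
#' @param x a [NoduleRecord-class].
#' @return `noduleVOI()` the VOI volume, `noduleMask()` the mask,
#'   `noduleLabel()` the class label.
#' @name record-accessors
NULL

#' @rdname record-accessors
#' @export
setGeneric("noduleVOI", function(x) standardGeneric("noduleVOI"))
#' @rdname record-accessors
#' @export
setMethod("noduleVOI", "NoduleRecord", function(x) x@voi)
#' @rdname record-accessors
#' @export
setGeneric("noduleMask", function(x) standardGeneric("noduleMask"))
#' @rdname record-accessors
#' @export
setMethod("noduleMask", "NoduleRecord", function(x) x@mask)
#' @rdname record-accessors
#' @export
setGeneric("noduleLabel", function(x) standardGeneric("noduleLabel"))
#' @rdname record-accessors
#' @export
setMethod("noduleLabel", "NoduleRecord", function(x) x@label)
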