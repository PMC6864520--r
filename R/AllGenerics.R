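#' Accessor generics
#'
#' Small accessor layer over the package classes so user code never touches
#' slots directly.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("descValues", function(x) standardGeneric("descValues"))

#' @rdname accessors
#' @export
setGeneric("searchOffsets", function(x) standardGeneric("searchOffsets"))

#' @rdname accessors
#' @export
setGeneric("varianceMap", function(x) standardGeneric("varianceMap"))

#' @rdname accessors
#' @export
setGeneric("simValues", function(x) standardGeneric("simValues"))

#' @rdname accessors
#' @export
setGeneric("displacements", function(x) standardGeneric("displacements"))

#' @rdname accessors
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))

#' @rdname accessors
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' @rdname accessors
#' @export
setGeneric("staticVertices", function(x) standardGeneric("staticVertices"))

#' @rdname accessors
#' @export
setGeneric("dynamicVertices", function(x) standardGeneric("dynamicVertices"))

#' @rdname accessors
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname accessors
#' @export
setGeneric("landmarkPoints", function(x) standardGeneric("landmarkPoints"))

#' @rdname accessors
#' @export
setGeneric("kernelAt", function(x, u) standardGeneric("kernelAt"))

#' @rdname accessors
#' @export
setGeneric("patchOffsets", function(x) standardGeneric("patchOffsets"))

#' @rdname accessors
#' @export
setGeneric("volumeData", function(x) standardGeneric("volumeData"))

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

# ---- methods ----

#' @rdname accessors
#' @export
setMethod("descValues", "DescriptorField", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("searchOffsets", "DescriptorField", function(x) x@searchOffsets)

#' @rdname accessors
#' @export
setMethod("varianceMap", "DescriptorField", function(x) x@varianceMap)

#' @rdname accessors
#' @export
setMethod("simValues", "SimilarityMap", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("displacements", "DeformationField", function(x) x@displacements)

#' @rdname accessors
#' @export
setMethod("displacements", "ControlGrid", function(x) x@displacements)

#' @rdname accessors
#' @export
setMethod("gridDims", "ControlGrid", function(x) x@dims)

#' @rdname accessors
#' @export
setMethod("gridSpacing", "ControlGrid", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("staticVertices", "VertexPartition", function(x) x@staticIdx)

#' @rdname accessors
#' @export
setMethod("dynamicVertices", "VertexPartition", function(x) x@dynamicIdx)

#' @rdname accessors
#' @export
setMethod("labelMatrix", "LabelSpace", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("landmarkPoints", "LandmarkSet", function(x) x@points)

#' @rdname accessors
#' @export
setMethod("patchOffsets", "FoveationOperator", function(x) x@offsets)

#' Kernel lookup by patch offset
#'
#' @param x a [FoveationOperator-class].
#' @param u integer(2), an in-plane patch offset.
#' @return the kernel matrix for offset \code{u} (attribute \code{radius}
#'   gives its half-extent).
#' @rdname accessors
#' @export
setMethod("kernelAt", "FoveationOperator", function(x, u) {
  hit <- which(x@offsets[, 1L] == u[1L] & x@offsets[, 2L] == u[2L])
  if (!length(hit)) stop("offset not in patch support")
  x@kernels[[hit]]
})

#' @rdname accessors
#' @export
setMethod("volumeData", "VolumeRecord", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("voxelSpacing", "VolumeRecord", function(x) x@spacing)

# ---- show methods ----

setMethod("show", "FoveationOperator", function(object) {
  cat(sprintf(
    "FoveationOperator: %dx%d patch, rho=%.3g, theta=%.3g, sigma0=%.4g (%d kernels)\n",
    object@patchShape[1L], object@patchShape[2L], object@rho, object@theta,
    object@sigma0, length(object@kernels)))
})

setMethod("show", "DescriptorField", function(object) {
  d <- dim(object@values)
  cat(sprintf("DescriptorField: %dx%dx%d volume, %d channels\n",
              d[1L], d[2L], d[3L], d[4L]))
})

setMethod("show", "SimilarityMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("SimilarityMap: %dx%dx%d, mean SAD_F = %.4f\n",
              d[1L], d[2L], d[3L], mean(object@values)))
})

setMethod("show", "ControlGrid", function(object) {
  cat(sprintf(
    "ControlGrid: %dx%dx%d vertices, spacing (%g, %g, %g) over %dx%dx%d volume\n",
    object@dims[1L], object@dims[2L], object@dims[3L],
    object@spacing[1L], object@spacing[2L], object@spacing[3L],
    object@imageDim[1L], object@imageDim[2L], object@imageDim[3L]))
})

setMethod("show", "DeformationField", function(object) {
  d <- dim(object@displacements)
  mag <- sqrt(rowSums(matrix(object@displacements, ncol = 3L)^2))
  cat(sprintf("DeformationField: %dx%dx%d, max |d| = %.3f voxels\n",
              d[1L], d[2L], d[3L], max(mag)))
})

setMethod("show", "LabelSpace", function(object) {
  cat(sprintf("LabelSpace: %d labels, quantum %g voxels, %d steps per axis\n",
              nrow(object@labels), object@quantum, object@maxSteps))
})

setMethod("show", "VertexPartition", function(object) {
  n <- prod(object@gridDims)
  cat(sprintf(
    "VertexPartition: |G|=%d, static %d, dynamic %d (%.1f%% dynamic)\n",
    n, length(object@staticIdx), length(object@dynamicIdx),
    100 * length(object@dynamicIdx) / n))
})

setMethod("show", "RegistrationResult", function(object) {
  rep <- object@report
  cat("RegistrationResult\n")
  cat(sprintf("  dynamic vertices: %d of %d\n",
              rep$partition$dynamic, rep$partition$total))
  if (length(rep$energyTrace))
    cat(sprintf("  final energy: %.6g\n",
                utils::tail(unlist(rep$energyTrace), 1L)))
  if (length(rep$warnings))
    cat("  warnings:", paste(rep$warnings, collapse = "; "), "\n")
})

setMethod("show", "TREResult", function(object) {
  cat(sprintf("TRE: mean %.3f +/- %.3f %s over %d landmarks\n",
              object@mean, object@sd, object@units,
              length(object@perLandmark)))
})

setMethod("show", "LandmarkSet", function(object) {
  cat(sprintf("LandmarkSet: %d points\n", nrow(object@points)))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %dx%dx%d, %d blobs, remap '%s' (noise %.3g), %d RBFs, amplitude %.2f vox, seed %d\n",
    object@shape[1L], object@shape[2L], object@shape[3L], object@nBlobs,
    object@remapMode, object@noiseSigma, object@nCenters, object@amplitude,
    object@seed))
})
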