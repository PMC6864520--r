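#' @import methods
NULL

#' Foveation operator: a bank of space-variant blur kernels
#'
#' A \code{FoveationOperator} holds one discrete blur kernel per offset
#' \code{u} of the in-plane patch support \code{S}. The kernel at the patch
#' centre (\code{u = 0}) is a near-delta with base standard deviation
#' \code{sigma0}; peripheral kernels widen with \code{|u|} and, for
#' \code{rho > 1}, elongate along the radial direction \code{angle(u) + theta}.
#' Every kernel is nonnegative and L1-normalised, so foveating a constant
#' image reproduces that constant.
#'
#' @slot patchShape integer(2), odd in-plane extent of the patch support S.
#' @slot rho numeric(1), kernel elongation (>= 1 elongates radially; 1 is
#'   isotropic).
#' @slot theta numeric(1), angular offset in radians added to the radial
#'   direction of each peripheral kernel.
#' @slot sigma0 numeric(1), standard deviation (in voxels) of the central
#'   kernel; default \code{1/(2*pi)}.
#' @slot offsets integer matrix, one row per patch offset \code{u} (two
#'   in-plane components), in channel order.
#' @slot kernels list of numeric matrices, one per row of \code{offsets};
#'   each of odd square extent \code{2*radius+1}, summing to 1.
#'
#' @seealso [buildFoveationOperator()]
#' @export
setClass("FoveationOperator",
  representation(
    patchShape = "integer",
    rho = "numeric",
    theta = "numeric",
    sigma0 = "numeric",
    offsets = "matrix",
    kernels = "list"
  )
)

setValidity("FoveationOperator", function(object) {
  msg <- character()
  if (length(object@patchShape) != 2L || any(object@patchShape %% 2L == 0L))
    msg <- c(msg, "patchShape must be two odd integers")
  if (object@rho <= 0) msg <- c(msg, "rho must be positive")
  if (nrow(object@offsets) != length(object@kernels))
    msg <- c(msg, "one kernel per offset required")
  sums <- vapply(object@kernels, sum, numeric(1))
  if (any(abs(sums - 1) > 1e-8))
    msg <- c(msg, "kernels must sum to 1")
  if (any(vapply(object@kernels, function(k) any(k < 0), logical(1))))
    msg <- c(msg, "kernels must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Per-voxel foveated patch
#'
#' The result of foveating a volume at one fixation point: one blurred
#' intensity per offset of the patch support S, arranged as a matrix with
#' the same in-plane shape as S.
#'
#' @slot values numeric matrix of blurred intensities, \code{patchShape} extent.
#' @slot center integer(3), the fixation voxel (1-based).
#' @export
setClass("FoveatedPatch",
  representation(values = "matrix", center = "integer")
)

#' FMIND descriptor field
#'
#' Per-voxel FMIND vectors: one channel per search offset \code{r}, each
#' channel the exponentiated, variance-normalised foveated distance to the
#' neighbour at \code{x + r}, rescaled so the per-voxel channel maximum is
#' exactly 1.
#'
#' @slot values 4D numeric array, volume dimensions by \code{|R|} channels.
#' @slot searchOffsets integer matrix \code{|R| x 3}, the search window R in
#'   channel order.
#' @slot varianceMap 3D numeric array of the foveated patch variance
#'   (floored before use as a denominator).
#' @slot varianceFloor numeric(1), the floor applied to \code{varianceMap}.
#' @export
setClass("DescriptorField",
  representation(
    values = "array",
    searchOffsets = "matrix",
    varianceMap = "array",
    varianceFloor = "numeric"
  )
)

setValidity("DescriptorField", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 4L) msg <- c(msg, "values must be a 4D array")
  if (d[4L] != nrow(object@searchOffsets))
    msg <- c(msg, "channel count must match searchOffsets rows")
  if (!identical(dim(object@varianceMap), d[1:3]))
    msg <- c(msg, "varianceMap must match volume dimensions")
  if (any(object@values <= 0) || any(object@values > 1 + 1e-12))
    msg <- c(msg, "channel values must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Voxelwise descriptor similarity map
#'
#' The mean absolute difference between two FMIND vectors at each voxel
#' (SAD_F), in [0, 1): zero where local structure agrees exactly.
#'
#' @slot values 3D numeric array of SAD_F values.
#' @export
setClass("SimilarityMap", representation(values = "array"))

setValidity("SimilarityMap", function(object) {
  if (any(object@values < 0) || any(object@values >= 1))
    "SAD_F values must lie in [0, 1)" else TRUE
})

#' Free-form deformation control grid
#'
#' Cubic B-spline control lattice covering the image domain with one margin
#' ring of vertices on every side. Vertex \code{(i,j,k)} (1-based) sits at
#' 0-based voxel position \code{(i-2)*spacing} per axis.
#'
#' @slot imageDim integer(3), the voxel dimensions of the covered volume.
#' @slot spacing numeric(3), vertex spacing per axis in voxels.
#' @slot dims integer(3), vertex counts per axis.
#' @slot displacements 4D numeric array \code{dims x 3} of vertex
#'   displacements in voxels.
#' @seealso [makeControlGrid()], [densify()]
#' @export
setClass("ControlGrid",
  representation(
    imageDim = "integer",
    spacing = "numeric",
    dims = "integer",
    displacements = "array"
  )
)

setValidity("ControlGrid", function(object) {
  msg <- character()
  if (any(object@dims < 2L)) msg <- c(msg, "at least 2 vertices per axis")
  if (!identical(dim(object@displacements), c(object@dims, 3L)))
    msg <- c(msg, "displacements must be dims x 3")
  if (length(msg)) msg else TRUE
})

#' Dense deformation field
#'
#' Per-voxel 3-component displacement in voxel units, stored x-fastest as a
#' 4D array with the component as the fourth dimension. Used both for
#' ground-truth synthetic warps and for estimated registrations; volumes are
#' warped backwards (pull) through the field.
#'
#' @slot displacements 4D numeric array, volume dimensions by 3 components.
#' @export
setClass("DeformationField", representation(displacements = "array"))

setValidity("DeformationField", function(object) {
  d <- dim(object@displacements)
  if (length(d) != 4L || d[4L] != 3L)
    return("displacements must be a 4D array with 3 components")
  if (any(!is.finite(object@displacements)))
    return("displacements must be finite")
  TRUE
})

#' Discrete displacement label space
#'
#' Candidate vertex displacements for the MRF: the zero vector (label 1)
#' plus axis-aligned moves \code{+/- k*quantum} per axis for
#' \code{k = 1..maxSteps}, giving \code{6*maxSteps + 1} labels.
#'
#' @slot labels numeric matrix, one 3-component displacement per row;
#'   row 1 is the zero displacement.
#' @slot quantum numeric(1), displacement step in voxels.
#' @slot maxSteps integer(1), steps per axis and sign.
#' @export
setClass("LabelSpace",
  representation(labels = "matrix", quantum = "numeric", maxSteps = "integer")
)

setValidity("LabelSpace", function(object) {
  msg <- character()
  if (any(object@labels[1L, ] != 0))
    msg <- c(msg, "label 1 must be the zero displacement")
  if (anyDuplicated(object@labels)) msg <- c(msg, "labels must be distinct")
  if (length(msg)) msg else TRUE
})

#' Static/dynamic partition of the control-vertex set
#'
#' Disjoint split of the FFD vertex set G into static vertices (frozen at
#' zero displacement) and dynamic vertices (optimised), derived from the
#' descriptor similarity map: a vertex is static when, in the local image
#' patch of radius \code{rlp} around it, the fraction of voxels with
#' similarity \code{1 - SAD_F > delta} exceeds the static factor
#' \code{epsilon}.
#'
#' @slot staticIdx integer vector, linear vertex indices of the static set.
#' @slot dynamicIdx integer vector, linear vertex indices of the dynamic set.
#' @slot gridDims integer(3), vertex counts of the underlying grid.
#' @slot params named list with \code{rlp}, \code{delta}, \code{epsilon}.
#' @seealso [partitionVertices()], [maskFromPartition()]
#' @export
setClass("VertexPartition",
  representation(
    staticIdx = "integer",
    dynamicIdx = "integer",
    gridDims = "integer",
    params = "list"
  )
)

setValidity("VertexPartition", function(object) {
  n <- prod(object@gridDims)
  all_idx <- sort(c(object@staticIdx, object@dynamicIdx))
  if (length(all_idx) != n || !identical(all_idx, seq_len(n)))
    return("staticIdx and dynamicIdx must partition the vertex set")
  TRUE
})

#' First-order MRF registration energy model
#'
#' Data costs per dynamic vertex and label, plus the L1 smoothness term
#' with weight \code{lambda} over the 6-neighbourhood vertex graph; the
#' total energy is normalised by the vertex count \code{|G|}. Static
#' vertices keep the zero label and contribute their fixed terms.
#'
#' @slot dataCosts numeric matrix, dynamic vertices by labels.
#' @slot staticCosts numeric vector, fixed data term of each static vertex
#'   (zero-label costs; zeros when not evaluated).
#' @slot labels numeric matrix of label displacements (rows match columns of
#'   \code{dataCosts}).
#' @slot lambda numeric(1), smoothness weight.
#' @slot edges integer matrix, one undirected vertex pair (linear indices)
#'   per row, the 6-neighbourhood lattice adjacency over all of G.
#' @slot gridDims integer(3).
#' @slot dynamicIdx,staticIdx integer vectors as in [VertexPartition-class].
#' @export
setClass("EnergyModel",
  representation(
    dataCosts = "matrix",
    staticCosts = "numeric",
    labels = "matrix",
    lambda = "numeric",
    edges = "matrix",
    gridDims = "integer",
    dynamicIdx = "integer",
    staticIdx = "integer"
  )
)

setValidity("EnergyModel", function(object) {
  msg <- character()
  if (any(!is.finite(object@dataCosts)) || any(object@dataCosts < 0))
    msg <- c(msg, "data costs must be finite and nonnegative")
  if (object@lambda < 0) msg <- c(msg, "lambda must be nonnegative")
  if (nrow(object@dataCosts) != length(object@dynamicIdx))
    msg <- c(msg, "one data-cost row per dynamic vertex")
  if (ncol(object@dataCosts) != nrow(object@labels))
    msg <- c(msg, "one data-cost column per label")
  if (length(msg)) msg else TRUE
})

#' Registration configuration
#'
#' Tunable parameters of the FMIND registration pipeline. Defaults follow
#' the method's standard parameterisation: elongation \code{rho = 2}, angular offset
#' \code{theta = 0}, a 5 x 5 foveated patch, smoothness weight
#' \code{lambda = 0.01}, partition patch radius \code{rlp = 7}, similarity
#' threshold \code{delta = 0.8} and static factor \code{epsilon = 0.9}.
#'
#' @slot rho,theta,sigma0 foveation parameters (see
#'   [FoveationOperator-class]).
#' @slot patchShape integer(2), in-plane patch support extent.
#' @slot planeAxis integer(1), axis (1-3) orthogonal to the patch plane;
#'   3 means axial in-plane patches.
#' @slot lambda numeric(1), MRF smoothness weight.
#' @slot rlp,delta,epsilon vertex-partition parameters.
#' @slot gridSpacing numeric(1), FFD vertex spacing in voxels.
#' @slot labelQuantum numeric(1), displacement step of the label space in
#'   voxels (first cycle).
#' @slot labelSteps integer(1), label steps per axis and sign.
#' @slot maxCycles integer(1), outer label-refinement cycles.
#' @slot refineQuantum logical(1), halve the quantum between cycles.
#' @slot quantumHold integer(1), cycles run at the full quantum before
#'   halving begins.
#' @slot maxSweeps integer(1), expansion sweeps per cycle.
#' @slot pyramidLevels integer(1), resolution levels; \code{NA} selects 2
#'   for volumes larger than 64 voxels per axis and 1 otherwise.
#' @slot refreshPartition logical(1), recompute the partition each cycle
#'   from the current warped descriptors.
#' @slot solver character(1), \code{"expansion"} (max-flow) or \code{"icm"}.
#' @slot varianceFloorFactor numeric(1), variance floor as a fraction of the
#'   squared intensity range.
#' @seealso [fmindConfig()], [registerFMIND()]
#' @export
setClass("FMINDConfig",
  representation(
    rho = "numeric", theta = "numeric", sigma0 = "numeric",
    patchShape = "integer", planeAxis = "integer",
    lambda = "numeric",
    rlp = "numeric", delta = "numeric", epsilon = "numeric",
    gridSpacing = "numeric",
    labelQuantum = "numeric", labelSteps = "integer",
    maxCycles = "integer", refineQuantum = "logical",
    quantumHold = "integer", maxSweeps = "integer",
    pyramidLevels = "integer", refreshPartition = "logical",
    solver = "character", varianceFloorFactor = "numeric"
  )
)

#' Result of a registration run
#'
#' @slot field the estimated [DeformationField-class].
#' @slot warped 3D numeric array, the float volume pulled through the field.
#' @slot report named list: parameters, partition counts, per-cycle energy
#'   traces, warnings and timings.
#' @export
setClass("RegistrationResult",
  representation(field = "DeformationField", warped = "array",
                 report = "list")
)

#' A set of landmark voxel coordinates
#'
#' Coordinates are 1-based voxel indices in R; the on-disk CSV format is
#' 0-based (see [readLandmarks()]).
#'
#' @slot points numeric matrix, N rows of (x, y, z).
#' @export
setClass("LandmarkSet", representation(points = "matrix"))

setValidity("LandmarkSet", function(object) {
  if (ncol(object@points) != 3L) return("points must have 3 columns")
  if (nrow(object@points) < 1L) return("at least one landmark required")
  if (any(!is.finite(object@points))) return("landmarks must be finite")
  TRUE
})

#' Target registration error summary
#'
#' @slot perLandmark numeric vector of per-landmark Euclidean errors.
#' @slot mean,sd numeric(1), mean and standard deviation of the errors.
#' @slot units character(1), \code{"voxels"} or \code{"mm"}.
#' @export
setClass("TREResult",
  representation(perLandmark = "numeric", mean = "numeric", sd = "numeric",
                 units = "character")
)

#' Synthetic multi-modal test case specification
#'
#' Describes one desk-scale evaluation case: a blob phantom, a second
#' "modality" created by a nonlinear intensity remapping plus noise, and a
#' smooth ground-truth warp built as a linear combination of Gaussian
#' radial basis functions.
#'
#' @slot shape integer(3), volume dimensions.
#' @slot nBlobs integer(1), phantom structure count.
#' @slot remapMode character(1), one of \code{"identity"}, \code{"invert"},
#'   \code{"gamma"}, \code{"nonmonotone-bands"}.
#' @slot noiseSigma numeric(1), additive Gaussian noise sd (intensity units,
#'   post-rescale).
#' @slot nCenters integer(1), RBF count.
#' @slot amplitude numeric(1), maximum displacement magnitude in voxels.
#' @slot rbfSigma numeric(1), RBF width in voxels.
#' @slot nLandmarks integer(1), auto-landmark count.
#' @slot seed integer(1), RNG seed.
#' @seealso [syntheticSpec()], [simulateCase()]
#' @export
setClass("SyntheticSpec",
  representation(
    shape = "integer", nBlobs = "integer", remapMode = "character",
    noiseSigma = "numeric", nCenters = "integer", amplitude = "numeric",
    rbfSigma = "numeric", nLandmarks = "integer", seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@amplitude < 0) msg <- c(msg, "amplitude must be >= 0")
  if (!object@remapMode %in%
      c("identity", "invert", "gamma", "nonmonotone-bands"))
    msg <- c(msg, "unknown remapMode")
  if (length(msg)) msg else TRUE
})

#' In-memory volume with voxel spacing
#'
#' Thin container for a scalar 3D (or 4D, for descriptor/field exports)
#' array read from or destined for a NIfTI file.
#'
#' @slot data numeric array.
#' @slot spacing numeric, voxel size in mm per axis.
#' @slot source character(1), originating path ("" for in-memory data).
#' @export
setClass("VolumeRecord",
  representation(data = "array", spacing = "numeric", source = "character")
)
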