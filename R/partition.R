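#' Partition control vertices into static and dynamic sets
#'
#' The descriptor-driven spatial constraint: around each control vertex, a
#' cubic local patch LP of radius \code{rlp} voxels (clipped to the
#' volume) is inspected, and \code{con} counts its voxels whose similarity
#' \code{1 - SAD_F > delta}. The vertex is static when
#' \code{con / |LP| > epsilon} (strict inequalities throughout); all other
#' vertices are dynamic and enter the MRF optimisation. The clipped patch
#' size is used in the ratio so border vertices are not biased toward
#' dynamic, and margin-ring vertex positions are clamped into the volume
#' so they are judged by the nearest image content.
#'
#' @param similarity a [SimilarityMap-class] between the reference and
#'   float descriptor fields.
#' @param grid a [ControlGrid-class] over the same volume.
#' @param rlp patch radius in voxels (>= 1).
#' @param delta similarity threshold in [0, 1].
#' @param epsilon static factor in [0, 1].
#' @return a [VertexPartition-class].
#' @export
partitionVertices <- function(similarity, grid, rlp = 7, delta = 0.8,
                              epsilon = 0.9) {
  if (delta < 0 || delta > 1) stop("delta must lie in [0, 1]")
  if (epsilon < 0 || epsilon > 1) stop("epsilon must lie in [0, 1]")
  if (rlp < 1) stop("rlp must be >= 1")
  sim <- similarity@values
  dm <- dim(sim)
  if (!identical(as.integer(dm), grid@imageDim))
    stop("similarity map and grid cover different volumes")
  rlp <- as.integer(round(rlp))
  ok <- array(as.numeric(1 - sim > delta), dm)
  boxSum <- makeBoxSummer(ok)
  dims <- grid@dims
  static <- logical(prod(dims))
  for (v in seq_len(prod(dims))) {
    t3 <- arrayInd(v, dims)
    # vertex voxel position, clamped into the volume so margin-ring
    # vertices are judged by the nearest image content
    ctr <- as.integer(round((t3 - 2) * grid@spacing)) + 1L
    ctr <- pmin(pmax(ctr, 1L), grid@imageDim)
    lo <- pmax(ctr - rlp, 1L)
    hi <- pmin(ctr + rlp, grid@imageDim)
    size <- prod(hi - lo + 1L)
    con <- boxSum(lo, hi)
    static[v] <- (con / size) > epsilon
  }
  new("VertexPartition",
      staticIdx = which(static), dynamicIdx = which(!static),
      gridDims = dims,
      params = list(rlp = rlp, delta = delta, epsilon = epsilon))
}

#' Binary registration mask from a vertex partition
#'
#' Marks every voxel lying in the cubic B-spline support of at least one
#' dynamic vertex — the region the deformation model can actually move.
#' This is the automatic mask the spatial constraint produces without
#' manual intervention or segmentation.
#'
#' @param partition a [VertexPartition-class].
#' @param imageDim integer(3), volume dimensions.
#' @param grid the [ControlGrid-class] the partition refers to.
#' @return 3D integer array of 0/1.
#' @export
maskFromPartition <- function(partition, imageDim, grid) {
  imageDim <- as.integer(imageDim)
  mask <- array(0L, imageDim)
  for (v in partition@dynamicIdx) {
    t3 <- arrayInd(v, partition@gridDims)
    rx <- .vertexSupportRange(t3[1L], grid@spacing[1L], imageDim[1L])
    ry <- .vertexSupportRange(t3[2L], grid@spacing[2L], imageDim[2L])
    rz <- .vertexSupportRange(t3[3L], grid@spacing[3L], imageDim[3L])
    if (rx[1L] > rx[2L] || ry[1L] > ry[2L] || rz[1L] > rz[2L]) next
    mask[rx[1L]:rx[2L], ry[1L]:ry[2L], rz[1L]:rz[2L]] <- 1L
  }
  mask
}
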