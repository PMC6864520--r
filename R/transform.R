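# Cubic B-spline basis, cardinal form centred on a knot: support (-2, 2).
bspline3 <- function(r) {
  a <- abs(r)
  ifelse(a < 1, (4 - 6 * a^2 + 3 * a^3) / 6,
         ifelse(a < 2, (2 - a)^3 / 6, 0))
}

#' Create a zero-initialised FFD control grid
#'
#' Vertex counts are \code{ceiling(imageDim / spacing) + 3} per axis: the
#' extra ring supplies the cubic B-spline margin so that every voxel lies
#' in a fully supported cell. Vertex \code{(i,j,k)} (1-based) sits at
#' 0-based voxel position \code{(i-2)*spacing}.
#'
#' @param imageDim integer(3), volume dimensions in voxels.
#' @param spacing vertex spacing in voxels (scalar or per-axis), >= 2.
#' @return a [ControlGrid-class] with zero displacements.
#' @examples
#' gridDims(makeControlGrid(c(64, 64, 64), 8))  # 11 x 11 x 11
#' @export
makeControlGrid <- function(imageDim, spacing = 8) {
  imageDim <- as.integer(imageDim)
  if (length(imageDim) != 3L || any(imageDim < 1L))
    stop("imageDim must be three positive integers")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing < 2)) stop("grid spacing must be at least 2 voxels")
  dims <- as.integer(ceiling(imageDim / spacing) + 3L)
  new("ControlGrid", imageDim = imageDim, spacing = as.numeric(spacing),
      dims = dims, displacements = array(0, c(dims, 3L)))
}

# Per-axis sparse interpolation matrix W (n voxels x d vertices):
# W[x, t] = B3((X/spacing) - t + 2) with X = x - 1 (0-based), four
# nonzeros per row. Its transpose is the basis-weighting matrix used for
# data-cost aggregation.
.axisBasisMatrix <- function(n, d, spacing) {
  X <- (seq_len(n) - 1) / spacing
  i0 <- floor(X)
  u <- X - i0
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  B <- cbind((1 - u)^3 / 6,
             (3 * u^3 - 6 * u^2 + 4) / 6,
             (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6,
             u^3 / 6)
  for (l in 0:3) {
    rows <- c(rows, seq_len(n))
    cols <- c(cols, i0 + 1L + l)
    vals <- c(vals, B[, l + 1L])
  }
  if (any(cols > d)) stop("control grid does not cover the volume")
  Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(n, d))
}

# Contract tensor A (3D) along the given axis with matrix M (new x old).
.tensorAxis <- function(A, M, axis) {
  d <- dim(A)
  perm <- c(axis, setdiff(1:3, axis))
  Ap <- aperm(A, perm)
  dp <- dim(Ap)
  res <- as.matrix(M %*% matrix(Ap, dp[1L], dp[2L] * dp[3L]))
  res <- array(res, c(nrow(M), dp[2L], dp[3L]))
  aperm(res, order(perm))
}

#' Densify a control grid into a voxelwise deformation field
#'
#' Cubic B-spline tensor-product interpolation of the vertex displacements
#' at every voxel. The result is C2-continuous across cells, and constant
#' vertex displacements reproduce that constant everywhere (partition of
#' unity).
#'
#' @param grid a [ControlGrid-class].
#' @return a [DeformationField-class] over the grid's image domain.
#' @export
densify <- function(grid) {
  dm <- grid@imageDim
  W <- lapply(1:3, function(a)
    .axisBasisMatrix(dm[a], grid@dims[a], grid@spacing[a]))
  out <- array(0, c(dm, 3L))
  for (cpt in 1:3) {
    A <- array(grid@displacements[, , , cpt], grid@dims)
    A <- .tensorAxis(A, W[[1L]], 1L)
    A <- .tensorAxis(A, W[[2L]], 2L)
    A <- .tensorAxis(A, W[[3L]], 3L)
    out[, , , cpt] <- A
  }
  new("DeformationField", displacements = out)
}

#' Warp a volume through a deformation field
#'
#' Backward (pull) warping: the output at voxel \code{x} samples the input
#' trilinearly at \code{x + field(x)} (displacements in voxels); samples
#' falling outside the domain clamp to the nearest edge.
#'
#' @param volume 3D numeric array.
#' @param field a [DeformationField-class] with matching dimensions.
#' @return warped 3D array of the same shape.
#' @export
warpVolume <- function(volume, field) {
  dm <- dim(volume)
  fd <- dim(field@displacements)
  if (length(dm) != 3L || !identical(as.integer(dm), as.integer(fd[1:3])))
    stop("volume and field dimensions must match")
  if (all(field@displacements == 0)) return(volume)
  g <- coordGrids(dm)
  s <- sampleTrilinear(volume,
                       g$x + as.vector(field@displacements[, , , 1L]),
                       g$y + as.vector(field@displacements[, , , 2L]),
                       g$z + as.vector(field@displacements[, , , 3L]))
  array(s, dm)
}

#' Number of dense deformation-field variables for a volume
#'
#' Three displacement components per voxel: \code{3 * nx * ny * nz}. For a
#' 256-cubed volume this is 50,331,648 unknowns, the count the FFD control
#' grid and the static/dynamic vertex partition exist to reduce.
#'
#' @param imageDim integer(3), volume dimensions.
#' @return the variable count (double, to avoid integer overflow).
#' @export
countFieldVariables <- function(imageDim) {
  if (any(imageDim < 1)) stop("dimensions must be positive")
  3 * prod(as.numeric(imageDim))
}

#' Resize a deformation field to a new geometry
#'
#' Trilinearly resamples each displacement component onto \code{newDim}
#' and scales the displacement magnitudes by the dimension ratio. Used to
#' carry a coarse pyramid level's field to the finer level.
#'
#' @param field a [DeformationField-class].
#' @param newDim integer(3), target dimensions.
#' @return resized [DeformationField-class].
#' @export
resizeField <- function(field, newDim) {
  od <- dim(field@displacements)[1:3]
  newDim <- as.integer(newDim)
  g <- coordGrids(newDim)
  scale <- (newDim - 1) / pmax(od - 1, 1L)
  cx <- (g$x - 1) / scale[1L] + 1
  cy <- (g$y - 1) / scale[2L] + 1
  cz <- (g$z - 1) / scale[3L] + 1
  out <- array(0, c(newDim, 3L))
  for (cpt in 1:3) {
    s <- sampleTrilinear(array(field@displacements[, , , cpt], od),
                         cx, cy, cz)
    out[, , , cpt] <- array(s * scale[cpt], newDim)
  }
  new("DeformationField", displacements = out)
}

#' Compose two deformation fields
#'
#' Returns the field of the composite warp "first \code{inner}, then
#' \code{outer}" under backward warping: \code{T(x) = d_in(x) +
#' d_out(x + d_in(x))} so that \code{warpVolume(V, T)} equals
#' \code{warpVolume(warpVolume(V, outer), inner)}.
#'
#' @param outer,inner [DeformationField-class] objects of equal shape.
#' @return composed [DeformationField-class].
#' @export
composeFields <- function(outer, inner) {
  dm <- dim(inner@displacements)[1:3]
  if (!identical(dim(outer@displacements), dim(inner@displacements)))
    stop("field dimensions must match")
  g <- coordGrids(dm)
  cx <- g$x + as.vector(inner@displacements[, , , 1L])
  cy <- g$y + as.vector(inner@displacements[, , , 2L])
  cz <- g$z + as.vector(inner@displacements[, , , 3L])
  out <- array(0, c(dm, 3L))
  for (cpt in 1:3) {
    s <- sampleTrilinear(array(outer@displacements[, , , cpt], dm),
                         cx, cy, cz)
    out[, , , cpt] <- array(as.vector(inner@displacements[, , , cpt]) + s,
                            dm)
  }
  new("DeformationField", displacements = out)
}

#' An identity (all-zero) deformation field
#'
#' @param imageDim integer(3), volume dimensions.
#' @return a [DeformationField-class] of zeros.
#' @export
identityField <- function(imageDim) {
  new("DeformationField",
      displacements = array(0, c(as.integer(imageDim), 3L)))
}
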