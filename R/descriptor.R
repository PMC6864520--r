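#' The default 3D search window: the six-neighbourhood
#'
#' @return integer matrix 6 x 3, one unit offset per row.
#' @export
sixNeighborhood <- function() {
  matrix(as.integer(c(
     1, 0, 0,
    -1, 0, 0,
     0, 1, 0,
     0,-1, 0,
     0, 0, 1,
     0, 0,-1)), ncol = 3L, byrow = TRUE,
    dimnames = list(NULL, c("dx", "dy", "dz")))
}

#' Compute the FMIND descriptor field of a volume
#'
#' For every voxel \code{x} and search offset \code{r}, the channel value is
#' \deqn{FMIND(I, x, r) = \frac{1}{n}\exp\left(-\frac{d_{FOV}(I, x, x+r)}
#'   {V_{FOV}(I, x)}\right)}
#' where \eqn{d_{FOV}} is the foveated patch distance, \eqn{V_{FOV}} the
#' foveated patch variance (mean of \eqn{d_{FOV}} over the patch support,
#' floored at \code{varianceFloor}) and \eqn{n} the per-voxel maximum of
#' the exponentials, so that every voxel's largest channel is exactly 1.
#' Fixation points falling outside the volume are mirror-folded back in.
#'
#' Intensities are rescaled to [0, 1] first (see [rescale01()]) so that
#' thresholds downstream are transferable across modalities; disable with
#' \code{rescale = FALSE} if the volume is already normalised.
#'
#' @param image 3D numeric array with finite values.
#' @param operator a [FoveationOperator-class]; default the 5 x 5,
#'   \code{rho = 2} operator.
#' @param offsets integer matrix of nonzero, distinct search offsets (rows);
#'   default [sixNeighborhood()].
#' @param planeAxis axis orthogonal to the foveated-patch plane.
#' @param varianceFloor floor for the variance denominator; \code{NULL}
#'   uses \code{1e-6} times the squared intensity range after rescaling.
#' @param rescale rescale intensities to [0, 1] first (default TRUE).
#' @return a [DescriptorField-class].
#' @examples
#' img <- array(stats::runif(8 * 8 * 4), c(8, 8, 4))
#' d <- computeFMIND(img)
#' max(abs(apply(descValues(d), 1:3, max) - 1))  # per-voxel max channel is 1
#' @export
computeFMIND <- function(image, operator = buildFoveationOperator(),
                         offsets = sixNeighborhood(), planeAxis = 3L,
                         varianceFloor = NULL, rescale = TRUE) {
  dm <- dim(image)
  if (length(dm) != 3L) stop("image must be a 3D array")
  if (any(!is.finite(image))) stop("image must be finite")
  offsets <- matrix(as.integer(offsets), ncol = 3L)
  if (nrow(offsets) == 0L) stop("search offset list must not be empty")
  if (any(rowSums(abs(offsets)) == 0L)) stop("search offsets must be nonzero")
  if (anyDuplicated(offsets)) stop("search offsets must be distinct")

  if (rescale) image <- rescale01(image)
  if (is.null(varianceFloor))
    varianceFloor <- 1e-6 * diff(range(image))^2
  varianceFloor <- max(varianceFloor, .Machine$double.xmin)

  stack <- .foveatedStack(image, operator, planeAxis)
  v <- pmax(.varianceVolume(stack, operator, planeAxis), varianceFloor)
  if (!is.array(v)) v <- array(v, dm)

  nr <- nrow(offsets)
  dvol <- array(NA_real_, c(dm, nr))
  for (i in seq_len(nr))
    dvol[, , , i] <- .dfovVolume(stack, offsets[i, ])
  # normalise inside the exponent (n = exp(-dmin/V)): algebraically the
  # same per-voxel max-normalisation, but immune to underflow when d >> V
  dmin <- apply(dvol, 1:3, min)
  vals <- exp(-sweep(dvol, 1:3, dmin) / as.vector(v))
  vals <- pmax(vals, .Machine$double.xmin)
  new("DescriptorField", values = vals, searchOffsets = offsets,
      varianceMap = v, varianceFloor = varianceFloor)
}

#' Voxelwise SAD between two descriptor fields
#'
#' The similarity map value at voxel \code{x} is the mean over search
#' offsets \code{r} of \code{|FMIND(I, x, r) - FMIND(J, x, r)|}; it is 0
#' where descriptors agree exactly and approaches 1 only for maximally
#' dissimilar descriptors. Both fields must share the volume shape and
#' search-offset order.
#'
#' @param descA,descB [DescriptorField-class] objects over the same
#'   geometry.
#' @return a [SimilarityMap-class].
#' @export
similaritySAD <- function(descA, descB) {
  if (!identical(dim(descA@values), dim(descB@values)) ||
      !identical(descA@searchOffsets, descB@searchOffsets))
    stop("incompatible descriptor fields: shape or search offsets differ")
  d <- dim(descA@values)
  acc <- 0
  for (i in seq_len(d[4L]))
    acc <- acc + abs(descA@values[, , , i] - descB@values[, , , i])
  new("SimilarityMap", values = array(acc / d[4L], d[1:3]))
}
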