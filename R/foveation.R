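#' Build an anisotropic foveation operator
#'
#' Constructs the bank of per-offset blur kernels that mimics retinal
#' acuity falloff: a near-delta kernel at the patch centre and, toward the
#' periphery, increasingly wide elliptical Gaussian kernels whose major
#' axis points along the radial direction \code{angle(u) + theta} with an
#' along/across standard-deviation ratio of \code{rho}.
#'
#' Each kernel is an elliptical Gaussian of scale
#' \code{sigma(u) = sigma0 * (1 + 2*|u|)} (major axis sd
#' \code{sqrt(rho)*sigma(u)}, minor axis sd \code{sigma(u)/sqrt(rho)}),
#' integrated over unit pixel cells on an integer grid truncated at
#' \code{ceiling(3*sqrt(rho)*sigma(u))}, then L1-normalised so constant
#' images are fixed points of foveation. The growth rate of
#' \code{sigma(u)} is chosen so that the second moments of the discretised
#' kernels realise the prescribed anisotropy \code{rho} to within a few
#' percent at every peripheral offset.
#'
#' @param patchShape integer(2), odd in-plane extent of the patch support
#'   S (default 5 x 5).
#' @param rho positive elongation factor; \code{rho = 1} gives isotropic
#'   kernels.
#' @param theta angular offset in radians (default 0).
#' @param sigma0 base standard deviation of the central kernel in voxels
#'   (default \code{1/(2*pi)}, a near-delta on the integer grid).
#' @return a [FoveationOperator-class].
#' @examples
#' op <- buildFoveationOperator(c(5, 5), rho = 2)
#' kernelAt(op, c(0, 0))[2, 2]  # central kernel is delta-like
#' @export
buildFoveationOperator <- function(patchShape = c(5L, 5L), rho = 2,
                                   theta = 0, sigma0 = 1 / (2 * pi)) {
  patchShape <- as.integer(patchShape)
  if (length(patchShape) == 1L) patchShape <- rep(patchShape, 2L)
  if (length(patchShape) != 2L || any(patchShape < 1L) ||
      any(patchShape %% 2L == 0L))
    stop("patchShape must be odd and positive in both dimensions")
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0)
    stop("rho must be a positive scalar")
  if (sigma0 <= 0) stop("sigma0 must be positive")

  h <- (patchShape - 1L) %/% 2L
  offs <- as.matrix(expand.grid(u1 = -h[1L]:h[1L], u2 = -h[2L]:h[2L]))
  offs <- matrix(as.integer(offs), ncol = 2L,
                 dimnames = list(NULL, c("u1", "u2")))

  kernels <- lapply(seq_len(nrow(offs)), function(i) {
    u <- offs[i, ]
    .foveationKernel(u, rho, theta, sigma0)
  })

  new("FoveationOperator", patchShape = patchShape, rho = rho,
      theta = theta, sigma0 = sigma0, offsets = offs, kernels = kernels)
}

# Discrete variance of a pixel-integrated 1D Gaussian of scale sigma.
.binnedVariance <- function(sigma, rad) {
  tt <- -rad:rad
  w <- stats::pnorm((tt + 0.5) / sigma) - stats::pnorm((tt - 0.5) / sigma)
  w <- w / sum(w)
  sum(tt^2 * w)
}

# Continuous scale whose pixel-integrated kernel has the target discrete
# variance (monotone; bisection). Compensates the variance the pixel grid
# adds, so the realised kernel anisotropy matches the prescription.
.calibrateSigma <- function(target, rad) {
  f <- function(s) .binnedVariance(s, rad) - target
  lo <- 1e-3; hi <- sqrt(target) + 1
  if (f(hi) < 0) return(hi)
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# One elliptical Gaussian blur kernel, integrated over pixel cells by
# subgrid supersampling (handles arbitrary orientation), L1-normalised.
# Peripheral axis scales are calibrated against pixel-quantisation spread.
.foveationKernel <- function(u, rho, theta, sigma0, subgrid = 5L) {
  r <- sqrt(sum(u^2))
  if (r == 0) {
    sMaj <- sigma0; sMin <- sigma0; phi <- 0
    rad <- max(1L, as.integer(ceiling(3 * sMaj)))
  } else {
    s <- sigma0 * (1 + 2 * r)
    sMaj <- sqrt(rho) * s
    sMin <- s / sqrt(rho)
    phi <- atan2(u[2L], u[1L]) + theta
    rad <- max(1L, as.integer(ceiling(3 * sMaj)))
    sMaj <- .calibrateSigma(sMaj^2, rad)
    sMin <- .calibrateSigma(sMin^2, rad)
  }
  targMaj <- if (r == 0) NA else rho * (sigma0 * (1 + 2 * r))^2
  targMin <- if (r == 0) NA else (sigma0 * (1 + 2 * r))^2 / rho
  tt <- -rad:rad
  sub <- (seq_len(subgrid) - (subgrid + 1) / 2) / subgrid
  g1 <- rep(tt, each = subgrid) + rep(sub, times = length(tt))
  X <- matrix(rep(g1, times = length(g1)), nrow = length(g1))
  Y <- t(X)
  a <- cos(phi) * X + sin(phi) * Y
  b <- -sin(phi) * X + cos(phi) * Y
  idx <- rep(seq_along(tt), each = subgrid)
  build <- function(sMaj, sMin) {
    w <- exp(-a^2 / (2 * sMaj^2) - b^2 / (2 * sMin^2))
    # collapse the subgrid back onto the integer lattice (the double
    # rowsum yields the transposed aggregation, hence the final t())
    k <- t(rowsum(t(rowsum(w, idx)), idx))
    k / sum(k)
  }
  k <- build(sMaj, sMin)
  if (r > 0) {
    # fixed-point polish: measure the realised along/across-axis discrete
    # variances and rescale toward the targets (rotated kernels pick up
    # extra cross-axis spread from pixel quantisation)
    ti <- matrix(rep(tt, times = length(tt)), length(tt))
    tj <- t(ti)
    pa <- cos(phi) * ti + sin(phi) * tj
    pb <- -sin(phi) * ti + cos(phi) * tj
    for (iter in 1:3) {
      va <- sum(pa^2 * k) - sum(pa * k)^2
      vb <- sum(pb^2 * k) - sum(pb * k)^2
      if (va <= 0 || vb <= 0) break
      sMaj <- sMaj * (targMaj / va)^0.4
      sMin <- sMin * (targMin / vb)^0.4
      k <- build(sMaj, sMin)
    }
  }
  attr(k, "radius") <- rad
  k
}

# Patch axes for a plane selector: the two in-plane axes, in order.
.planeAxes <- function(planeAxis) {
  planeAxis <- as.integer(planeAxis)
  if (!planeAxis %in% 1:3) stop("planeAxis must be 1, 2 or 3")
  setdiff(1:3, planeAxis)
}

#' Foveate a volume at one fixation point
#'
#' Computes the foveated patch at fixation voxel \code{x}: for each patch
#' offset \code{u}, the image is blurred with that offset's kernel and
#' sampled at \code{x + u}, within the plane through \code{x} selected by
#' \code{planeAxis}. Out-of-volume samples use mirror padding.
#'
#' @param image 3D numeric array.
#' @param x integer(3), fixation voxel (1-based), inside the volume.
#' @param operator a [FoveationOperator-class].
#' @param planeAxis axis orthogonal to the patch plane (default 3: axial).
#' @return a [FoveatedPatch-class] with \code{patchShape} values.
#' @export
foveatePatch <- function(image, x, operator, planeAxis = 3L) {
  dm <- dim(image)
  if (length(dm) != 3L) stop("image must be a 3D array")
  x <- checkVoxelInside(x, dm, "fixation point")
  ax <- .planeAxes(planeAxis)
  vals <- vapply(seq_len(nrow(operator@offsets)), function(i) {
    .foveaSample(image, x, operator@offsets[i, ], operator@kernels[[i]], ax)
  }, numeric(1))
  m <- matrix(vals, nrow = operator@patchShape[1L])
  new("FoveatedPatch", values = m, center = x)
}

# Single foveated sample: sum_t I[fold(x + u + t)] * k(t), in-plane axes ax.
.foveaSample <- function(image, x, u, k, ax) {
  dm <- dim(image)
  rad <- attr(k, "radius")
  tt <- -rad:rad
  i1 <- mirrorIndex(x[ax[1L]] + u[1L] + tt, dm[ax[1L]])
  i2 <- mirrorIndex(x[ax[2L]] + u[2L] + tt, dm[ax[2L]])
  idx <- vector("list", 3L)
  idx[[ax[1L]]] <- i1
  idx[[ax[2L]]] <- i2
  idx[[setdiff(1:3, ax)]] <- x[setdiff(1:3, ax)]
  sub <- image[idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE]
  sum(as.vector(sub) * as.vector(k))
}

#' Foveated patch distance between two fixation points
#'
#' Squared Euclidean norm of the difference between the foveated patches
#' at \code{x1} and \code{x2}; symmetric and zero iff the patches agree.
#'
#' @inheritParams foveatePatch
#' @param x1,x2 integer(3), fixation voxels inside the volume.
#' @return nonnegative scalar.
#' @export
foveatedDistance <- function(image, x1, x2, operator, planeAxis = 3L) {
  p1 <- foveatePatch(image, x1, operator, planeAxis)
  p2 <- foveatePatch(image, x2, operator, planeAxis)
  sum((p1@values - p2@values)^2)
}

#' Foveated patch variance at a voxel
#'
#' The mean foveated distance from \code{x} to \code{x + m} over all
#' in-plane patch offsets \code{m} spanning S (the zero offset included).
#' It controls the attenuation of the descriptor exponential; before use
#' as a denominator it is floored at \code{floor} so flat regions do not
#' divide by zero.
#'
#' @inheritParams foveatePatch
#' @param floor the variance floor; \code{NULL} (default) uses
#'   \code{1e-6 * diff(range(image))^2}. Pass 0 for the raw value.
#' @return nonnegative scalar, \code{max(raw variance, floor)}.
#' @export
foveatedVariance <- function(image, x, operator, planeAxis = 3L,
                             floor = NULL) {
  dm <- dim(image)
  x <- checkVoxelInside(x, dm, "fixation point")
  if (is.null(floor)) floor <- 1e-6 * diff(range(image))^2
  ax <- .planeAxes(planeAxis)
  offs <- operator@offsets
  acc <- 0
  for (i in seq_len(nrow(offs))) {
    m3 <- c(0L, 0L, 0L)
    m3[ax] <- offs[i, ]
    x2 <- x + m3
    x2[1L] <- mirrorIndex(x2[1L], dm[1L])
    x2[2L] <- mirrorIndex(x2[2L], dm[2L])
    x2[3L] <- mirrorIndex(x2[3L], dm[3L])
    acc <- acc + foveatedDistance(image, x, x2, operator, planeAxis)
  }
  max(acc / nrow(offs), floor)
}

# ---- fast stack machinery (shared with the descriptor module) ----

# Foveated sample stacks: one volume per patch offset u, where
# stack[[i]][x] = sum_t I[fold(x + u_i + t)] * k_i(t). Computed by mirror
# padding once and FFT convolution per kernel (EBImage), slice-wise in the
# patch plane.
.foveatedStack <- function(image, operator, planeAxis = 3L) {
  dm <- dim(image)
  ax <- .planeAxes(planeAxis)
  perm <- c(ax, setdiff(1:3, ax))
  vol <- aperm(image, perm)  # in-plane axes first
  dmp <- dim(vol)
  offs <- operator@offsets
  rads <- vapply(operator@kernels, attr, integer(1), which = "radius")
  pad <- max(abs(offs)) + max(rads)
  p1 <- mirrorIndex((1L - pad):(dmp[1L] + pad), dmp[1L])
  p2 <- mirrorIndex((1L - pad):(dmp[2L] + pad), dmp[2L])
  padded <- vol[p1, p2, , drop = FALSE]
  n <- nrow(offs)
  stack <- vector("list", n)
  for (i in seq_len(n)) {
    k <- operator@kernels[[i]]
    # EBImage::filter2 flips the kernel (convolution); pass it rotated to
    # obtain the correlation sum_t I(y + t) k(t).
    kc <- k[rev(seq_len(nrow(k))), rev(seq_len(ncol(k))), drop = FALSE]
    conv <- EBImage::filter2(padded, kc, boundary = "circular")
    u <- offs[i, ]
    s <- conv[pad + u[1L] + seq_len(dmp[1L]),
              pad + u[2L] + seq_len(dmp[2L]), , drop = FALSE]
    stack[[i]] <- aperm(array(s, dmp), order(perm))
  }
  stack
}

# d_FOV volume for a (3-component, integer) search offset r: per voxel x,
# sum_u (stack_u[x] - stack_u[fold(x + r)])^2. Mirror-folded fixation.
.dfovVolume <- function(stack, r) {
  acc <- 0
  for (s in stack) {
    d <- s - shiftMirror(s, r)
    acc <- acc + d * d
  }
  acc
}

# Foveated variance volume: mean of d_FOV over the in-plane patch offsets.
.varianceVolume <- function(stack, operator, planeAxis = 3L) {
  ax <- .planeAxes(planeAxis)
  offs <- operator@offsets
  acc <- 0
  for (i in seq_len(nrow(offs))) {
    m3 <- c(0L, 0L, 0L)
    m3[ax] <- offs[i, ]
    acc <- acc + .dfovVolume(stack, m3)
  }
  acc / nrow(offs)
}
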