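#' Specify a synthetic multi-modal registration case
#'
#' Desk-scale stand-in for clinical evaluation data: a smooth blob phantom
#' plays the reference anatomy, a nonlinear intensity remapping plus noise
#' produces the second "modality", and a linear combination of Gaussian
#' radial basis functions supplies a smooth ground-truth deformation whose
#' peak magnitude is \code{amplitude} voxels.
#'
#' Defaults: a 64-cubed volume with 30 structures, the contrast-inverting
#' remap (the archetypal multi-modal relationship, e.g. T1 versus T2
#' weighting) with modality-specific noise sd 0.02, 8 RBF centres of width
#' 16 voxels (about twice the default FFD grid spacing, so the deformation
#' model can represent the warp), amplitude 4 voxels and 30 landmarks.
#'
#' @param shape integer(3) volume dimensions.
#' @param nBlobs phantom structure count.
#' @param remapMode \code{"identity"}, \code{"invert"}, \code{"gamma"} or
#'   \code{"nonmonotone-bands"}.
#' @param noiseSigma additive Gaussian noise sd (intensity units).
#' @param nCenters RBF count.
#' @param amplitude maximum displacement magnitude in voxels (>= 0).
#' @param rbfSigma RBF width in voxels.
#' @param nLandmarks automatic landmark count.
#' @param seed RNG seed.
#' @return a [SyntheticSpec-class].
#' @export
syntheticSpec <- function(shape = c(64L, 64L, 64L), nBlobs = 30L,
                          remapMode = "invert",
                          noiseSigma = 0.02, nCenters = 8L, amplitude = 4,
                          rbfSigma = 16, nLandmarks = 30L, seed = 1L) {
  new("SyntheticSpec", shape = as.integer(shape), nBlobs = as.integer(nBlobs),
      remapMode = remapMode, noiseSigma = noiseSigma,
      nCenters = as.integer(nCenters), amplitude = amplitude,
      rbfSigma = rbfSigma, nLandmarks = as.integer(nLandmarks),
      seed = as.integer(seed))
}

#' Generate a structured blob phantom
#'
#' A set of randomly placed ellipsoidal structures with smooth sigmoid
#' edges (transition width about 1.5 voxels, emulating tissue boundaries)
#' over a low uniform background, rescaled to [0, 1]. Later structures
#' overwrite earlier ones where they overlap, producing the nested,
#' piecewise-homogeneous intensity layout typical of anatomical images —
#' the kind of edge structure self-similarity descriptors key on.
#' Deterministic for a fixed seed; the caller's RNG state is untouched.
#'
#' @param shape integer(3) volume dimensions.
#' @param nBlobs number of structures (0 gives the constant background).
#' @param seed RNG seed.
#' @param background background level before rescaling.
#' @param edgeWidth boundary transition width in voxels.
#' @param textureAmp amplitude of the band-limited intensity texture
#'   superimposed on all tissue (0 disables it).
#' @param textureScale correlation length of the coarse texture in voxels.
#' @param fineTextureAmp amplitude of the voxel-scale texture component
#'   (uncorrelated heterogeneity shared by both modalities, the fine
#'   anatomical detail self-similarity descriptors respond to).
#' @return 3D numeric array in [0, 1].
#' @export
makePhantom <- function(shape = c(64L, 64L, 64L), nBlobs = 12L, seed = 1L,
                        background = 0.1, edgeWidth = 1.5,
                        textureAmp = 0.15, textureScale = 1.5,
                        fineTextureAmp = 0.12) {
  shape <- as.integer(shape)
  withSeed(seed, {
    vol <- array(background, shape)
    if (nBlobs >= 1L) {
      ax <- lapply(shape, function(n) seq_len(n))
      for (b in seq_len(nBlobs)) {
        ctr <- stats::runif(3, 0.15, 0.85) * shape
        semi <- stats::runif(3, 0.08, 0.2) * shape
        amp <- stats::runif(1, 0.25, 1)
        q2 <- outer(outer((ax[[1L]] - ctr[1L])^2 / semi[1L]^2,
                          (ax[[2L]] - ctr[2L])^2 / semi[2L]^2, "+"),
                    (ax[[3L]] - ctr[3L])^2 / semi[3L]^2, "+")
        # signed distance to the ellipsoid surface, approximately in voxels
        sd <- (sqrt(q2) - 1) * mean(semi)
        inside <- 1 / (1 + exp(sd / (edgeWidth / 2)))
        vol <- vol * (1 - inside) + amp * inside
      }
      if (textureAmp > 0) {
        # tissue heterogeneity: correlated random field, like the intensity
        # texture self-similarity descriptors respond to in real scans
        tex <- array(stats::rnorm(prod(shape)), shape)
        tex <- .gaussBlur3(tex, textureScale)
        vol <- vol + textureAmp * tex / stats::sd(tex)
      }
      if (fineTextureAmp > 0)
        vol <- vol + array(stats::rnorm(prod(shape), 0, fineTextureAmp),
                           shape)
      vol <- rescale01(vol)
    }
    vol
  })
}

# Separable 3D Gaussian blur with mirror boundary (small direct kernels).
.gaussBlur3 <- function(vol, sigma) {
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-rad:rad)^2 / (2 * sigma^2))
  k <- k / sum(k)
  for (a in 1:3) {
    acc <- 0
    d <- c(0L, 0L, 0L)
    for (i in seq_along(k)) {
      d[a] <- i - rad - 1L
      acc <- acc + k[i] * shiftMirror(vol, d)
    }
    vol <- acc
  }
  vol
}

# Fixed non-monotone transfer function: the unit interval is split into
# four bands which are permuted and alternately reversed, so intensity
# order is destroyed while band identity (structure) is preserved.
.bandRemap <- function(v) {
  b <- pmin(floor(v * 4), 3)
  frac <- v * 4 - b
  base <- c(0.75, 0.00, 0.50, 0.25)[b + 1]
  sgn <- c(1, -1, 1, -1)[b + 1]
  base + ifelse(sgn > 0, frac, 1 - frac) * 0.25
}

#' Create the second "modality" of a phantom
#'
#' Applies a voxelwise intensity transfer function and additive Gaussian
#' noise, then clips to [0, 1]. \code{"invert"} maps v to 1 - v;
#' \code{"gamma"} applies v^0.4; \code{"nonmonotone-bands"} permutes and
#' alternately reverses four intensity bands, emulating the complicated,
#' non-functional intensity relationships of genuinely multi-modal
#' acquisitions.
#'
#' @param volume 3D array with values in [0, 1].
#' @param remapMode transfer function name.
#' @param noiseSigma additive Gaussian noise sd.
#' @param seed RNG seed for the noise.
#' @return remapped 3D array in [0, 1].
#' @export
remapModality <- function(volume, remapMode = "nonmonotone-bands",
                          noiseSigma = 0.02, seed = 1L) {
  if (min(volume) < -1e-9 || max(volume) > 1 + 1e-9)
    stop("volume must be scaled to [0, 1]")
  out <- switch(remapMode,
    "identity" = volume,
    "invert" = 1 - volume,
    "gamma" = volume^0.4,
    "nonmonotone-bands" = array(.bandRemap(as.vector(volume)), dim(volume)),
    stop("unknown remap mode: ", remapMode))
  if (noiseSigma > 0) {
    out <- withSeed(seed,
      out + array(stats::rnorm(length(out), 0, noiseSigma), dim(out)))
  }
  array(pmin(pmax(out, 0), 1), dim(volume))
}

#' Sample a smooth ground-truth deformation from Gaussian RBFs
#'
#' Each displacement component is a linear combination
#' \eqn{\sum_k w_k \exp(-\|x - c_k\|^2 / (2\sigma^2))} with random centres
#' and standard-normal weights, globally scaled so the maximum
#' displacement magnitude over the volume equals \code{amplitude}
#' exactly (zero amplitude gives the identity field).
#'
#' @param shape integer(3) volume dimensions.
#' @param nCenters number of RBF centres.
#' @param amplitude peak displacement magnitude in voxels.
#' @param rbfSigma RBF width in voxels.
#' @param seed RNG seed.
#' @param details return the centres, weights and global scale alongside
#'   the field (for inspection).
#' @return a [DeformationField-class], or a list with elements
#'   \code{field}, \code{centers}, \code{weights}, \code{scale} when
#'   \code{details = TRUE}.
#' @export
sampleRBFDeformation <- function(shape = c(64L, 64L, 64L), nCenters = 8L,
                                 amplitude = 4, rbfSigma = 16, seed = 1L,
                                 details = FALSE) {
  shape <- as.integer(shape)
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (amplitude == 0) {
    fld <- identityField(shape)
    if (details)
      return(list(field = fld, centers = matrix(numeric(0), 0, 3),
                  weights = matrix(numeric(0), 0, 3), scale = 0))
    return(fld)
  }
  withSeed(seed, {
    centers <- matrix(stats::runif(3L * nCenters, 0.1, 0.9), ncol = 3L) *
      matrix(shape, nCenters, 3L, byrow = TRUE)
    weights <- matrix(stats::rnorm(3L * nCenters), ncol = 3L)
    comp <- lapply(1:3, function(c) array(0, shape))
    ax <- lapply(shape, seq_len)
    for (k in seq_len(nCenters)) {
      gx <- exp(-(ax[[1L]] - centers[k, 1L])^2 / (2 * rbfSigma^2))
      gy <- exp(-(ax[[2L]] - centers[k, 2L])^2 / (2 * rbfSigma^2))
      gz <- exp(-(ax[[3L]] - centers[k, 3L])^2 / (2 * rbfSigma^2))
      basis <- outer(outer(gx, gy), gz)
      for (c in 1:3) comp[[c]] <- comp[[c]] + weights[k, c] * basis
    }
    mag <- sqrt(comp[[1L]]^2 + comp[[2L]]^2 + comp[[3L]]^2)
    scale <- amplitude / max(mag)
    out <- array(0, c(shape, 3L))
    for (c in 1:3) out[, , , c] <- comp[[c]] * scale
    fld <- new("DeformationField", displacements = out)
    if (details)
      list(field = fld, centers = centers, weights = weights, scale = scale)
    else fld
  })
}

#' Automatically pick salient landmarks
#'
#' Emulates manual landmark selection: candidate voxels are those whose
#' gradient magnitude (central differences) reaches the volume's top
#' decile and that keep a margin from the faces; \code{n} of them are
#' drawn in a seed-determined order subject to a minimum mutual distance.
#'
#' @param volume 3D numeric array.
#' @param n number of landmarks.
#' @param seed RNG seed.
#' @param minDist minimum pairwise Euclidean distance in voxels.
#' @param margin minimum distance from the volume faces in voxels.
#' @return a [LandmarkSet-class] (1-based voxel coordinates).
#' @export
pickLandmarks <- function(volume, n = 30L, seed = 1L, minDist = 4,
                          margin = 3L) {
  dm <- dim(volume)
  if (n < 1L) stop("n must be >= 1")
  gm <- .gradientMagnitude(volume)
  thr <- stats::quantile(gm, 0.9, names = FALSE)
  cand <- which(gm >= thr)
  cpos <- arrayInd(cand, dm)
  inside <- cpos[, 1L] > margin & cpos[, 1L] <= dm[1L] - margin &
            cpos[, 2L] > margin & cpos[, 2L] <= dm[2L] - margin &
            cpos[, 3L] > margin & cpos[, 3L] <= dm[3L] - margin
  cpos <- cpos[inside, , drop = FALSE]
  if (nrow(cpos) < n) stop("not enough salient candidate voxels")
  withSeed(seed, {
    ord <- sample.int(nrow(cpos))
    chosen <- matrix(numeric(0), 0, 3)
    for (i in ord) {
      p <- cpos[i, ]
      if (nrow(chosen) == 0L ||
          min(sqrt(rowSums(sweep(chosen, 2L, p)^2))) >= minDist) {
        chosen <- rbind(chosen, p)
        if (nrow(chosen) == n) break
      }
    }
    if (nrow(chosen) < n)
      stop("could not place ", n, " landmarks at minimum distance ", minDist)
    new("LandmarkSet", points = unname(chosen))
  })
}

.gradientMagnitude <- function(vol) {
  dm <- dim(vol)
  g2 <- 0
  for (a in 1:3) {
    d <- c(0L, 0L, 0L); d[a] <- 1L
    g <- (shiftMirror(vol, d) - shiftMirror(vol, -d)) / 2
    g2 <- g2 + g^2
  }
  sqrt(g2)
}

#' Build a complete synthetic registration case
#'
#' Draws the phantom, the ground-truth RBF field and the landmarks, and
#' assembles the multi-modal pair so that the ground truth is exactly the
#' field the registration should estimate: the \emph{reference} is the
#' phantom pulled through the true field, and the \emph{float} is the
#' intensity-remapped (other-modality) phantom. Pulling the float through
#' the true field then reproduces the reference's geometry voxel for
#' voxel, so \code{TRE(truth, estimate)} genuinely measures registration
#' error and the unregistered TRE is the mean true displacement magnitude
#' at the landmarks.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with \code{reference}, \code{float} (3D arrays),
#'   \code{trueField} ([DeformationField-class]), \code{landmarks}
#'   ([LandmarkSet-class]) and \code{spec}.
#' @examples
#' case <- simulateCase(syntheticSpec(shape = c(24, 24, 24), seed = 7))
#' dim(case$reference)
#' @export
simulateCase <- function(spec = syntheticSpec()) {
  base <- makePhantom(spec@shape, spec@nBlobs, seed = spec@seed)
  flt <- remapModality(base, spec@remapMode, spec@noiseSigma,
                       seed = spec@seed + 1L)
  tl <- sampleRBFDeformation(spec@shape, spec@nCenters, spec@amplitude,
                             spec@rbfSigma, seed = spec@seed + 2L)
  ref <- warpVolume(base, tl)
  lm <- pickLandmarks(ref, spec@nLandmarks, seed = spec@seed + 3L)
  list(reference = ref, float = flt, trueField = tl, landmarks = lm,
       spec = spec)
}
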