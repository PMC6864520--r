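test_that("phantoms are deterministic, bounded and structured", {
  p1 <- makePhantom(c(16, 16, 16), nBlobs = 5, seed = 7)
  p2 <- makePhantom(c(16, 16, 16), nBlobs = 5, seed = 7)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  p3 <- makePhantom(c(16, 16, 16), nBlobs = 5, seed = 8)
  expect_false(identical(p1, p3))

  flat <- makePhantom(c(12, 12, 12), nBlobs = 0, seed = 1)
  expect_identical(length(unique(as.vector(flat))), 1L)

  # gradient magnitude positive somewhere for a structured phantom
  g <- fmindreg:::.gradientMagnitude(p1)
  expect_gt(max(g), 0)
})

test_that("phantom generation leaves the caller's RNG state alone", {
  set.seed(123)
  before <- .Random.seed
  makePhantom(c(8, 8, 8), nBlobs = 2, seed = 55)
  expect_identical(.Random.seed, before)
})

test_that("modality remaps apply their transfer functions exactly", {
  v <- makePhantom(c(12, 12, 12), nBlobs = 4, seed = 2)
  expect_identical(remapModality(v, "identity", noiseSigma = 0), v)
  expect_equal(remapModality(v, "invert", noiseSigma = 0), 1 - v)
  expect_equal(remapModality(v, "gamma", noiseSigma = 0), v^0.4)
  expect_error(remapModality(v, "sepia"), "unknown remap mode")
  expect_error(remapModality(v * 3, "invert"), "scaled")

  # band remap: voxelwise oracle of the piecewise transfer function
  bands <- remapModality(v, "nonmonotone-bands", noiseSigma = 0)
  oracle <- vapply(as.vector(v), function(x) {
    b <- min(floor(x * 4), 3)
    fr <- x * 4 - b
    base <- c(0.75, 0.00, 0.50, 0.25)[b + 1]
    if (b %% 2 == 0) base + fr * 0.25 else base + (1 - fr) * 0.25
  }, numeric(1))
  expect_equal(as.vector(bands), oracle, tolerance = 1e-12)

  noisy <- remapModality(v, "invert", noiseSigma = 0.1, seed = 4)
  expect_true(all(noisy >= 0 & noisy <= 1))
  expect_false(identical(noisy, 1 - v))
  expect_identical(noisy, remapModality(v, "invert", noiseSigma = 0.1,
                                        seed = 4))
})

test_that("RBF deformations scale exactly to the requested amplitude", {
  f0 <- sampleRBFDeformation(c(16, 16, 16), amplitude = 0, seed = 1)
  expect_true(all(displacements(f0) == 0))

  f <- sampleRBFDeformation(c(16, 16, 16), nCenters = 4, amplitude = 3,
                            rbfSigma = 6, seed = 5)
  d <- displacements(f)
  mag <- sqrt(d[, , , 1]^2 + d[, , , 2]^2 + d[, , , 3]^2)
  expect_equal(max(mag), 3, tolerance = 1e-6)
  expect_identical(
    displacements(sampleRBFDeformation(c(16, 16, 16), nCenters = 4,
                                       amplitude = 3, rbfSigma = 6,
                                       seed = 5)), d)
})

test_that("RBF field values equal the explicit radial-basis sum", {
  det <- sampleRBFDeformation(c(12, 12, 12), nCenters = 3, amplitude = 2,
                              rbfSigma = 5, seed = 9, details = TRUE)
  d <- displacements(det$field)
  for (probe in list(c(3, 7, 5), c(10, 2, 11))) {
    for (cpt in 1:3) {
      val <- 0
      for (k in 1:3) {
        r2 <- sum((probe - det$centers[k, ])^2)
        val <- val + det$weights[k, cpt] * exp(-r2 / (2 * 5^2))
      }
      expect_equal(d[probe[1], probe[2], probe[3], cpt], val * det$scale,
                   tolerance = 1e-10)
    }
  }
})

test_that("landmarks are salient, separated and reproducible", {
  ph <- makePhantom(c(24, 24, 24), nBlobs = 8, seed = 3)
  lm <- pickLandmarks(ph, n = 10, seed = 2, minDist = 4)
  pts <- landmarkPoints(lm)
  expect_identical(nrow(pts), 10L)
  expect_true(all(pts >= 1 & sweep(pts, 2, dim(ph), "<=")))
  dmat <- as.matrix(stats::dist(pts))
  expect_gte(min(dmat[upper.tri(dmat)]), 4)
  # saliency: gradient magnitudes reach the volume's top decile
  g <- fmindreg:::.gradientMagnitude(ph)
  thr <- stats::quantile(g, 0.9, names = FALSE)
  expect_true(all(g[pts] >= thr))
  expect_identical(landmarkPoints(pickLandmarks(ph, n = 10, seed = 2,
                                                minDist = 4)), pts)
  lone <- pickLandmarks(ph, n = 1, seed = 1)
  expect_identical(nrow(landmarkPoints(lone)), 1L)
  expect_error(pickLandmarks(ph, n = 5000, seed = 1), "not enough|could not")
})

test_that("simulateCase assembles a reproducible multi-modal pair", {
  spec <- syntheticSpec(shape = c(16L, 16L, 16L), nBlobs = 5, amplitude = 2,
                        rbfSigma = 6, nLandmarks = 5, seed = 13)
  c1 <- simulateCase(spec)
  c2 <- simulateCase(spec)
  expect_identical(c1$reference, c2$reference)
  expect_identical(c1$float, c2$float)
  expect_identical(displacements(c1$trueField), displacements(c2$trueField))
  expect_identical(landmarkPoints(c1$landmarks), landmarkPoints(c2$landmarks))
  expect_identical(dim(c1$reference), c(16L, 16L, 16L))
  # pulling the float through the true field aligns it with the reference
  # geometry: the reference is the phantom pulled through that same field
  base <- makePhantom(spec@shape, spec@nBlobs, seed = spec@seed)
  expect_identical(c1$reference, warpVolume(base, c1$trueField))
})
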