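# Discrete covariance of a kernel: principal axis angle and std ratio.
kernelMoments <- function(k) {
  rad <- attr(k, "radius")
  tt <- -rad:rad
  X <- matrix(rep(tt, times = length(tt)), length(tt))
  Y <- t(X)
  mx <- sum(X * k); my <- sum(Y * k)
  cxx <- sum((X - mx)^2 * k)
  cyy <- sum((Y - my)^2 * k)
  cxy <- sum((X - mx) * (Y - my) * k)
  eg <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2L))
  list(stdRatio = sqrt(eg$values[1L] / eg$values[2L]),
       angle = atan2(eg$vectors[2L, 1L], eg$vectors[1L, 1L]))
}

angDiff <- function(a, b) {
  d <- abs(a - b) %% pi          # axes are orientation-free
  min(d, pi - d) * 180 / pi
}

test_that("operator construction validates its arguments", {
  expect_error(buildFoveationOperator(c(4, 5)), "odd")
  expect_error(buildFoveationOperator(c(5, 5), rho = 0), "positive")
  expect_error(buildFoveationOperator(c(5, 5), rho = -1), "positive")
  expect_error(buildFoveationOperator(c(-5, 5)), "odd")
})

test_that("kernels are normalised, nonnegative and delta-like at the centre", {
  op <- buildFoveationOperator(c(5, 5), rho = 2, theta = 0)
  sums <- vapply(seq_len(nrow(patchOffsets(op))), function(i)
    sum(kernelAt(op, patchOffsets(op)[i, ])), numeric(1))
  expect_true(all(abs(sums - 1) < 1e-12))
  k0 <- kernelAt(op, c(0, 0))
  rad <- attr(k0, "radius")
  expect_gte(k0[rad + 1, rad + 1], 0.99)
  expect_true(all(vapply(op@kernels, min, numeric(1)) >= 0))
})

test_that("peripheral kernels align radially with the prescribed elongation", {
  op <- buildFoveationOperator(c(7, 7), rho = 2, theta = 0)
  offs <- patchOffsets(op)
  for (i in seq_len(nrow(offs))) {
    u <- offs[i, ]
    if (all(u == 0)) next
    m <- kernelMoments(kernelAt(op, u))
    expect_lt(abs(m$stdRatio - 2) / 2, 0.10)
    expect_lt(angDiff(m$angle, atan2(u[2L], u[1L])), 5)
  }
  # u = (3, 0): horizontal major axis, ratio ~ rho
  m <- kernelMoments(kernelAt(op, c(3, 0)))
  expect_lt(angDiff(m$angle, 0), 5)
  expect_lt(abs(m$stdRatio - 2) / 2, 0.10)
})

test_that("theta rotates the kernel axes", {
  op <- buildFoveationOperator(c(5, 5), rho = 2, theta = pi / 4)
  m <- kernelMoments(kernelAt(op, c(2, 0)))
  expect_lt(angDiff(m$angle, pi / 4), 5)
})

test_that("rho = 1 gives isotropic kernels invariant under 90-degree rotation", {
  op <- buildFoveationOperator(c(5, 5), rho = 1, theta = 0)
  offs <- patchOffsets(op)
  for (i in seq_len(nrow(offs))) {
    u <- offs[i, ]
    if (all(u == 0)) next
    m <- kernelMoments(kernelAt(op, u))
    expect_lt(abs(m$stdRatio - 1), 0.01)
    # rotating the offset by 90 degrees rotates the kernel
    rotU <- c(-u[2L], u[1L])
    k <- kernelAt(op, u)
    kr <- kernelAt(op, rotU)
    krBack <- t(kr)[, rev(seq_len(ncol(kr))), drop = FALSE]  # rotate -90
    expect_lt(max(abs(k - krBack)), 1e-10)
  }
})

test_that("kernel spread is non-decreasing with offset radius", {
  op <- buildFoveationOperator(c(7, 7), rho = 2)
  offs <- patchOffsets(op)
  rads <- sqrt(rowSums(offs^2))
  spread <- vapply(seq_len(nrow(offs)), function(i) {
    k <- kernelAt(op, offs[i, ])
    rad <- attr(k, "radius")
    tt <- -rad:rad
    X <- matrix(rep(tt, times = length(tt)), length(tt))
    sum(X^2 * k) + sum(t(X)^2 * k)   # trace of second moment
  }, numeric(1))
  ord <- order(rads)
  expect_true(all(diff(spread[ord])[diff(rads[ord]) > 1e-9] > -1e-9))
})

test_that("foveating a constant image reproduces the constant", {
  op <- buildFoveationOperator()
  p <- foveatePatch(array(3.3, c(8, 8, 4)), c(4, 4, 2), op)
  expect_equal(max(abs(p@values - 3.3)), 0, tolerance = 1e-12)
})

test_that("an impulse image reads back the central kernel weight", {
  op <- buildFoveationOperator()
  img <- array(0, c(9, 9, 3))
  img[5, 5, 2] <- 1
  p <- foveatePatch(img, c(5, 5, 2), op)
  k0 <- kernelAt(op, c(0, 0))
  rad <- attr(k0, "radius")
  h <- (op@patchShape[1L] - 1L) %/% 2L
  expect_equal(p@values[h + 1, h + 1], k0[rad + 1, rad + 1],
               tolerance = 1e-12)
})

test_that("foveatePatch matches the literal foveation sum", {
  op <- buildFoveationOperator(c(5, 5), rho = 2)
  img <- randomVolume(c(10, 9, 4), seed = 3)
  for (x in list(c(5, 5, 2), c(1, 1, 1), c(10, 9, 4), c(2, 8, 3))) {
    got <- as.vector(foveatePatch(img, x, op)@values)
    expect_equal(got, oracleFoveate(img, x, op), tolerance = 1e-10)
  }
  # non-default patch plane
  got <- as.vector(foveatePatch(img, c(5, 4, 2), op, planeAxis = 1L)@values)
  expect_equal(got, oracleFoveate(img, c(5, 4, 2), op, planeAxis = 1L),
               tolerance = 1e-10)
})

test_that("out-of-volume fixation points are rejected", {
  op <- buildFoveationOperator()
  img <- randomVolume(c(8, 8, 4))
  expect_error(foveatePatch(img, c(0, 4, 2), op), "outside")
  expect_error(foveatedDistance(img, c(1, 1, 1), c(9, 1, 1), op), "outside")
  expect_error(foveatedVariance(img, c(4, 4, 5), op), "outside")
})

test_that("foveated distance is a symmetric squared patch distance", {
  op <- buildFoveationOperator()
  img <- randomVolume(c(16, 16, 4), seed = 7)
  expect_identical(foveatedDistance(img, c(5, 5, 2), c(5, 5, 2), op), 0)
  withr::with_seed(8, {
    for (i in 1:50) {
      x1 <- c(sample(16, 1), sample(16, 1), sample(4, 1))
      x2 <- c(sample(16, 1), sample(16, 1), sample(4, 1))
      expect_equal(foveatedDistance(img, x1, x2, op),
                   foveatedDistance(img, x2, x1, op))
    }
  })
  # checkerboard, against the naive patch-difference norm
  chk <- array(0, c(8, 8, 1))
  chk[] <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  d <- foveatedDistance(chk, c(3, 3, 1), c(4, 3, 1), op)
  ref <- sum((oracleFoveate(chk, c(3, 3, 1), op) -
              oracleFoveate(chk, c(4, 3, 1), op))^2)
  expect_equal(d, ref, tolerance = 1e-10)
  expect_gt(d, 0)
})

test_that("foveated variance floors, scales quadratically and matches Eq-style mean", {
  op <- buildFoveationOperator()
  const <- array(2, c(8, 8, 3))
  expect_equal(foveatedVariance(const, c(4, 4, 2), op, floor = 1e-6), 1e-6)
  img <- randomVolume(c(12, 12, 3), seed = 5)
  v1 <- foveatedVariance(img, c(6, 6, 2), op, floor = 0)
  v3 <- foveatedVariance(3 * img, c(6, 6, 2), op, floor = 0)
  expect_equal(v3, 9 * v1, tolerance = 1e-10)
  # literal mean of |S| foveated distances with folded fixation points
  dm <- dim(img)
  x <- c(6, 6, 2)
  offs <- patchOffsets(op)
  ds <- vapply(seq_len(nrow(offs)), function(i) {
    x2 <- foldPoint(x + c(offs[i, ], 0L), dm)
    foveatedDistance(img, x, x2, op)
  }, numeric(1))
  expect_equal(v1, mean(ds), tolerance = 1e-10)
})
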