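test_that("control grid dimensions include the B-spline margin ring", {
  expect_identical(gridDims(makeControlGrid(c(64, 64, 64), 8)),
                   c(11L, 11L, 11L))
  expect_identical(gridDims(makeControlGrid(c(20, 30, 10), 10)),
                   c(5L, 6L, 4L))
  expect_error(makeControlGrid(c(16, 16, 16), 1), "at least 2")
  # degenerate volume still yields a valid minimal grid
  g1 <- makeControlGrid(c(1, 1, 1), 8)
  expect_true(all(gridDims(g1) >= 2L))
  expect_equal(max(abs(displacements(densify(g1)))), 0)
})

test_that("densify reproduces constants (partition of unity)", {
  g <- makeControlGrid(c(16, 12, 10), 4)
  expect_true(all(displacements(densify(g)) == 0))
  d <- displacements(g)
  d[, , , 1] <- 2.5; d[, , , 2] <- -1; d[, , , 3] <- 0.25
  g@displacements <- d
  f <- displacements(densify(g))
  expect_lt(max(abs(f[, , , 1] - 2.5)), 1e-12)
  expect_lt(max(abs(f[, , , 2] + 1)), 1e-12)
  expect_lt(max(abs(f[, , , 3] - 0.25)), 1e-12)
})

test_that("densify equals direct tensor-product basis evaluation", {
  g <- makeControlGrid(c(14, 12, 10), 4)
  d <- displacements(g)
  d[4, 3, 3, ] <- c(1.5, -2, 0.5)   # single displaced vertex
  g@displacements <- d
  f <- displacements(densify(g))
  withr::with_seed(11, {
    for (i in 1:10) {
      v <- c(sample(14, 1), sample(12, 1), sample(10, 1))
      expect_equal(f[v[1], v[2], v[3], ], oracleBsplineAt(g, v),
                   tolerance = 1e-10)
    }
  })
  # and for a fully random grid, including voxels on cell boundaries
  d[] <- withr::with_seed(12, stats::runif(length(d), -1, 1))
  g@displacements <- d
  f <- displacements(densify(g))
  for (v in list(c(1, 1, 1), c(5, 5, 5), c(4, 8, 9), c(14, 12, 10)))
    expect_equal(f[v[1], v[2], v[3], ], oracleBsplineAt(g, v),
                 tolerance = 1e-10)
})

test_that("densified fields are C2-smooth across cell boundaries", {
  g <- makeControlGrid(c(32, 8, 8), 4)
  d <- displacements(g)
  d[] <- withr::with_seed(13, stats::runif(length(d), -2, 2))
  g@displacements <- d
  f <- displacements(densify(g))[, 4, 4, 1]
  # third differences ~ f''' stay at the spline's analytic scale
  # (|beta3'''| sums to <= 8 over the active vertices, knot spacing 4);
  # a value or derivative discontinuity would show up at O(max |c|)
  d3 <- diff(f, differences = 3)
  expect_lt(max(abs(d3)), 8 * max(abs(d)) / 4^3 + 1e-9)
})

test_that("warp handles identity, integer shifts and linear volumes", {
  vol <- randomVolume(c(10, 10, 6), 21)
  expect_identical(warpVolume(vol, identityField(dim(vol))), vol)

  imp <- array(0, c(8, 8, 8)); imp[4, 4, 4] <- 1
  shift <- identityField(c(8, 8, 8))
  s <- shift@displacements; s[, , , 3] <- 1
  shift@displacements <- s
  w <- warpVolume(imp, shift)       # w(x) = imp(x + e_z)
  expect_equal(w[4, 4, 3], 1)
  expect_equal(sum(w), 1)

  ramp <- array(0, c(12, 12, 12))
  g <- coordGrids(c(12, 12, 12))
  ramp[] <- 3 * g$x - g$y + 0.25 * g$z
  fld <- identityField(c(12, 12, 12))
  fd <- fld@displacements
  fd[] <- withr::with_seed(22, stats::runif(length(fd), -1.5, 1.5))
  fld@displacements <- fd
  w <- warpVolume(ramp, fld)
  expt <- 3 * (g$x + as.vector(fd[, , , 1])) -
    (g$y + as.vector(fd[, , , 2])) + 0.25 * (g$z + as.vector(fd[, , , 3]))
  interior <- g$x > 2 & g$x < 11 & g$y > 2 & g$y < 11 & g$z > 2 & g$z < 11
  expect_lt(max(abs(as.vector(w) - expt)[interior]), 1e-6)

  expect_error(warpVolume(array(0, c(4, 4, 4)), identityField(c(5, 4, 4))),
               "match")
})

test_that("warping with the zero field first changes nothing", {
  vol <- randomVolume(c(9, 9, 5), 31)
  fld <- identityField(c(9, 9, 5))
  fd <- fld@displacements
  fd[] <- withr::with_seed(32, stats::runif(length(fd), -1, 1))
  fld@displacements <- fd
  expect_identical(warpVolume(warpVolume(vol, identityField(dim(vol))), fld),
                   warpVolume(vol, fld))
})

test_that("dense field variable counts follow 3 * nx * ny * nz", {
  expect_identical(countFieldVariables(c(256, 256, 256)), 50331648)
  expect_identical(countFieldVariables(c(1, 1, 1)), 3)
  expect_identical(countFieldVariables(c(64, 64, 64)), 786432)
  expect_error(countFieldVariables(c(0, 1, 1)), "positive")
})

test_that("field composition and resizing behave at the identity", {
  fld <- identityField(c(8, 8, 8))
  fd <- fld@displacements
  fd[] <- withr::with_seed(33, stats::runif(length(fd), -1, 1))
  fld@displacements <- fd
  z <- identityField(c(8, 8, 8))
  expect_equal(displacements(composeFields(fld, z)), displacements(fld))
  r <- resizeField(fld, c(8, 8, 8))
  expect_equal(displacements(r), displacements(fld), tolerance = 1e-12)
})
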