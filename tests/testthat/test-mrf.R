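test_that("label spaces sample axis-aligned displacements around zero", {
  s <- buildLabelSpace(1, 1)
  expect_identical(nrow(labelMatrix(s)), 7L)
  expect_identical(labelMatrix(s)[1, ], c(0, 0, 0))
  expect_false(anyDuplicated(labelMatrix(s)) > 0)
  s2 <- buildLabelSpace(3, 2)
  expect_identical(nrow(labelMatrix(s2)), 19L)
  expect_equal(max(sqrt(rowSums(labelMatrix(s2)^2))), 6)
  expect_error(buildLabelSpace(0, 1), "maxSteps")
  expect_error(buildLabelSpace(1, 0), "quantum")
})

test_that("smoothness cost is the L1 label distance", {
  expect_identical(smoothCost(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_identical(smoothCost(c(1, 0, 0), c(0, 2, 0)), 3)
  withr::with_seed(40, {
    for (i in 1:20) {
      a <- stats::runif(3, -4, 4); b <- stats::runif(3, -4, 4)
      expect_equal(smoothCost(a, b), smoothCost(b, a))
      expect_gte(smoothCost(a, b), 0)
    }
  })
})

test_that("data cost vanishes for identical images at the zero label", {
  img <- makePhantom(c(12, 12, 12), nBlobs = 3, seed = 2)
  d <- computeFMIND(img)
  g <- makeControlGrid(c(12, 12, 12), 4)
  expect_lt(dataCost(d, d, g, c(3, 3, 3), c(0, 0, 0)), 1e-10)
})

test_that("data cost matches a naive voxel loop on a toy problem", {
  dA <- computeFMIND(randomVolume(c(6, 6, 6), 51))
  dB <- computeFMIND(randomVolume(c(6, 6, 6), 52))
  g <- makeControlGrid(c(6, 6, 6), 3)
  gd <- displacements(g)
  gd[] <- withr::with_seed(53, stats::runif(length(gd), -0.5, 0.5))
  g@displacements <- gd
  for (vtx in list(c(2, 2, 2), c(3, 2, 3))) {
    for (lab in list(c(0, 0, 0), c(1, 0, 0), c(0, -1.5, 0.5))) {
      expect_equal(dataCost(dA, dB, g, vtx, lab),
                   oracleDataCost(dA, dB, g, vtx, lab),
                   tolerance = 1e-10)
    }
  }
})

test_that("data cost prefers the true inverse of a constant shift", {
  ph <- makePhantom(c(16, 16, 16), nBlobs = 4, seed = 3)
  flt <- array(0, dim(ph))
  flt[3:16, , ] <- ph[1:14, , ]      # float shifted +2 along x
  flt[1:2, , ] <- ph[2:1, , ]
  dR <- computeFMIND(ph)
  dF <- computeFMIND(flt)
  g <- makeControlGrid(c(16, 16, 16), 4)
  vtx <- c(3, 3, 3)
  expect_gte(dataCost(dR, dF, g, vtx, c(0, 0, 0)),
             dataCost(dR, dF, g, vtx, c(2, 0, 0)))
})

test_that("the vectorised data-cost table agrees with the per-vertex op", {
  dA <- computeFMIND(randomVolume(c(8, 8, 8), 61))
  dB <- computeFMIND(randomVolume(c(8, 8, 8), 62))
  g <- makeControlGrid(c(8, 8, 8), 4)
  labels <- labelMatrix(buildLabelSpace(1, 1))
  dyn <- c(8L, 14L, 33L)
  tab <- fmindreg:::.dataCostTable(dA, dB, g, labels, dyn)
  for (i in seq_along(dyn)) {
    vtx <- arrayInd(dyn[i], gridDims(g))
    for (l in c(1L, 3L, 6L))
      expect_equal(tab[i, l],
                   dataCost(dA, dB, g, as.integer(vtx), labels[l, ]),
                   tolerance = 1e-10)
  }
})

test_that("optimization is a no-op when every vertex is static", {
  part <- partitionVertices(
    new("SimilarityMap", values = array(0, c(12, 12, 12))),
    makeControlGrid(c(12, 12, 12), 4))
  expect_length(dynamicVertices(part), 0)
  model <- buildEnergyModel(matrix(numeric(0), 0, 7),
                            buildLabelSpace(1, 1), part)
  res <- optimizeLabels(model)
  expect_true(all(res$labeling == 1L))
  expect_length(res$trace, 1L)
  expect_identical(res$energy, 0)
})

test_that("a single dynamic vertex takes its exhaustive local optimum", {
  dims <- c(3L, 3L, 3L)
  part <- new("VertexPartition", staticIdx = setdiff(1:27, 14L),
              dynamicIdx = 14L, gridDims = dims, params = list())
  space <- buildLabelSpace(1, 1)
  lam <- 0.05
  withr::with_seed(70, {
    for (rep in 1:5) {
      costs <- matrix(stats::runif(7), 1, 7)
      model <- buildEnergyModel(costs, space, part, lambda = lam)
      res <- optimizeLabels(model)
      # neighbours are static at zero: local cost is data + 2*lambda*|T_l|
      local <- costs[1, ] + 2 * lam * 6 * rowSums(abs(labelMatrix(space)))
      expect_equal(res$labeling[14L], which.min(local))
    }
  })
})

test_that("expansion reaches the exhaustive minimum on small instances", {
  dims <- c(2L, 2L, 2L)
  part <- new("VertexPartition", staticIdx = integer(0), dynamicIdx = 1:8,
              gridDims = dims, params = list())
  space <- buildLabelSpace(1, 1)
  lam <- 0.01
  withr::with_seed(80, {
    for (rep in 1:3) {
      costs <- matrix(stats::runif(8 * 7), 8, 7)
      model <- buildEnergyModel(costs, space, part, lambda = lam)
      res <- optimizeLabels(model, maxSweeps = 5)
      expect_true(all(diff(res$trace) <= 1e-12))
      emin <- oracleExhaustiveMin(costs, labelMatrix(space), lam, dims)
      expect_lte(res$energy, emin * 2 + 1e-12)
      expect_gte(res$energy, emin - 1e-12)
    }
  })
})

test_that("identical descriptor fields keep the identity labeling at zero energy", {
  img <- makePhantom(c(12, 12, 12), nBlobs = 3, seed = 5)
  d <- computeFMIND(img)
  g <- makeControlGrid(c(12, 12, 12), 4)
  dims <- gridDims(g)
  part <- new("VertexPartition", staticIdx = integer(0),
              dynamicIdx = seq_len(prod(dims)), gridDims = dims,
              params = list())
  space <- buildLabelSpace(1, 1)
  costs <- fmindreg:::.dataCostTable(d, d, g, labelMatrix(space),
                                     part@dynamicIdx)
  model <- buildEnergyModel(costs, space, part)
  res <- optimizeLabels(model)
  expect_true(all(res$labeling == 1L))
  expect_lt(res$energy, 1e-10)
})

test_that("mirrored label costs mirror the solution", {
  dims <- c(2L, 2L, 1L)
  part <- new("VertexPartition", staticIdx = integer(0), dynamicIdx = 1:4,
              gridDims = dims, params = list())
  space <- buildLabelSpace(1, 1)
  # mirror label i: swap +d and -d (rows 2<->3, 4<->5, 6<->7)
  mirror <- c(1L, 3L, 2L, 5L, 4L, 7L, 6L)
  withr::with_seed(90, {
    costs <- matrix(stats::runif(4 * 7), 4, 7)
    m1 <- buildEnergyModel(costs, space, part, lambda = 0.02)
    m2 <- buildEnergyModel(costs[, mirror], space, part, lambda = 0.02)
    r1 <- optimizeLabels(m1, maxSweeps = 5)
    r2 <- optimizeLabels(m2, maxSweeps = 5)
    expect_equal(r1$energy, r2$energy, tolerance = 1e-12)
    expect_identical(mirror[r2$labeling], r1$labeling)
  })
})

test_that("the ICM fallback also minimises monotonically", {
  dims <- c(2L, 2L, 2L)
  part <- new("VertexPartition", staticIdx = integer(0), dynamicIdx = 1:8,
              gridDims = dims, params = list())
  space <- buildLabelSpace(1, 1)
  withr::with_seed(95, {
    costs <- matrix(stats::runif(8 * 7), 8, 7)
    model <- buildEnergyModel(costs, space, part)
    res <- optimizeLabels(model, maxSweeps = 10, solver = "icm")
    expect_true(all(diff(res$trace) <= 1e-12))
    emin <- oracleExhaustiveMin(costs, labelMatrix(space), 0.01, dims)
    expect_lte(res$energy, 2 * emin + 1e-12)
  })
})
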