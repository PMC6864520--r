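#' Construct a registration configuration
#'
#' Defaults follow the method's standard parameterisation: a 5 x 5
#' foveated patch with elongation \code{rho = 2} and \code{theta = 0},
#' smoothness weight \code{lambda = 0.01}, partition parameters
#' \code{rlp = 7}, \code{delta = 0.8}, \code{epsilon = 0.9}. The FFD grid
#' spacing (8 voxels), the label sampling (4 steps of 1 voxel per axis
#' and sign; 5 cycles, the first 3 at the full quantum so moves can
#' compose along all three axes, then halving for sub-voxel refinement)
#' and the 2-level pyramid switch for volumes above 64 voxels per axis
#' are this package's documented choices.
#'
#' @param rho,theta,sigma0,patchShape,planeAxis foveation parameters.
#' @param lambda MRF smoothness weight.
#' @param rlp,delta,epsilon vertex-partition parameters.
#' @param gridSpacing FFD vertex spacing in voxels.
#' @param labelQuantum first-cycle displacement step in voxels.
#' @param labelSteps label steps per axis and sign.
#' @param maxCycles outer label-refinement cycles.
#' @param refineQuantum halve the quantum between cycles.
#' @param quantumHold cycles run at the full quantum before halving
#'   begins (with axis-aligned labels, a second full-range cycle lets a
#'   vertex compose moves along two axes before refinement).
#' @param maxSweeps expansion sweeps per cycle.
#' @param pyramidLevels resolution levels (NA = automatic).
#' @param refreshPartition recompute the partition each cycle.
#' @param solver \code{"expansion"} or \code{"icm"}.
#' @param varianceFloorFactor variance floor relative to the squared
#'   intensity range.
#' @return an [FMINDConfig-class].
#' @export
fmindConfig <- function(rho = 2, theta = 0, sigma0 = 1 / (2 * pi),
                        patchShape = c(5L, 5L), planeAxis = 3L,
                        lambda = 0.01,
                        rlp = 7, delta = 0.8, epsilon = 0.9,
                        gridSpacing = 8,
                        labelQuantum = 1, labelSteps = 4L,
                        maxCycles = 5L, refineQuantum = TRUE,
                        quantumHold = 3L,
                        maxSweeps = 2L,
                        pyramidLevels = NA_integer_,
                        refreshPartition = FALSE,
                        solver = "expansion",
                        varianceFloorFactor = 1e-6) {
  new("FMINDConfig",
      rho = rho, theta = theta, sigma0 = sigma0,
      patchShape = as.integer(patchShape), planeAxis = as.integer(planeAxis),
      lambda = lambda, rlp = rlp, delta = delta, epsilon = epsilon,
      gridSpacing = gridSpacing,
      labelQuantum = labelQuantum, labelSteps = as.integer(labelSteps),
      maxCycles = as.integer(maxCycles), refineQuantum = refineQuantum,
      quantumHold = as.integer(quantumHold),
      maxSweeps = as.integer(maxSweeps),
      pyramidLevels = as.integer(pyramidLevels),
      refreshPartition = refreshPartition,
      solver = solver, varianceFloorFactor = varianceFloorFactor)
}

# Config as a flat named list (reports, (de)serialisation).
.configList <- function(config) {
  sn <- slotNames(config)
  stats::setNames(lapply(sn, function(s) slot(config, s)), sn)
}

#' Register a float volume to a reference volume
#'
#' End-to-end FMIND registration: intensities are rescaled to [0, 1], the
#' FMIND descriptor field of each volume is computed, their SAD_F map
#' partitions the FFD control vertices into static and dynamic sets, and
#' cycles of expansion-move MRF optimisation assign discrete displacement
#' labels to the dynamic vertices (the label quantum optionally halving
#' each cycle). The accumulated vertex displacements are densified into
#' the output deformation field and the float volume is pulled through it.
#'
#' The run is deterministic for fixed inputs and configuration. When every
#' vertex is static (the volumes are already aligned everywhere at the
#' partition's sensitivity) the identity field is returned and the report
#' carries a warning.
#'
#' @param reference,float 3D numeric arrays of identical shape with finite
#'   intensities.
#' @param config an [FMINDConfig-class]; see [fmindConfig()].
#' @return a [RegistrationResult-class]: estimated field, warped float
#'   volume and a report (parameters, partition counts, energy traces,
#'   warnings, timing).
#' @examples
#' \donttest{
#' img <- array(stats::runif(24^3), c(24, 24, 24))
#' res <- registerFMIND(img, img)  # identical images: identity field
#' }
#' @export
registerFMIND <- function(reference, float, config = fmindConfig()) {
  if (!identical(dim(reference), dim(float)))
    stop("reference and float volumes must have the same shape")
  if (length(dim(reference)) != 3L) stop("volumes must be 3D arrays")
  if (any(!is.finite(reference)) || any(!is.finite(float)))
    stop("volumes must have finite intensities")

  levels <- config@pyramidLevels
  if (is.na(levels)) levels <- if (any(dim(reference) > 64L)) 2L else 1L

  t0 <- proc.time()[["elapsed"]]
  if (levels <= 1L) {
    res <- .registerSingleLevel(reference, float, config)
  } else {
    res <- .registerPyramid(reference, float, config, levels)
  }
  res@report$elapsedSeconds <- proc.time()[["elapsed"]] - t0
  res
}

.registerSingleLevel <- function(reference, float, config) {
  dm <- dim(reference)
  refS <- rescale01(reference)
  fltS <- rescale01(float)
  op <- buildFoveationOperator(config@patchShape, config@rho, config@theta,
                               config@sigma0)
  descR <- computeFMIND(refS, op, planeAxis = config@planeAxis,
                        varianceFloor = config@varianceFloorFactor,
                        rescale = FALSE)
  descF <- computeFMIND(fltS, op, planeAxis = config@planeAxis,
                        varianceFloor = config@varianceFloorFactor,
                        rescale = FALSE)
  sim <- similaritySAD(descR, descF)
  grid <- makeControlGrid(dm, config@gridSpacing)
  part <- partitionVertices(sim, grid, config@rlp, config@delta,
                            config@epsilon)

  report <- list(
    parameters = .configList(config),
    partition = list(total = prod(part@gridDims),
                     static = length(part@staticIdx),
                     dynamic = length(part@dynamicIdx)),
    energyTrace = list(),
    warnings = character())

  if (!length(part@dynamicIdx)) {
    report$warnings <- c(report$warnings,
      "all control vertices static; returning the identity transform")
    # energy of the identity labeling: data terms of the (all-static)
    # vertices at zero displacement, averaged over |G|
    idCosts <- .dataCostTable(descR, descF, grid,
                              matrix(0, 1L, 3L),
                              seq_len(prod(grid@dims)),
                              normalize = FALSE)
    report$energy <- sum(idCosts) / prod(grid@dims)
    return(new("RegistrationResult", field = identityField(dm),
               warped = float, report = report))
  }

  quantum <- config@labelQuantum
  for (cycle in seq_len(config@maxCycles)) {
    space <- buildLabelSpace(config@labelSteps, quantum)
    if (config@refreshPartition && cycle > 1L) {
      fld <- densify(grid)
      wFlt <- warpVolume(fltS, fld)
      descW <- computeFMIND(wFlt, op, planeAxis = config@planeAxis,
                            varianceFloor = config@varianceFloorFactor,
                            rescale = FALSE)
      part <- partitionVertices(similaritySAD(descR, descW), grid,
                                config@rlp, config@delta, config@epsilon)
      if (!length(part@dynamicIdx)) break
    }
    costs <- .dataCostTable(descR, descF, grid, space@labels,
                            part@dynamicIdx, normalize = FALSE)
    model <- buildEnergyModel(costs, space, part, config@lambda)
    opt <- optimizeLabels(model, maxSweeps = config@maxSweeps,
                          solver = config@solver)
    report$energyTrace[[cycle]] <- opt$trace
    moved <- space@labels[opt$labeling[part@dynamicIdx], , drop = FALSE]
    disp <- grid@displacements
    for (cpt in 1:3) {
      comp <- array(disp[, , , cpt], grid@dims)
      comp[part@dynamicIdx] <- comp[part@dynamicIdx] + moved[, cpt]
      disp[, , , cpt] <- comp
    }
    grid@displacements <- disp
    if (config@refineQuantum && cycle >= config@quantumHold)
      quantum <- quantum / 2
  }

  field <- densify(grid)
  report$partition$dynamic <- length(part@dynamicIdx)
  report$partition$static <- length(part@staticIdx)
  new("RegistrationResult", field = field,
      warped = warpVolume(float, field), report = report)
}

# Two-level coarse-to-fine wrapper: register block-reduced volumes first,
# pre-warp the float with the upsampled coarse field, refine at full
# resolution, compose.
.registerPyramid <- function(reference, float, config, levels) {
  dm <- dim(reference)
  refC <- .downsample2(reference)
  fltC <- .downsample2(float)
  cfgC <- config
  cfgC@pyramidLevels <- 1L
  resC <- .registerSingleLevel(refC, fltC, cfgC)
  coarseUp <- resizeField(resC@field, dm)
  fltPre <- warpVolume(float, coarseUp)
  resF <- .registerSingleLevel(reference, fltPre, cfgC)
  total <- composeFields(coarseUp, resF@field)
  report <- resF@report
  report$coarseLevel <- resC@report
  new("RegistrationResult", field = total,
      warped = warpVolume(float, total), report = report)
}

# 2x block-mean downsampling (odd trailing voxels are dropped).
.downsample2 <- function(vol) {
  dm <- dim(vol) %/% 2L * 2L
  v <- vol[seq_len(dm[1L]), seq_len(dm[2L]), seq_len(dm[3L]), drop = FALSE]
  h <- dm %/% 2L
  dim(v) <- c(2L, h[1L], 2L, h[2L], 2L, h[3L])
  out <- apply(v, c(2L, 4L, 6L), mean)
  array(out, h)
}

#' Landmark-based target registration error
#'
#' At each landmark the true and estimated displacement vectors are
#' sampled trilinearly and the Euclidean norm of their difference is
#' taken; the summary is the arithmetic mean (and sd) over landmarks.
#' With \code{mode = "composition"} the residual
#' \code{d_est(x) + d_true(x + d_est(x))} is measured instead — the
#' distance by which the composite of the estimated and true warps misses
#' the identity.
#'
#' @param landmarks a [LandmarkSet-class] (1-based voxel coordinates).
#' @param fieldTrue,fieldEst [DeformationField-class] objects of equal
#'   shape containing the ground-truth and estimated displacements.
#' @param voxelSize numeric(3) mm per voxel; the default (1,1,1) reports
#'   the TRE in voxel units.
#' @param mode \code{"displacement"} (default) or \code{"composition"}.
#' @return a [TREResult-class].
#' @examples
#' f <- identityField(c(8, 8, 8))
#' lm <- new("LandmarkSet", points = cbind(4, 4, 4))
#' evaluateTRE(lm, f, f)  # zero error
#' @export
evaluateTRE <- function(landmarks, fieldTrue, fieldEst,
                        voxelSize = c(1, 1, 1),
                        mode = c("displacement", "composition")) {
  mode <- match.arg(mode)
  if (!identical(dim(fieldTrue@displacements),
                 dim(fieldEst@displacements)))
    stop("deformation fields must have the same shape")
  pts <- landmarks@points
  if (nrow(pts) < 1L) stop("landmark set is empty")
  dm <- dim(fieldTrue@displacements)[1:3]
  if (any(pts < 1) || any(sweep(pts, 2L, dm, ">")))
    stop("landmarks must lie inside the field domain")
  sampleField <- function(field, px, py, pz) {
    vapply(1:3, function(cpt)
      sampleTrilinear(array(field@displacements[, , , cpt], dm),
                      px, py, pz),
      numeric(length(px)))
  }
  dT <- sampleField(fieldTrue, pts[, 1L], pts[, 2L], pts[, 3L])
  dE <- sampleField(fieldEst, pts[, 1L], pts[, 2L], pts[, 3L])
  dT <- matrix(dT, nrow(pts)); dE <- matrix(dE, nrow(pts))
  if (mode == "displacement") {
    diff <- dT - dE
  } else {
    warpedPts <- pts + dE
    dTw <- sampleField(fieldTrue, warpedPts[, 1L], warpedPts[, 2L],
                       warpedPts[, 3L])
    diff <- dE + matrix(dTw, nrow(pts))
  }
  diff <- sweep(diff, 2L, voxelSize, "*")
  err <- sqrt(rowSums(diff^2))
  units <- if (all(voxelSize == 1)) "voxels" else "mm"
  new("TREResult", perLandmark = err, mean = mean(err),
      sd = if (length(err) > 1L) stats::sd(err) else 0,
      units = units)
}
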