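#' Build the discrete displacement label space
#'
#' Axis-aligned displacement sampling: the zero vector plus
#' \code{+/- k * quantum} along each axis for \code{k = 1..maxSteps},
#' \code{6*maxSteps + 1} labels in total. Label 1 is always the zero
#' displacement.
#'
#' @param maxSteps integer >= 1, steps per axis and sign.
#' @param quantum positive displacement step in voxels.
#' @return a [LabelSpace-class].
#' @examples
#' nrow(labelMatrix(buildLabelSpace(1, 1)))  # 7
#' @export
buildLabelSpace <- function(maxSteps = 4L, quantum = 1) {
  maxSteps <- as.integer(maxSteps)
  if (is.na(maxSteps) || maxSteps < 1L) stop("maxSteps must be >= 1")
  if (!is.numeric(quantum) || quantum <= 0) stop("quantum must be positive")
  rows <- list(c(0, 0, 0))
  for (k in seq_len(maxSteps)) {
    for (axis in 1:3) {
      for (sgn in c(1, -1)) {
        v <- c(0, 0, 0)
        v[axis] <- sgn * k * quantum
        rows[[length(rows) + 1L]] <- v
      }
    }
  }
  new("LabelSpace", labels = do.call(rbind, rows), quantum = quantum,
      maxSteps = maxSteps)
}

#' Pairwise smoothness cost between two labels
#'
#' The L1 norm of the difference of the two candidate displacements,
#' encouraging neighbouring control vertices to move together.
#'
#' @param labelA,labelB numeric(3) displacement vectors.
#' @return nonnegative scalar.
#' @export
smoothCost <- function(labelA, labelB) sum(abs(labelA - labelB))

# 6-neighbourhood adjacency over a vertex lattice: one row per undirected
# pair of linear (column-major) vertex indices.
.gridEdges <- function(dims) {
  idx <- array(seq_len(prod(dims)), dims)
  e <- list()
  if (dims[1L] > 1L)
    e[[1L]] <- cbind(as.vector(idx[-dims[1L], , ]), as.vector(idx[-1L, , ]))
  if (dims[2L] > 1L)
    e[[2L]] <- cbind(as.vector(idx[, -dims[2L], ]), as.vector(idx[, -1L, ]))
  if (dims[3L] > 1L)
    e[[3L]] <- cbind(as.vector(idx[, , -dims[3L]]), as.vector(idx[, , -1L]))
  do.call(rbind, e)
}

# 0-based voxel box on which vertex t (1-based triple) has B-spline
# support along one axis: X in ((t-4)*sp, t*sp), open.
.vertexSupportRange <- function(t, sp, n) {
  lo <- floor((t - 4) * sp + 1) + 1   # smallest 1-based voxel strictly inside
  hi <- ceiling(t * sp + 1) - 1
  c(max(1, lo), min(n, hi))
}

#' Data cost of one vertex/label pair
#'
#' Discretisation of the data term: the SAD_F between the reference
#' descriptor and the float descriptor resampled through (current field +
#' candidate label displacement), aggregated over the vertex's B-spline
#' support with the vertex's basis value as weight and normalised by the
#' total weight. The candidate displacement is treated as constant over
#' the support (first-order approximation, standard for discrete FFD
#' registration).
#'
#' @param descRef,descFloat [DescriptorField-class] objects on the same
#'   geometry.
#' @param grid a [ControlGrid-class]; its current displacements define the
#'   base field the candidate is added to.
#' @param vertex integer(3), 1-based vertex index triple.
#' @param label numeric(3), candidate displacement in voxels.
#' @return nonnegative scalar.
#' @export
dataCost <- function(descRef, descFloat, grid, vertex, label) {
  dm <- grid@imageDim
  vertex <- as.integer(vertex)
  rx <- .vertexSupportRange(vertex[1L], grid@spacing[1L], dm[1L])
  ry <- .vertexSupportRange(vertex[2L], grid@spacing[2L], dm[2L])
  rz <- .vertexSupportRange(vertex[3L], grid@spacing[3L], dm[3L])
  if (rx[1L] > rx[2L] || ry[1L] > ry[2L] || rz[1L] > rz[2L]) return(0)
  xs <- rx[1L]:rx[2L]; ys <- ry[1L]:ry[2L]; zs <- rz[1L]:rz[2L]
  wx <- bspline3((xs - 1) / grid@spacing[1L] - vertex[1L] + 2)
  wy <- bspline3((ys - 1) / grid@spacing[2L] - vertex[2L] + 2)
  wz <- bspline3((zs - 1) / grid@spacing[3L] - vertex[3L] + 2)
  w <- outer(outer(wx, wy), wz)
  base <- densify(grid)@displacements
  gx <- rep.int(xs, length(ys) * length(zs))
  gy <- rep.int(rep(ys, each = length(xs)), length(zs))
  gz <- rep(zs, each = length(xs) * length(ys))
  cx <- gx + as.vector(base[xs, ys, zs, 1L]) + label[1L]
  cy <- gy + as.vector(base[xs, ys, zs, 2L]) + label[2L]
  cz <- gz + as.vector(base[xs, ys, zs, 3L]) + label[3L]
  nch <- dim(descRef@values)[4L]
  sad <- 0
  for (i in seq_len(nch)) {
    fl <- sampleTrilinear(array(descFloat@values[, , , i], dm), cx, cy, cz)
    sad <- sad + abs(as.vector(descRef@values[xs, ys, zs, i]) - fl)
  }
  sad <- sad / nch
  sum(w * array(sad, dim(w))) / sum(w)
}

# Full data-cost table for all dynamic vertices and all labels, sharing
# the per-label warped similarity volumes. Equivalent to dataCost() per
# vertex but computed with three separable basis contractions per label.
# With normalize = FALSE the basis-weighted sum is returned unnormalised —
# the discretisation of the data term as an integral over the support
# region, the scale on which the default smoothness weight of 0.01 is
# calibrated; the normalised variant is the per-vertex mean SAD.
.dataCostTable <- function(descRef, descFloat, grid, labels, dynamicIdx,
                           baseField = NULL, normalize = TRUE) {
  dm <- grid@imageDim
  if (is.null(baseField)) baseField <- densify(grid)
  g <- coordGrids(dm)
  bx <- g$x + as.vector(baseField@displacements[, , , 1L])
  by <- g$y + as.vector(baseField@displacements[, , , 2L])
  bz <- g$z + as.vector(baseField@displacements[, , , 3L])
  U <- lapply(1:3, function(a)
    Matrix::t(.axisBasisMatrix(dm[a], grid@dims[a], grid@spacing[a])))
  wtot <- .tensorAxis(.tensorAxis(.tensorAxis(
    array(1, dm), U[[1L]], 1L), U[[2L]], 2L), U[[3L]], 3L)
  nch <- dim(descRef@values)[4L]
  floatCh <- lapply(seq_len(nch), function(i)
    array(descFloat@values[, , , i], dm))
  nl <- nrow(labels)
  costs <- matrix(0, length(dynamicIdx), nl)
  for (l in seq_len(nl)) {
    sad <- 0
    for (i in seq_len(nch)) {
      fl <- sampleTrilinear(floatCh[[i]],
                            bx + labels[l, 1L],
                            by + labels[l, 2L],
                            bz + labels[l, 3L])
      sad <- sad + abs(as.vector(descRef@values[, , , i]) - fl)
    }
    M <- array(sad / nch, dm)
    num <- .tensorAxis(.tensorAxis(.tensorAxis(
      M, U[[1L]], 1L), U[[2L]], 2L), U[[3L]], 3L)
    costs[, l] <- if (normalize)
      as.vector(num)[dynamicIdx] / as.vector(wtot)[dynamicIdx]
    else as.vector(num)[dynamicIdx]
  }
  costs
}

#' Assemble a first-order MRF energy model
#'
#' @param dataCosts numeric matrix, dynamic vertices (rows, in
#'   \code{dynamicVertices(partition)} order) by labels (columns).
#' @param labels a [LabelSpace-class] or its label matrix.
#' @param partition a [VertexPartition-class].
#' @param lambda smoothness weight (default 0.01).
#' @param staticCosts optional fixed data terms of the static vertices
#'   (defaults to zeros; a constant offset that never changes the optimum).
#' @return an [EnergyModel-class].
#' @export
buildEnergyModel <- function(dataCosts, labels, partition, lambda = 0.01,
                             staticCosts = NULL) {
  if (is(labels, "LabelSpace")) labels <- labels@labels
  if (is.null(staticCosts)) staticCosts <- numeric(length(partition@staticIdx))
  new("EnergyModel",
      dataCosts = dataCosts, staticCosts = staticCosts, labels = labels,
      lambda = lambda, edges = .gridEdges(partition@gridDims),
      gridDims = partition@gridDims,
      dynamicIdx = partition@dynamicIdx, staticIdx = partition@staticIdx)
}

# Energy of a full labeling (vector over ALL vertices, label indices;
# static vertices must hold label 1). Per the first-order MRF form the
# pairwise sum runs over ordered neighbour pairs, so each undirected edge
# counts twice; the total is normalised by |G|.
.mrfEnergy <- function(model, labeling) {
  nG <- prod(model@gridDims)
  dataTerm <- sum(model@dataCosts[cbind(seq_len(nrow(model@dataCosts)),
                                        labeling[model@dynamicIdx])]) +
    sum(model@staticCosts)
  la <- model@labels[labeling[model@edges[, 1L]], , drop = FALSE]
  lb <- model@labels[labeling[model@edges[, 2L]], , drop = FALSE]
  smoothTerm <- 2 * sum(abs(la - lb))
  (dataTerm + model@lambda * smoothTerm) / nG
}

# One alpha-expansion move solved as a min-cut (igraph max-flow).
# labeling: current label indices over all vertices; returns new labeling.
.expansionMove <- function(model, labeling, alpha) {
  dyn <- model@dynamicIdx
  nd <- length(dyn)
  pos <- integer(prod(model@gridDims)); pos[dyn] <- seq_len(nd)
  lam2 <- 2 * model@lambda
  lab <- model@labels
  alphaVec <- lab[alpha, ]

  # unary costs: cost0 = keep current, cost1 = switch to alpha
  cost0 <- model@dataCosts[cbind(seq_len(nd), labeling[dyn])]
  cost1 <- model@dataCosts[, alpha]

  # accumulate weights onto vertices, summing over repeated indices
  accum <- function(idx, w, n) {
    out <- numeric(n)
    if (length(idx)) {
      s <- rowsum(w, idx)
      out[as.integer(rownames(s))] <- s
    }
    out
  }

  ePairs <- model@edges
  aIsDyn <- pos[ePairs[, 1L]] > 0L
  bIsDyn <- pos[ePairs[, 2L]] > 0L

  # dynamic-static edges fold into the dynamic endpoint's unary costs
  for (side in 1:2) {
    mixed <- which(if (side == 1L) aIsDyn & !bIsDyn else !aIsDyn & bIsDyn)
    if (!length(mixed)) next
    dp <- pos[ePairs[mixed, side]]
    cur <- labeling[ePairs[mixed, side]]
    cost0 <- cost0 +
      accum(dp, lam2 * rowSums(abs(lab[cur, , drop = FALSE])), nd)
    cost1 <- cost1 + accum(dp, rep(lam2 * sum(abs(alphaVec)),
                                   length(dp)), nd)
  }

  both <- which(aIsDyn & bIsDyn)
  pa <- pos[ePairs[both, 1L]]
  pb <- pos[ePairs[both, 2L]]
  curA <- labeling[ePairs[both, 1L]]
  curB <- labeling[ePairs[both, 2L]]
  A <- lam2 * rowSums(abs(lab[curA, , drop = FALSE] -
                          lab[curB, , drop = FALSE]))
  B <- lam2 * rowSums(abs(sweep(lab[curA, , drop = FALSE], 2L, alphaVec)))
  C <- lam2 * rowSums(abs(sweep(lab[curB, , drop = FALSE], 2L, alphaVec,
                                FUN = function(x, y) y - x)))
  # decomposition: E = A + (C-A) x_a + (D-C) x_b + (B+C-A-D)(1-x_a) x_b,
  # D = 0 (both alpha); metric L1 cost guarantees submodularity.
  uA <- C - A
  uB <- -C
  pw <- B + C - A
  if (any(pw < -1e-9)) stop("non-submodular expansion term")
  pw <- pmax(pw, 0)

  # net unary coefficient on x_p; cap(s->p) pays x_p = 1 (switch),
  # cap(p->t) pays x_p = 0 (keep)
  u <- cost1 - cost0
  if (length(both)) u <- u + accum(pa, uA, nd) + accum(pb, uB, nd)
  capS <- pmax(u, 0)
  capT <- pmax(-u, 0)

  s <- nd + 1L; t <- nd + 2L
  from <- c(rep(s, nd), seq_len(nd))
  to <- c(seq_len(nd), rep(t, nd))
  cap <- c(capS, capT)
  if (length(both)) {
    keep <- pw > 0
    from <- c(from, pa[keep])
    to <- c(to, pb[keep])
    cap <- c(cap, pw[keep])
  }
  gr <- igraph::make_empty_graph(n = nd + 2L, directed = TRUE)
  gr <- igraph::add_edges(gr, rbind(from, to))
  mf <- igraph::max_flow(gr, source = s, target = t, capacity = cap)
  switchTo <- setdiff(as.integer(mf$partition2), t)  # sink side: x = 1

  out <- labeling
  out[dyn[switchTo]] <- alpha
  out
}

# ICM fallback / polish: per-vertex exhaustive minimisation with the
# identity-biased tie-break (smaller L1 magnitude, then lower index).
.icmSweep <- function(model, labeling, labelOrder) {
  dyn <- model@dynamicIdx
  lam2 <- 2 * model@lambda
  lab <- model@labels
  nbrs <- .vertexNeighbors(model@gridDims)
  changed <- FALSE
  for (i in seq_along(dyn)) {
    p <- dyn[i]
    nb <- nbrs[[p]]
    nbLab <- lab[labeling[nb], , drop = FALSE]
    best <- labeling[p]; bestCost <- Inf
    for (l in labelOrder) {
      cost <- model@dataCosts[i, l] +
        lam2 * sum(abs(sweep(nbLab, 2L, lab[l, ])))
      if (cost < bestCost - 1e-12) { bestCost <- cost; best <- l }
    }
    if (best != labeling[p]) { labeling[p] <- best; changed <- TRUE }
  }
  attr(labeling, "changed") <- changed
  labeling
}

.vertexNeighbors <- function(dims) {
  e <- .gridEdges(dims)
  n <- prod(dims)
  nbrs <- vector("list", n)
  for (i in seq_len(n)) nbrs[[i]] <- integer(0)
  for (r in seq_len(nrow(e))) {
    a <- e[r, 1L]; b <- e[r, 2L]
    nbrs[[a]] <- c(nbrs[[a]], b)
    nbrs[[b]] <- c(nbrs[[b]], a)
  }
  nbrs
}

#' Minimise the MRF registration energy over dynamic vertices
#'
#' Expansion-move minimisation: labels are visited in order of increasing
#' L1 magnitude (ties by index, biasing toward the identity) and each
#' visit solves a binary min-cut; a move is kept only if it strictly
#' lowers the energy, so the recorded energy trace is non-increasing.
#' Sweeps repeat until no label improves the energy or \code{maxSweeps}
#' is reached. Static vertices stay at the zero label throughout, but
#' edges between static and dynamic vertices remain in the smoothness
#' term so the frozen boundary regularises its neighbours.
#'
#' @param model an [EnergyModel-class].
#' @param maxSweeps maximum full passes over the label set.
#' @param solver \code{"expansion"} (default, max-flow based) or
#'   \code{"icm"} (coordinate descent).
#' @return list with \code{labeling} (label indices over all vertices;
#'   static vertices hold 1), \code{energy} (final value) and
#'   \code{trace} (energy after the initial state and after each
#'   accepted/attempted sweep step).
#' @export
optimizeLabels <- function(model, maxSweeps = 3L,
                           solver = c("expansion", "icm")) {
  solver <- match.arg(solver)
  nG <- prod(model@gridDims)
  labeling <- rep(1L, nG)
  trace <- .mrfEnergy(model, labeling)
  if (!length(model@dynamicIdx))
    return(list(labeling = labeling, energy = trace, trace = trace))

  mags <- rowSums(abs(model@labels))
  labelOrder <- order(mags, seq_len(nrow(model@labels)))

  # second deterministic start: per-vertex data-cost argmin (identity-biased
  # tie-break); sweeps begin from whichever start has lower energy
  greedy <- labeling
  greedy[model@dynamicIdx] <- labelOrder[
    apply(model@dataCosts[, labelOrder, drop = FALSE], 1L, which.min)]
  eGreedy <- .mrfEnergy(model, greedy)
  if (eGreedy < trace[1L] - 1e-12) {
    labeling <- greedy
    trace <- c(trace, eGreedy)
  }

  for (sweep in seq_len(maxSweeps)) {
    improved <- FALSE
    if (solver == "expansion") {
      for (alpha in labelOrder) {
        cand <- .expansionMove(model, labeling, alpha)
        eNew <- .mrfEnergy(model, cand)
        if (eNew < trace[length(trace)] - 1e-12) {
          labeling <- cand
          improved <- TRUE
        }
        trace <- c(trace, min(eNew, trace[length(trace)]))
      }
    } else {
      labeling2 <- .icmSweep(model, labeling, labelOrder)
      eNew <- .mrfEnergy(model, labeling2)
      if (eNew < trace[length(trace)] - 1e-12) {
        labeling <- labeling2
        improved <- TRUE
      }
      trace <- c(trace, min(eNew, trace[length(trace)]))
    }
    if (!improved) break
  }
  list(labeling = labeling, energy = trace[length(trace)], trace = trace)
}
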