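# Independent naive-transcription oracles. These re-derive every quantity
# directly from its defining formula (explicit sums, literal pseudocode
# loops) and deliberately share no code with the package's fast paths.

oracleFold <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  j <- ifelse(j >= n, 2L * n - 1L - j, j)
  j + 1L
}

# Literal foveation sum: value(u) = sum_xi I(xi + x) v_u(xi - u), with the
# patch plane selected by planeAxis and mirror folding of sample indices.
oracleFoveate <- function(image, x, op, planeAxis = 3L) {
  dm <- dim(image)
  ax <- setdiff(1:3, planeAxis)
  offs <- patchOffsets(op)
  vals <- numeric(nrow(offs))
  for (i in seq_len(nrow(offs))) {
    u <- offs[i, ]
    k <- kernelAt(op, u)
    rad <- attr(k, "radius")
    tt <- -rad:rad
    i1 <- oracleFold(x[ax[1L]] + u[1L] + tt, dm[ax[1L]])
    i2 <- oracleFold(x[ax[2L]] + u[2L] + tt, dm[ax[2L]])
    idx <- as.list(x)
    idx[[ax[1L]]] <- i1
    idx[[ax[2L]]] <- i2
    sub <- image[idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE]
    vals[i] <- sum(as.vector(sub) * as.vector(k))
  }
  vals
}

# All foveated patches of a volume, cached: voxels x patch offsets.
oraclePatchCache <- function(image, op, planeAxis = 3L) {
  dm <- dim(image)
  n <- prod(dm)
  offs <- patchOffsets(op)
  P <- matrix(NA_real_, n, nrow(offs))
  for (v in seq_len(n)) {
    x <- arrayInd(v, dm)
    P[v, ] <- oracleFoveate(image, as.integer(x), op, planeAxis)
  }
  P
}

oracleDfovFromCache <- function(P, dm, x1, x2) {
  v1 <- (x1[3L] - 1L) * dm[1L] * dm[2L] + (x1[2L] - 1L) * dm[1L] + x1[1L]
  v2 <- (x2[3L] - 1L) * dm[1L] * dm[2L] + (x2[2L] - 1L) * dm[1L] + x2[1L]
  sum((P[v1, ] - P[v2, ])^2)
}

foldPoint <- function(x, dm) {
  c(oracleFold(x[1L], dm[1L]), oracleFold(x[2L], dm[2L]),
    oracleFold(x[3L], dm[3L]))
}

# Literal per-voxel FMIND: distances, variance (mean over patch offsets,
# floored), exponentials, per-voxel max normalisation. image must already
# be intensity-normalised.
oracleFMIND <- function(image, op, offsets, planeAxis = 3L,
                        varianceFloor = 1e-6) {
  dm <- dim(image)
  ax <- setdiff(1:3, planeAxis)
  P <- oraclePatchCache(image, op, planeAxis)
  pOffs <- patchOffsets(op)
  nr <- nrow(offsets)
  out <- array(NA_real_, c(dm, nr))
  vmap <- array(NA_real_, dm)
  for (v in seq_len(prod(dm))) {
    x <- as.integer(arrayInd(v, dm))
    ds <- numeric(nrow(pOffs))
    for (i in seq_len(nrow(pOffs))) {
      m3 <- c(0L, 0L, 0L)
      m3[ax] <- pOffs[i, ]
      ds[i] <- oracleDfovFromCache(P, dm, x, foldPoint(x + m3, dm))
    }
    V <- max(mean(ds), varianceFloor)
    vmap[v] <- V
    es <- numeric(nr)
    for (i in seq_len(nr))
      es[i] <- exp(-oracleDfovFromCache(P, dm, x, foldPoint(x + offsets[i, ], dm)) / V)
    idx <- cbind(x[1L], x[2L], x[3L], seq_len(nr))
    out[idx] <- es / max(es)
  }
  list(values = out, variance = vmap)
}

oracleSAD <- function(a, b) {
  d <- dim(a)
  acc <- array(0, d[1:3])
  for (i in seq_len(d[4L])) acc <- acc + abs(a[, , , i] - b[, , , i])
  acc / d[4L]
}

# Literal transcription of the vertex-partition pseudocode: triple loop
# over vertices, explicit voxel loop over the local patch.
oraclePartition <- function(simArr, grid, rlp, delta, epsilon) {
  dims <- gridDims(grid)
  dm <- dim(simArr)
  sp <- gridSpacing(grid)
  staticSet <- integer(0)
  for (k in seq_len(dims[3L])) for (j in seq_len(dims[2L]))
    for (i in seq_len(dims[1L])) {
      ctr <- as.integer(round((c(i, j, k) - 2) * sp)) + 1L
      ctr <- pmin(pmax(ctr, 1L), dm)
      lo <- pmax(ctr - rlp, 1L)
      hi <- pmin(ctr + rlp, dm)
      lin <- (k - 1L) * dims[1L] * dims[2L] + (j - 1L) * dims[1L] + i
      con <- 0L
      size <- 0L
      for (zz in lo[3L]:hi[3L]) for (yy in lo[2L]:hi[2L])
        for (xx in lo[1L]:hi[1L]) {
          size <- size + 1L
          if (1 - simArr[xx, yy, zz] > delta) con <- con + 1L
        }
      if (con / size > epsilon) staticSet <- c(staticSet, lin)
    }
  staticSet
}

# Direct cubic B-spline tensor evaluation of a control grid at one voxel.
oracleBsplineAt <- function(grid, voxel) {
  sp <- gridSpacing(grid)
  dims <- gridDims(grid)
  disp <- displacements(grid)
  b3 <- function(r) {
    a <- abs(r)
    if (a < 1) (4 - 6 * a^2 + 3 * a^3) / 6
    else if (a < 2) (2 - a)^3 / 6
    else 0
  }
  out <- c(0, 0, 0)
  s <- (voxel - 1) / sp
  for (tz in seq_len(dims[3L])) for (ty in seq_len(dims[2L]))
    for (tx in seq_len(dims[1L])) {
      w <- b3(s[1L] - tx + 2) * b3(s[2L] - ty + 2) * b3(s[3L] - tz + 2)
      if (w > 0)
        for (cpt in 1:3) out[cpt] <- out[cpt] + w * disp[tx, ty, tz, cpt]
    }
  out
}

# Naive data cost for one vertex: explicit voxel loop over its support.
oracleDataCost <- function(descRef, descFloat, grid, vertex, label) {
  dm <- dim(descValues(descRef))[1:3]
  sp <- gridSpacing(grid)
  base <- displacements(densify(grid))
  b3 <- function(r) {
    a <- abs(r)
    if (a < 1) (4 - 6 * a^2 + 3 * a^3) / 6
    else if (a < 2) (2 - a)^3 / 6
    else 0
  }
  tri <- function(vol, p) {
    p <- pmin(pmax(p, 1), dim(vol))
    f0 <- pmin(floor(p), dim(vol) - 1L)
    f0 <- pmax(f0, 1L)
    fr <- p - f0
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) fr[1L] else 1 - fr[1L]) *
           (if (dy) fr[2L] else 1 - fr[2L]) *
           (if (dz) fr[3L] else 1 - fr[3L])
      acc <- acc + w * vol[f0[1L] + dx, f0[2L] + dy, f0[3L] + dz]
    }
    acc
  }
  refV <- descValues(descRef)
  fltV <- descValues(descFloat)
  nch <- dim(refV)[4L]
  num <- 0; den <- 0
  for (zz in seq_len(dm[3L])) for (yy in seq_len(dm[2L]))
    for (xx in seq_len(dm[1L])) {
      w <- b3((xx - 1) / sp[1L] - vertex[1L] + 2) *
           b3((yy - 1) / sp[2L] - vertex[2L] + 2) *
           b3((zz - 1) / sp[3L] - vertex[3L] + 2)
      if (w <= 0) next
      p <- c(xx + base[xx, yy, zz, 1L] + label[1L],
             yy + base[xx, yy, zz, 2L] + label[2L],
             zz + base[xx, yy, zz, 3L] + label[3L])
      sad <- 0
      for (i in seq_len(nch))
        sad <- sad + abs(refV[xx, yy, zz, i] -
                         tri(array(fltV[, , , i], dm), p))
      num <- num + w * sad / nch
      den <- den + w
    }
  num / den
}

# Exhaustive MRF minimum by vectorised enumeration of all labelings of a
# 2x2x2 fully dynamic vertex grid.
oracleExhaustiveMin <- function(dataCosts, labels, lambda, gridDims) {
  nl <- nrow(labels)
  n <- prod(gridDims)
  E <- numeric(nl^n)
  code <- 0:(nl^n - 1)
  idx <- matrix(0L, length(E), n)
  for (p in seq_len(n)) idx[, p] <- (code %/% nl^(p - 1)) %% nl + 1L
  for (p in seq_len(n)) E <- E + dataCosts[cbind(p, idx[, p])]
  arr <- array(seq_len(n), gridDims)
  edges <- rbind(
    cbind(as.vector(arr[-gridDims[1L], , ]), as.vector(arr[-1L, , ])),
    cbind(as.vector(arr[, -gridDims[2L], ]), as.vector(arr[, -1L, ])),
    cbind(as.vector(arr[, , -gridDims[3L]]), as.vector(arr[, , -1L])))
  S <- as.matrix(stats::dist(labels, method = "manhattan"))
  for (r in seq_len(nrow(edges)))
    E <- E + 2 * lambda *
      S[(idx[, edges[r, 2L]] - 1L) * nl + idx[, edges[r, 1L]]]
  min(E) / n
}

# Shared fixture: a small deterministic random volume.
randomVolume <- function(dm, seed = 1) {
  withr::with_seed(seed, array(stats::runif(prod(dm)), dm))
}
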