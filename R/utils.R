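# Internal helpers: boundary folding, shifting, interpolation, RNG scoping.

# Reflect 1-based indices into [1, n] (half-sample symmetric: the edge voxel
# is duplicated, matching mirror padding built by index slicing). Handles
# arbitrarily far out-of-range indices by folding with period 2n.
mirrorIndex <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  j <- ifelse(j >= n, 2L * n - 1L - j, j)
  j + 1L
}

# Shifted view of a 3D array with mirror boundary: out[x] = vol[fold(x + d)].
shiftMirror <- function(vol, d) {
  dm <- dim(vol)
  vol[mirrorIndex(seq_len(dm[1L]) + d[1L], dm[1L]),
      mirrorIndex(seq_len(dm[2L]) + d[2L], dm[2L]),
      mirrorIndex(seq_len(dm[3L]) + d[3L], dm[3L]), drop = FALSE]
}

#' Rescale a volume to the unit intensity range
#'
#' Maps the minimum to 0 and the maximum to 1; a constant volume maps to
#' all zeros. Descriptor computation applies this internally so that the
#' similarity threshold, static factor and variance floor are transferable
#' across modalities.
#'
#' @param vol numeric array.
#' @return array of the same shape with values in [0, 1].
#' @export
rescale01 <- function(vol) {
  r <- range(vol)
  if (!all(is.finite(r))) stop("volume contains non-finite intensities")
  if (r[2L] == r[1L]) return(array(0, dim(vol)))
  (vol - r[1L]) / (r[2L] - r[1L])
}

# Evaluate a scoped RNG expression: runs expr with set.seed(seed) and
# restores the caller's RNG state afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Trilinear sampling of a 3D array at (possibly fractional) 1-based voxel
# coordinates, clamped to the volume edge. cx, cy, cz are equal-length
# numeric vectors; returns a vector of samples.
sampleTrilinear <- function(vol, cx, cy, cz) {
  dm <- dim(vol)
  cx <- pmin(pmax(cx, 1), dm[1L])
  cy <- pmin(pmax(cy, 1), dm[2L])
  cz <- pmin(pmax(cz, 1), dm[3L])
  x0 <- pmin(floor(cx), dm[1L] - 1L); x0 <- pmax(x0, 1L)
  y0 <- pmin(floor(cy), dm[2L] - 1L); y0 <- pmax(y0, 1L)
  z0 <- pmin(floor(cz), dm[3L] - 1L); z0 <- pmax(z0, 1L)
  if (dm[1L] == 1L) x0 <- rep(1L, length(cx))
  if (dm[2L] == 1L) y0 <- rep(1L, length(cy))
  if (dm[3L] == 1L) z0 <- rep(1L, length(cz))
  fx <- cx - x0; fy <- cy - y0; fz <- cz - z0
  sx <- 1L; sy <- dm[1L]; sz <- dm[1L] * dm[2L]
  dx <- if (dm[1L] > 1L) sx else 0L
  dy <- if (dm[2L] > 1L) sy else 0L
  dz <- if (dm[3L] > 1L) sz else 0L
  base <- (x0 - 1L) * sx + (y0 - 1L) * sy + (z0 - 1L) * sz + 1L
  v <- as.vector(vol)
  v[base]                * (1 - fx) * (1 - fy) * (1 - fz) +
  v[base + dx]           * fx       * (1 - fy) * (1 - fz) +
  v[base + dy]           * (1 - fx) * fy       * (1 - fz) +
  v[base + dx + dy]      * fx       * fy       * (1 - fz) +
  v[base + dz]           * (1 - fx) * (1 - fy) * fz +
  v[base + dx + dz]      * fx       * (1 - fy) * fz +
  v[base + dy + dz]      * (1 - fx) * fy       * fz +
  v[base + dx + dy + dz] * fx       * fy       * fz
}

# Voxel coordinate grids (1-based) for a 3D shape, as three vectors in
# x-fastest order matching as.vector() of an array of that shape.
coordGrids <- function(dm) {
  list(
    x = rep.int(seq_len(dm[1L]), times = dm[2L] * dm[3L]),
    y = rep.int(rep(seq_len(dm[2L]), each = dm[1L]), times = dm[3L]),
    z = rep(seq_len(dm[3L]), each = dm[1L] * dm[2L])
  )
}

# Inclusive box sums over a 3D 0/1 (or numeric) array via an integral image.
# Returns a closure sum(lo, hi) with lo/hi integer(3), already clipped.
makeBoxSummer <- function(arr) {
  dm <- dim(arr)
  S <- array(0, dm + 1L)
  S[-1L, -1L, -1L] <- arr
  S <- apply(S, c(2L, 3L), cumsum)            # cumsum over x -> dims (x,y,z)
  S <- aperm(apply(S, c(1L, 3L), cumsum), c(2L, 1L, 3L))  # over y
  S <- aperm(apply(S, c(1L, 2L), cumsum), c(2L, 3L, 1L))  # over z
  function(lo, hi) {
    if (any(hi < lo)) return(0)
    a <- lo; b <- hi + 1L
    S[b[1], b[2], b[3]] - S[a[1], b[2], b[3]] -
      S[b[1], a[2], b[3]] - S[b[1], b[2], a[3]] +
      S[a[1], a[2], b[3]] + S[a[1], b[2], a[3]] +
      S[b[1], a[2], a[3]] - S[a[1], a[2], a[3]]
  }
}

# Argument checking helpers
checkVoxelInside <- function(x, dm, what = "point") {
  if (length(x) != 3L) stop(what, " must be a length-3 voxel index")
  if (any(x < 1L) || any(x > dm))
    stop(what, " lies outside the volume")
  invisible(as.integer(round(x)))
}
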