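# internal helpers shared across modules

# evaluate expr with a temporarily seeded RNG, restoring global state after
withSeed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# voxel-center coordinates (mm) for a grid; returns list of per-axis vectors
voxelCenters <- function(dims, spacing, origin = c(0, 0, 0)) {
  lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 0.5) * spacing)
}

# nvox x 3 matrix of voxel-center coordinates in array (column-major) order
voxelCoordMatrix <- function(dims, spacing, origin = c(0, 0, 0)) {
  cc <- voxelCenters(dims, spacing, origin)
  cbind(rep(cc[[1]], times = dims[2] * dims[3]),
        rep(rep(cc[[2]], each = dims[1]), times = dims[3]),
        rep(cc[[3]], each = dims[1] * dims[2]))
}

# trilinear interpolation of a 3D array at continuous 1-based voxel indices
# (nq x 3 matrix); indices are clamped to the valid interpolation range
trilinear <- function(vol, idx) {
  d <- dim(vol)
  cl <- function(v, n) pmin(pmax(v, 1), n - 1e-9)
  x <- cl(idx[, 1], d[1]); y <- cl(idx[, 2], d[2]); z <- cl(idx[, 3], d[3])
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L)
  z0 <- pmin(floor(z), d[3] - 1L)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  at <- function(i, j, k) vol[cbind(i, j, k)]
  v000 <- at(x0, y0, z0);         v100 <- at(x0 + 1, y0, z0)
  v010 <- at(x0, y0 + 1, z0);     v110 <- at(x0 + 1, y0 + 1, z0)
  v001 <- at(x0, y0, z0 + 1);     v101 <- at(x0 + 1, y0, z0 + 1)
  v011 <- at(x0, y0 + 1, z0 + 1); v111 <- at(x0 + 1, y0 + 1, z0 + 1)
  (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
    (v010 * (1 - fx) + v110 * fx) * fy * (1 - fz) +
    (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
    (v011 * (1 - fx) + v111 * fx) * fy * fz
}

# shift a 3D logical/numeric array by one voxel along axis, zero-filling
shiftArray <- function(a, axis, by) {
  d <- dim(a)
  out <- array(vector(typeof(a), 1), d)
  src <- dst <- lapply(d, seq_len)
  if (by > 0) { dst[[axis]] <- (1 + by):d[axis]; src[[axis]] <- 1:(d[axis] - by) }
  else { dst[[axis]] <- 1:(d[axis] + by); src[[axis]] <- (1 - by):d[axis] }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# 6-neighborhood binary erosion / dilation of a logical 3D array
erodeMask <- function(mask, iterations = 1L) {
  m <- mask
  for (i in seq_len(iterations)) {
    keep <- m
    for (ax in 1:3) for (s in c(-1L, 1L)) keep <- keep & shiftArray(m, ax, s)
    m <- keep
  }
  m
}

dilateMask <- function(mask, iterations = 1L) {
  m <- mask
  for (i in seq_len(iterations)) {
    grow <- m
    for (ax in 1:3) for (s in c(-1L, 1L)) grow <- grow | shiftArray(m, ax, s)
    m <- grow
  }
  m
}
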