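# shared fixtures, all built in code

# minimal spectral library on a coarse grid with easy hand numbers
tinyLibrary <- function() {
  SpectralLibrary(c(600, 610, 620, 630, 640),
                  list(HbO = c(3, 2.5, 2, 1.5, 1),
                       PBB5 = c(1, 1.5, 2, 2.5, 3)))
}

# wrap a bands x pixels matrix into a single-frame VolumeStack
stackFromMatrix <- function(Y, wl, dims, frameTimes = 0) {
  nf <- length(frameTimes)
  stopifnot(ncol(Y) == prod(dims) * nf)
  vol <- array(0, c(dims, length(wl), nf))
  for (f in seq_len(nf)) for (i in seq_along(wl))
    vol[, , , i, f] <- array(Y[i, (f - 1) * prod(dims) + seq_len(prod(dims))],
                             dims)
  new("VolumeStack", volumes = vol, spacing = 0.2, origin = c(0, 0, 0),
      wavelengths = wl, frameTimes = frameTimes, provenance = list())
}

# strongest local maxima (6-neighborhood) of a volume, ordered by value
topLocalMaxima <- function(v, n = 2) {
  d <- dim(v)
  shift <- function(a, ax, by) {
    out <- array(-Inf, d)
    src <- dst <- lapply(d, seq_len)
    if (by > 0) { dst[[ax]] <- (1 + by):d[ax]; src[[ax]] <- 1:(d[ax] - by) }
    else { dst[[ax]] <- 1:(d[ax] + by); src[[ax]] <- (1 - by):d[ax] }
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  isMax <- array(TRUE, d)
  for (ax in 1:3) for (s in c(-1, 1)) isMax <- isMax & (v > shift(v, ax, s))
  cand <- which(isMax, arr.ind = TRUE)
  cand[order(v[cand], decreasing = TRUE)[seq_len(min(n, nrow(cand)))], ,
       drop = FALSE]
}

# simulate a point-absorber sinogram (noise off) and reconstruct it
pointSourceRecon <- function(voxels, dims = c(64, 64, 64), spacing = 0.2,
                             nDetectors = 256L) {
  ctr <- dims * spacing / 2
  geom <- makeArrayGeometry(ctr, nDetectors = nDetectors)
  p0 <- array(0, dims)
  p0[voxels] <- 1
  tr <- projectVolume(p0, geom, spacing)
  s <- degradeSinogram(array(tr, c(dim(tr), 1, 1)), geom, 600, 0)
  list(volume = backproject(s, dims, spacing), sinogram = s, geom = geom)
}

# balanced two-endmember simplex mixture with pure pixels (unit-max spectra)
vcaFixture <- function(noiseSd = 0, seed = 42, dims = c(12, 12, 2)) {
  wl <- seq(600, 655, by = 5)
  lib <- bundledSpectralLibrary()
  e1 <- interpolateSpectrum(lib, "HbO", wl); e1 <- e1 / max(e1)
  e2 <- interpolateSpectrum(lib, "PBB5", wl); e2 <- e2 / max(e2)
  n <- prod(dims)
  set.seed(seed)
  a1 <- stats::runif(n)
  A <- rbind(a1, 1 - a1)
  A[, 1:5] <- rbind(rep(1, 5), rep(0, 5))
  A[, 6:10] <- rbind(rep(0, 5), rep(1, 5))
  Y <- cbind(e1, e2) %*% A
  if (noiseSd > 0) Y <- Y + stats::rnorm(length(Y), 0, noiseSd * max(Y))
  list(stack = stackFromMatrix(Y, wl, dims), e1 = e1, e2 = e2, wl = wl)
}
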