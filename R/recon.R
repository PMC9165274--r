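#' Normalize a sinogram by pulse energy
#'
#' Divides every (wavelength, frame) block of traces by its recorded laser
#' pulse energy and resets the energies to 1, so normalizing twice is a
#' no-op. This exactly cancels simulated per-pulse energy jitter.
#'
#' @param s a \linkS4class{Sinogram} with positive energies.
#' @return the normalized \linkS4class{Sinogram}.
#' @export
normalizeEnergy <- function(s) {
  stopifnot(is(s, "Sinogram"))
  if (any(s@energies <= 0)) stop("nonpositive pulse energy")
  d <- dim(s@signals)
  out <- s@signals
  for (w in seq_len(d[3])) for (f in seq_len(d[4]))
    out[, , w, f] <- out[, , w, f] / s@energies[w, f]
  initialize(s, signals = out, energies = matrix(1, d[3], d[4]))
}

#' Back-project one (wavelength, frame) of a sinogram
#'
#' Delay-and-sum: \eqn{v(r) = \sum_d w_d q_d(|r - r_d| / c)} with linear
#' interpolation in the delay, solid-angle weights normalized to sum to 1,
#' and the pre-filter \eqn{q = -t \, ds/dt} (matching the N-shape forward
#' model) or the raw trace. Delays outside the recorded window contribute
#' zero and are counted in a warning.
#'
#' @param s a (normalized) \linkS4class{Sinogram}.
#' @param dims integer(3) reconstruction grid size.
#' @param spacingMm voxel spacing (mm); @param origin grid corner (mm).
#' @param wavelength wavelength in nm (must be in the sinogram).
#' @param frame frame index.
#' @param filter "ubp" (default, derivative-model pre-filter) or "das".
#' @return a 3D volume.
#' @export
backproject <- function(s, dims, spacingMm, origin = c(0, 0, 0),
                        wavelength = s@wavelengths[1], frame = 1L,
                        filter = c("ubp", "das")) {
  filter <- match.arg(filter)
  wi <- match(wavelength, s@wavelengths)
  if (is.na(wi)) stop("wavelength not present in sinogram: ", wavelength)
  v <- .dasEngine(s, dims, spacingMm, origin,
                  cbind(wi, as.integer(frame)), filter)
  array(v[, 1], dims)
}

# the actual engine (detector-outer loop; per-detector geometry reused for
# every combo)
.dasEngine <- function(s, dims, spacingMm, origin, combos, filter) {
  geom <- s@geometry
  nDet <- nrow(geom@positions)
  wts <- geom@weights / sum(geom@weights)
  X <- voxelCoordMatrix(dims, spacingMm, origin)
  ns <- geom@nSamples
  cdt <- geom@speedOfSound / geom@sampleRateMHz
  nc <- nrow(combos)
  out <- matrix(0, nrow(X), nc)
  clipped <- 0L
  for (d in seq_len(nDet)) {
    dif <- sweep(X, 2, geom@positions[d, ])
    fidx <- sqrt(rowSums(dif * dif)) / cdt + 1
    i0 <- floor(fidx)
    frac <- fidx - i0
    ok <- i0 >= 1L & i0 < ns
    clipped <- clipped + sum(!ok)
    i0k <- as.integer(i0[ok]); frk <- frac[ok]
    for (k in seq_len(nc)) {
      tr <- s@signals[d, , combos[k, 1], combos[k, 2]]
      q <- if (filter == "das") tr else {
        dtUs <- 1 / geom@sampleRateMHz
        der <- c(0, (tr[3:ns] - tr[1:(ns - 2)]) / (2 * dtUs), 0)
        -der * (0:(ns - 1)) * dtUs
      }
      contrib <- numeric(nrow(X))
      contrib[ok] <- q[i0k] * (1 - frk) + q[i0k + 1L] * frk
      out[, k] <- out[, k] + wts[d] * contrib
    }
  }
  if (clipped > 0L)
    warning(clipped, " voxel-detector delays fell outside the recorded window")
  out
}

#' Reconstruct every (wavelength, frame) of a sinogram
#'
#' Energy-normalizes the sinogram (if not already normalized) and maps
#' \code{\link{backproject}} over all wavelength/frame combinations.
#'
#' @inheritParams backproject
#' @param normalize run \code{\link{normalizeEnergy}} first (default TRUE).
#' @return a \linkS4class{VolumeStack} with provenance (filter, grid, speed
#'   of sound).
#' @export
reconstructStack <- function(s, dims, spacingMm, origin = c(0, 0, 0),
                             filter = c("ubp", "das"), normalize = TRUE) {
  filter <- match.arg(filter)
  if (normalize) s <- normalizeEnergy(s)
  nw <- length(s@wavelengths); nf <- length(s@frameTimes)
  combos <- cbind(rep(seq_len(nw), times = nf),
                  rep(seq_len(nf), each = nw))
  v <- .dasEngine(s, dims, spacingMm, origin, combos, filter)
  vol <- array(0, c(dims, nw, nf))
  for (k in seq_len(nrow(combos)))
    vol[, , , combos[k, 1], combos[k, 2]] <- v[, k]
  new("VolumeStack", volumes = vol, spacing = spacingMm, origin = origin,
      wavelengths = s@wavelengths, frameTimes = s@frameTimes,
      provenance = list(filter = filter,
                        speedOfSound = s@geometry@speedOfSound,
                        nDetectors = nrow(s@geometry@positions),
                        noiseSigma = s@noiseSigma))
}
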