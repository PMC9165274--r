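#' Optical fields of the forward model
#'
#' @slot muA absorption coefficient volume (1/cm, a.u.-scaled).
#' @slot muSPrime scalar reduced scattering coefficient (1/cm).
#' @slot muEff effective attenuation volume,
#'   \eqn{\sqrt{3 \mu_a (\mu_a + \mu_s')}} (diffusion theory).
#' @slot fluence light fluence volume, 1 at the illuminated surface.
#' @export
setClass("OpticalFields",
  representation(muA = "array", muSPrime = "numeric", muEff = "array",
                 fluence = "array"))

setValidity("OpticalFields", function(object) {
  if (any(object@muA < 0)) return("muA must be nonnegative")
  if (any(object@fluence > 1 + 1e-12)) return("fluence must be <= 1")
  if (any(object@fluence < 0)) return("fluence must be >= 0")
  TRUE
})

#' Build a spherical-cap detection array
#'
#' Detectors are spread quasi-uniformly (Fibonacci lattice) over a spherical
#' cap below the imaged volume, pointing up — the geometry of a hemispherical
#' optoacoustic array. The detection band is a Gaussian around the center
#' frequency whose full width equals \code{fractionalBandwidth *
#' centerFreqMHz}.
#'
#' @param center cap sphere center (mm), typically the grid center.
#' @param nDetectors number of detectors (>= 64), default 256.
#' @param radiusMm sphere radius (mm), default 15.
#' @param capHalfAngleDeg half-angle of the cap measured from straight down;
#'   90 covers the full lower hemisphere.
#' @param speedOfSound mm/us, default 1.50.
#' @param sampleRateMHz sampling rate, default 40 (25 ns samples).
#' @param nSamples samples per trace, default 1024.
#' @param centerFreqMHz,fractionalBandwidth detection band model; set
#'   \code{fractionalBandwidth = Inf} for an all-pass band.
#' @return an \linkS4class{ArrayGeometry}.
#' @export
makeArrayGeometry <- function(center, nDetectors = 256L, radiusMm = 15,
                              capHalfAngleDeg = 90, speedOfSound = 1.5,
                              sampleRateMHz = 40, nSamples = 1024L,
                              centerFreqMHz = 4, fractionalBandwidth = 1) {
  n <- as.integer(nDetectors)
  i <- seq_len(n)
  u <- (i - 0.5) / n
  cosTheta <- 1 - u * (1 - cos(capHalfAngleDeg * pi / 180))
  sinTheta <- sqrt(pmax(0, 1 - cosTheta^2))
  phi <- i * pi * (3 - sqrt(5))
  pos <- cbind(center[1] + radiusMm * sinTheta * cos(phi),
               center[2] + radiusMm * sinTheta * sin(phi),
               center[3] - radiusMm * cosTheta)
  new("ArrayGeometry", positions = pos, speedOfSound = speedOfSound,
      sampleRateMHz = sampleRateMHz, nSamples = as.integer(nSamples),
      centerFreqMHz = centerFreqMHz,
      fractionalBandwidth = fractionalBandwidth,
      weights = rep(1 / n, n))
}

#' Absorption coefficient map from concentration maps
#'
#' \eqn{\mu_a(r) = \sum_c \epsilon_c(\lambda) C_c(r)}: linear in every
#' concentration map.
#'
#' @param maps named list of chromophore concentration volumes.
#' @param lib a \linkS4class{SpectralLibrary} providing
#'   \eqn{\epsilon_c(\lambda)}.
#' @param lambdaNm wavelength (nm) within the library range.
#' @return absorption volume (a.u.-scaled 1/cm).
#' @export
absorptionMap <- function(maps, lib, lambdaNm) {
  stopifnot(is.list(maps), length(maps) >= 1L)
  missing <- setdiff(names(maps), chromophores(lib))
  if (length(missing))
    stop("chromophore absent from library: ", paste(missing, collapse = ", "))
  muA <- array(0, dim(maps[[1]]))
  for (cn in names(maps))
    muA <- muA + interpolateSpectrum(lib, cn, lambdaNm) * maps[[cn]]
  muA
}

#' Light fluence by effective-attenuation depth model
#'
#' Effective attenuation from diffusion theory,
#' \eqn{\mu_{eff} = \sqrt{3 \mu_a (\mu_a + \mu_s')}}, integrated along the
#' top-illumination (dorsal, +z) direction: the fluence of a voxel is
#' \eqn{\exp(-\sum \mu_{eff} \Delta z)} accumulated over the voxels strictly
#' above it, so the surface layer has fluence exactly 1.
#'
#' @param muA absorption volume (1/cm).
#' @param muSPrime reduced scattering coefficient (1/cm), default 10.
#' @param spacingMm voxel spacing (mm).
#' @return an \linkS4class{OpticalFields}.
#' @export
fluenceField <- function(muA, muSPrime = 10, spacingMm) {
  if (any(muA < 0)) stop("negative absorption coefficient")
  muEff <- sqrt(3 * muA * (muA + muSPrime))
  d <- dim(muA)
  dzCm <- spacingMm / 10
  fl <- array(1, d)
  if (d[3] > 1L) {
    acc <- matrix(0, d[1], d[2])
    for (k in (d[3] - 1L):1L) {
      acc <- acc + muEff[, , k + 1L] * dzCm
      fl[, , k] <- exp(-acc)
    }
  }
  new("OpticalFields", muA = muA, muSPrime = muSPrime, muEff = muEff,
      fluence = fl)
}

#' Initial optoacoustic pressure
#'
#' \eqn{p_0 = \Gamma \mu_a \Phi} with the Grueneisen parameter in a.u.
#'
#' @param muA absorption volume; @param fluence fluence volume (same shape).
#' @param gamma Grueneisen parameter, default 1.
#' @return initial pressure volume (a.u.).
#' @export
initialPressure <- function(muA, fluence, gamma = 1) {
  stopifnot(identical(dim(muA), dim(fluence)))
  gamma * muA * fluence
}

# time-derivative of traces along the sample dimension (central differences,
# zero at the edges); m is [sample x trace] oriented
.timeDerivative <- function(m, dtUs) {
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  out[2:(n - 1), ] <- (m[3:n, , drop = FALSE] - m[1:(n - 2), , drop = FALSE]) /
    (2 * dtUs)
  out
}

# core projection engine: p0 matrix [nvox x ncombo] -> signals
# [det x sample x ncombo]; spherical spreading 1/(4 pi r), impulse binned at
# round(r / (c dt)), optional N-shape time derivative
.projectEngine <- function(p0mat, geom, dims, spacingMm, origin,
                           derivative = TRUE) {
  nz <- which(rowSums(abs(p0mat)) > 0)
  nDet <- nrow(geom@positions)
  ns <- geom@nSamples
  nc <- ncol(p0mat)
  out <- array(0, c(nDet, ns, nc))
  if (length(nz) == 0L) return(out)
  X <- voxelCoordMatrix(dims, spacingMm, origin)[nz, , drop = FALSE]
  dtUs <- 1 / geom@sampleRateMHz
  cdt <- geom@speedOfSound * dtUs
  vox <- spacingMm^3
  p0nz <- p0mat[nz, , drop = FALSE]
  for (d in seq_len(nDet)) {
    dif <- sweep(X, 2, geom@positions[d, ])
    dist <- sqrt(rowSums(dif * dif))
    idx <- as.integer(round(dist / cdt)) + 1L
    if (any(idx > ns) || any(idx < 1L))
      stop("voxel outside recorded time window (increase nSamples)")
    amp <- vox / (4 * pi * dist)
    acc <- rowsum(p0nz * amp, group = idx)
    rows <- as.integer(rownames(acc))
    tr <- matrix(0, ns, nc)
    tr[rows, ] <- acc
    if (derivative) tr <- .timeDerivative(tr, dtUs)
    out[d, , ] <- tr
  }
  out
}

#' Project an initial-pressure volume onto detector traces
#'
#' Each voxel contributes a discrete impulse at time-of-flight
#' \eqn{|r - r_d| / c} with amplitude \eqn{p_0 V / (4\pi |r - r_d|)}
#' (sample n covers time n*dt, 0-based). With \code{derivative = TRUE}
#' (default) a time-derivative operator is applied, producing the N-shaped
#' signal model.
#'
#' @param p0 initial pressure volume.
#' @param geom an \linkS4class{ArrayGeometry}.
#' @param spacingMm voxel spacing (mm); @param origin grid corner (mm).
#' @param derivative apply the N-shape derivative model.
#' @return matrix [detector x sample].
#' @export
projectVolume <- function(p0, geom, spacingMm, origin = c(0, 0, 0),
                          derivative = TRUE) {
  s <- .projectEngine(matrix(as.numeric(p0), ncol = 1), geom, dim(p0),
                      spacingMm, origin, derivative = derivative)
  s[, , 1]
}

# Gaussian detection-band gain on the FFT grid of n samples
.bandGain <- function(geom, n) {
  if (!is.finite(geom@fractionalBandwidth) || geom@centerFreqMHz <= 0)
    return(rep(1, n))
  fs <- geom@sampleRateMHz
  f <- (0:(n - 1)) * fs / n
  fa <- pmin(f, fs - f)
  sigf <- geom@fractionalBandwidth * geom@centerFreqMHz /
    (2 * sqrt(2 * log(2)))
  exp(-(fa - geom@centerFreqMHz)^2 / (2 * sigf^2))
}

# apply the band filter to a [det x sample x wl x frame] array
.bandFilter <- function(signals, geom) {
  g <- .bandGain(geom, dim(signals)[2])
  if (all(g == 1)) return(signals)
  d <- dim(signals)
  m <- matrix(aperm(signals, c(2, 1, 3, 4)), nrow = d[2])
  m <- Re(stats::mvfft(stats::mvfft(m) * g, inverse = TRUE)) / d[2]
  aperm(array(m, c(d[2], d[1], d[3], d[4])), c(2, 1, 3, 4))
}

#' Degrade clean traces into a measured sinogram
#'
#' Applies the Gaussian detection band of the array, multiplies every
#' (wavelength, frame) block by its pulse energy, and adds i.i.d. Gaussian
#' noise; deterministic for a fixed seed.
#'
#' @param traces 4D array [detector x sample x wavelength x frame].
#' @param geom an \linkS4class{ArrayGeometry}.
#' @param wavelengthsNm,frameTimesS axis metadata.
#' @param energies matrix [wavelength x frame] of pulse energies (> 0),
#'   default all 1.
#' @param noiseSigma standard deviation of additive noise, default 0.
#' @param seed RNG seed for the noise.
#' @return a \linkS4class{Sinogram}.
#' @export
degradeSinogram <- function(traces, geom, wavelengthsNm, frameTimesS,
                            energies = NULL, noiseSigma = 0, seed = 1L) {
  d <- dim(traces)
  if (is.null(energies)) energies <- matrix(1, d[3], d[4])
  if (any(energies <= 0)) stop("energies must be > 0")
  out <- .bandFilter(traces, geom)
  for (w in seq_len(d[3])) for (f in seq_len(d[4]))
    out[, , w, f] <- out[, , w, f] * energies[w, f]
  if (noiseSigma > 0)
    out <- out + withSeed(seed, array(stats::rnorm(length(out), 0, noiseSigma), d))
  new("Sinogram", signals = out, energies = energies, geometry = geom,
      wavelengths = as.numeric(wavelengthsNm),
      frameTimes = as.numeric(frameTimesS), noiseSigma = noiseSigma)
}

#' Simulate a multi-wavelength, multi-frame sinogram from a frame series
#'
#' Full optical + acoustic forward chain: per (wavelength, frame) the HbO and
#' probe concentration maps are converted to an absorption map, attenuated by
#' the effective-attenuation fluence model, converted to initial pressure and
#' projected onto the detector array; the traces are then band-filtered,
#' scaled by jittered per-pulse laser energies, and corrupted with Gaussian
#' noise whose level is set relative to the clean signal's standard
#' deviation.
#'
#' @param fs a \linkS4class{FrameSeries}.
#' @param lib a \linkS4class{SpectralLibrary} with HbO and PBB5.
#' @param geom an \linkS4class{ArrayGeometry}.
#' @param wavelengthsNm acquisition wavelengths, default 600--640 by 10.
#' @param frames indices of frames to acquire (default all).
#' @param muSPrime reduced scattering (1/cm), default 10.
#' @param gamma Grueneisen parameter.
#' @param derivative N-shape signal model flag.
#' @param applyFluence model light attenuation (on for realism).
#' @param noiseRel additive noise sd as a fraction of the clean signal sd.
#' @param energyJitterSd log-sd of the per-pulse energy jitter.
#' @param seed RNG seed.
#' @return a \linkS4class{Sinogram}.
#' @export
simulateSinogram <- function(fs, lib, geom,
                             wavelengthsNm = seq(600, 640, by = 10),
                             frames = seq_along(fs@frameTimes),
                             muSPrime = 10, gamma = 1, derivative = TRUE,
                             applyFluence = TRUE, noiseRel = 0.02,
                             energyJitterSd = 0.03, seed = 1L) {
  p <- fs@phantom
  nw <- length(wavelengthsNm); nf <- length(frames)
  nvox <- prod(p@dims)
  p0mat <- matrix(0, nvox, nw * nf)
  k <- 0L
  for (f in frames) for (w in seq_len(nw)) {
    k <- k + 1L
    maps <- list(HbO = p@hboMap, PBB5 = fs@pbb5Maps[[f]])
    muA <- absorptionMap(maps, lib, wavelengthsNm[w])
    fl <- if (applyFluence)
      fluenceField(muA, muSPrime, p@spacing)@fluence else array(1, p@dims)
    p0mat[, k] <- initialPressure(muA, fl, gamma)
  }
  sig <- .projectEngine(p0mat, geom, p@dims, p@spacing, p@origin,
                        derivative = derivative)
  # combos were laid out frame-major, wavelength-minor
  traces <- array(0, c(nrow(geom@positions), geom@nSamples, nw, nf))
  k <- 0L
  for (f in seq_len(nf)) for (w in seq_len(nw)) {
    k <- k + 1L
    traces[, , w, f] <- sig[, , k]
  }
  clean <- .bandFilter(traces, geom)
  energies <- withSeed(seed + 1L,
                       matrix(exp(stats::rnorm(nw * nf, 0, energyJitterSd)),
                              nw, nf))
  noiseSigma <- if (noiseRel > 0) noiseRel * stats::sd(clean) else 0
  degradeSinogram(traces, geom, wavelengthsNm, fs@frameTimes[frames],
                  energies = energies, noiseSigma = noiseSigma, seed = seed)
}
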