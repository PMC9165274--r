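#' Wavelength grid of an object
#' @param x a \linkS4class{SpectralLibrary}, \linkS4class{Sinogram},
#'   \linkS4class{VolumeStack} or \linkS4class{ExtractedSpectrum}.
#' @return numeric vector of wavelengths in nm.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' Frame times of an object
#' @param x a \linkS4class{FrameSeries}, \linkS4class{Sinogram},
#'   \linkS4class{VolumeStack}, \linkS4class{AbundanceMaps} or
#'   \linkS4class{VOIReport}.
#' @return numeric vector of frame times in seconds.
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' Chromophore or component names of an object
#' @param x a \linkS4class{SpectralLibrary} or \linkS4class{AbundanceMaps}.
#' @return character vector of names.
#' @export
setGeneric("chromophores", function(x) standardGeneric("chromophores"))

setMethod("wavelengths", "SpectralLibrary", function(x) x@wavelengths)
setMethod("wavelengths", "Sinogram", function(x) x@wavelengths)
setMethod("wavelengths", "VolumeStack", function(x) x@wavelengths)
setMethod("wavelengths", "ExtractedSpectrum", function(x) x@wavelengths)

setMethod("frameTimes", "FrameSeries", function(x) x@frameTimes)
setMethod("frameTimes", "Sinogram", function(x) x@frameTimes)
setMethod("frameTimes", "VolumeStack", function(x) x@frameTimes)
setMethod("frameTimes", "AbundanceMaps", function(x) x@frameTimes)
setMethod("frameTimes", "VOIReport", function(x) x@frameTimes)

setMethod("chromophores", "SpectralLibrary", function(x) colnames(x@spectra))
setMethod("chromophores", "AbundanceMaps", function(x) x@components)

#' @describeIn wavelengths number of detectors, samples, wavelengths, frames
#' @export
setMethod("dim", "Sinogram", function(x) dim(x@signals))

setMethod("show", "SpectralLibrary", function(object) {
  cat("SpectralLibrary:", length(object@wavelengths), "wavelengths",
      sprintf("[%g-%g nm],", min(object@wavelengths), max(object@wavelengths)),
      ncol(object@spectra), "chromophores:",
      paste(colnames(object@spectra), collapse = ", "), "\n")
})

setMethod("show", "BrainPhantom", function(object) {
  cat("BrainPhantom:", paste(object@dims, collapse = " x "), "voxels @",
      object@spacing, "mm;", length(object@regionNames), "regions;",
      sum(object@vesselMask), "vessel voxels; seed", object@seed, "\n")
})

setMethod("show", "FrameSeries", function(object) {
  cat("FrameSeries:", length(object@frameTimes), "frames",
      sprintf("[%g-%g s],", min(object@frameTimes), max(object@frameTimes)),
      "genotype", object@genotype, "dose", object@doseScale, "\n")
})

setMethod("show", "ArrayGeometry", function(object) {
  cat("ArrayGeometry:", nrow(object@positions), "detectors;",
      object@sampleRateMHz, "MHz x", object@nSamples, "samples; c =",
      object@speedOfSound, "mm/us\n")
})

setMethod("show", "Sinogram", function(object) {
  d <- dim(object@signals)
  cat("Sinogram:", d[1], "detectors x", d[2], "samples x", d[3],
      "wavelengths x", d[4], "frames; noise sd", object@noiseSigma, "\n")
})

setMethod("show", "VolumeStack", function(object) {
  d <- dim(object@volumes)
  cat("VolumeStack:", paste(d[1:3], collapse = " x "), "voxels @",
      object@spacing, "mm;", d[4], "wavelengths x", d[5], "frames\n")
})

setMethod("show", "AbundanceMaps", function(object) {
  cat("AbundanceMaps:", paste(object@components, collapse = ", "), "over",
      length(object@wavelengthsUsed), "wavelengths (",
      paste(object@wavelengthsUsed, collapse = ", "), "nm )\n")
})

setMethod("show", "ProfileFit", function(object) {
  cat(sprintf("ProfileFit: fwhm = %.2f um (sigma %.2f um), R^2 = %.4f\n",
              object@fwhm, object@params[["sigma"]], object@rSquared))
})

setMethod("show", "VOIReport", function(object) {
  cat("VOIReport:", nrow(object@values), "regions x", ncol(object@values),
      "frames; group", object@group, "; rater", object@rater, "\n")
})

setMethod("show", "FitReport", function(object) {
  cat(sprintf("FitReport (%s): log10 IC50 = %s; R^2 = %.4f, SSE = %.4g, dof = %d\n",
              object@model,
              paste(signif(object@coef[grep("logIC50", names(object@coef))], 4),
                    collapse = ", "),
              object@rSquared, object@sse, as.integer(object@dof)))
})
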