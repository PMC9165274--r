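#' @import methods
NULL

#' Chromophore absorption spectra on a common wavelength grid
#'
#' Holds per-chromophore absorption values (arbitrary but consistent units)
#' tabulated over a strictly increasing optical wavelength grid. Used both to
#' build absorption maps in the forward model and as the design spectra for
#' linear unmixing.
#'
#' @slot wavelengths numeric, strictly increasing wavelengths in nm, all
#'   within 400--900 nm.
#' @slot spectra numeric matrix, one row per wavelength, one named column per
#'   chromophore; all values >= 0.
#' @slot unitsTag free-text unit label (absorption values are arbitrary
#'   consistent units).
#' @slot sourceTag named character, provenance string per chromophore.
#' @export
setClass("SpectralLibrary",
  representation(wavelengths = "numeric", spectra = "matrix",
                 unitsTag = "character", sourceTag = "character"))

setValidity("SpectralLibrary", function(object) {
  w <- object@wavelengths
  s <- object@spectra
  if (length(w) < 2L) return("need at least two wavelengths")
  if (any(diff(w) <= 0)) return("wavelength grid must be strictly increasing")
  if (any(w < 400 | w > 900)) return("wavelengths must lie within [400, 900] nm")
  if (nrow(s) != length(w)) return("one spectrum value required per wavelength")
  if (is.null(colnames(s)) || any(!nzchar(colnames(s))))
    return("spectra columns must be named by chromophore")
  if (anyDuplicated(colnames(s))) return("duplicate chromophore names")
  if (any(!is.finite(s)) || any(s < 0)) return("absorption values must be finite and >= 0")
  TRUE
})

#' Atlas-labelled digital mouse-brain phantom
#'
#' A voxelized brain with integer volume-of-interest (VOI) labels
#' (0 = extracranial background), a vessel mask including a superior sagittal
#' sinus tube on the dorsal midline, and a nonnegative oxygenated-hemoglobin
#' concentration map. Voxel centers sit at \code{origin + (i - 0.5) * spacing}
#' (1-based index i, right-handed axes, mm); the whole labelled brain fits in
#' a 15 x 15 x 15 mm field of view.
#'
#' @slot dims integer(3), grid size per axis.
#' @slot spacing scalar voxel spacing in mm (isotropic).
#' @slot origin numeric(3), position of the grid corner in mm.
#' @slot labels integer 3D array of VOI labels.
#' @slot regionNames named character; names are label integers as strings.
#' @slot vesselMask logical 3D array.
#' @slot hboMap numeric 3D array, HbO concentration (a.u.).
#' @slot seed integer seed the phantom was generated from.
#' @export
setClass("BrainPhantom",
  representation(dims = "integer", spacing = "numeric", origin = "numeric",
                 labels = "array", regionNames = "character",
                 vesselMask = "array", hboMap = "array", seed = "integer"))

setValidity("BrainPhantom", function(object) {
  d <- object@dims
  if (length(d) != 3L || any(d < 1L)) return("dims must be three positive integers")
  if (!identical(dim(object@labels), as.integer(d))) return("labels dim mismatch")
  if (!identical(dim(object@vesselMask), as.integer(d))) return("vesselMask dim mismatch")
  if (!identical(dim(object@hboMap), as.integer(d))) return("hboMap dim mismatch")
  if (length(object@spacing) != 1L || object@spacing <= 0) return("spacing must be a positive scalar")
  if (any(object@hboMap < 0)) return("hboMap must be nonnegative")
  if (any(object@vesselMask & object@hboMap <= 0))
    return("hboMap must be strictly positive on the vessel mask")
  need <- c("cortex", "hippocampus", "thalamus", "cerebellum")
  if (!all(need %in% object@regionNames))
    return("regions cortex, hippocampus, thalamus, cerebellum are required")
  lab <- object@labels
  for (nm in names(object@regionNames)) {
    if (!any(lab == as.integer(nm)))
      return(sprintf("declared region '%s' has zero volume", object@regionNames[[nm]]))
  }
  idx <- which(lab > 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return("phantom has no brain voxels")
  ext <- (apply(idx, 2, max) - apply(idx, 2, min) + 1) * object@spacing
  if (any(ext > 15 + 1e-9)) return("labelled brain exceeds the 15 mm field of view")
  TRUE
})

#' Bolus and retention kinetics configuration
#'
#' Parameters of the synthetic probe kinetics: a gamma-variate vascular bolus
#' starting at the injection time and a two-compartment parenchymal
#' uptake/washout driven by the vascular pool, modulated per region by a
#' relative binding multiplier (tau load) and a dose scale.
#'
#' @slot tInject injection start time (s), default 30.
#' @slot frameTimes acquisition frame times (s), increasing.
#' @slot doseScale multiplicative dose factor (1 = the 25 mg/kg analogue).
#' @slot vascularShape,vascularScale gamma-variate shape (dimensionless) and
#'   scale (s); the vascular peak sits at \code{tInject + shape * scale}.
#' @slot uptakeRate,washoutRate parenchymal two-compartment rates (1/s).
#' @slot genotype "P301L" or "WT".
#' @slot tauLoad named numeric, region -> relative binding multiplier.
#' @slot wtFraction fraction of tau load retained by wild-type animals.
#' @export
setClass("KineticsConfig",
  representation(tInject = "numeric", frameTimes = "numeric",
                 doseScale = "numeric", vascularShape = "numeric",
                 vascularScale = "numeric", uptakeRate = "numeric",
                 washoutRate = "numeric", genotype = "character",
                 tauLoad = "numeric", wtFraction = "numeric"))

setValidity("KineticsConfig", function(object) {
  if (object@tInject < 0) return("tInject must be >= 0")
  if (length(object@frameTimes) == 0L || any(diff(object@frameTimes) <= 0))
    return("frameTimes must be non-empty and increasing")
  if (object@doseScale <= 0) return("doseScale must be > 0")
  if (object@vascularShape <= 0 || object@vascularScale <= 0 ||
      object@uptakeRate <= 0 || object@washoutRate <= 0)
    return("all rates must be > 0")
  if (!object@genotype %in% c("P301L", "WT")) return("genotype must be 'P301L' or 'WT'")
  if (any(object@tauLoad < 0)) return("tauLoad must be >= 0")
  if (object@wtFraction < 0 || object@wtFraction > 1) return("wtFraction must be in [0,1]")
  TRUE
})

#' Time-resolved probe concentration maps over a phantom
#'
#' One nonnegative PBB5 concentration volume per acquisition frame, all zero
#' before the injection time.
#'
#' @slot phantom the \linkS4class{BrainPhantom}.
#' @slot frameTimes frame times in seconds.
#' @slot pbb5Maps list of 3D arrays, one per frame.
#' @slot genotype "P301L" or "WT".
#' @slot doseScale dose multiplier used.
#' @export
setClass("FrameSeries",
  representation(phantom = "BrainPhantom", frameTimes = "numeric",
                 pbb5Maps = "list", genotype = "character",
                 doseScale = "numeric"))

setValidity("FrameSeries", function(object) {
  if (length(object@pbb5Maps) != length(object@frameTimes))
    return("one concentration map required per frame")
  d <- object@phantom@dims
  for (m in object@pbb5Maps) {
    if (!identical(dim(m), as.integer(d))) return("map dim mismatch")
    if (any(m < 0)) return("concentration maps must be nonnegative")
  }
  TRUE
})

#' Spherical-cap detection array geometry
#'
#' Detector positions on a spherical cap below the imaged volume, with a
#' constant speed of sound, a sampling clock, and a Gaussian detection-band
#' model (center frequency and fractional bandwidth).
#'
#' @slot positions N x 3 matrix of detector positions (mm).
#' @slot speedOfSound scalar, mm/us (default 1.50).
#' @slot sampleRateMHz sampling rate in MHz.
#' @slot nSamples number of time samples per trace.
#' @slot centerFreqMHz detection band center frequency (MHz).
#' @slot fractionalBandwidth full width of the Gaussian band relative to the
#'   center frequency; \code{Inf} disables band-limiting.
#' @slot weights per-detector solid-angle weights (sum to 1 at use time).
#' @export
setClass("ArrayGeometry",
  representation(positions = "matrix", speedOfSound = "numeric",
                 sampleRateMHz = "numeric", nSamples = "integer",
                 centerFreqMHz = "numeric", fractionalBandwidth = "numeric",
                 weights = "numeric"))

setValidity("ArrayGeometry", function(object) {
  if (nrow(object@positions) < 64L) return("at least 64 detectors required")
  if (ncol(object@positions) != 3L) return("positions must be N x 3")
  if (object@speedOfSound <= 0) return("speed of sound must be > 0")
  if (object@sampleRateMHz <= 0) return("sample rate must be > 0")
  if (object@nSamples < 2L) return("need at least 2 samples")
  if (length(object@weights) != nrow(object@positions))
    return("one weight per detector required")
  if (any(object@weights <= 0)) return("weights must be > 0")
  TRUE
})

#' Multi-wavelength, multi-frame detector traces
#'
#' Per-detector pressure traces for every (wavelength, frame) combination,
#' with the per-pulse laser energies used to scale them and the acquisition
#' geometry.
#'
#' @slot signals 4D array [detector x sample x wavelength x frame].
#' @slot energies matrix [wavelength x frame] of pulse energies (> 0).
#' @slot geometry the \linkS4class{ArrayGeometry}.
#' @slot wavelengths wavelengths in nm.
#' @slot frameTimes frame times in seconds.
#' @slot noiseSigma standard deviation of the additive noise applied.
#' @export
setClass("Sinogram",
  representation(signals = "array", energies = "matrix",
                 geometry = "ArrayGeometry", wavelengths = "numeric",
                 frameTimes = "numeric", noiseSigma = "numeric"))

setValidity("Sinogram", function(object) {
  d <- dim(object@signals)
  if (length(d) != 4L) return("signals must be 4D [det x sample x wl x frame]")
  g <- object@geometry
  if (d[1] != nrow(g@positions)) return("detector count mismatch")
  if (d[2] != g@nSamples) return("sample count mismatch")
  if (d[3] != length(object@wavelengths)) return("wavelength count mismatch")
  if (d[4] != length(object@frameTimes)) return("frame count mismatch")
  if (!identical(dim(object@energies), c(d[3], d[4]))) return("energies must be [wl x frame]")
  if (any(object@energies <= 0)) return("energies must be > 0")
  TRUE
})

#' Reconstructed volumes indexed by wavelength and frame
#'
#' @slot volumes 5D array [x, y, z, wavelength, frame] (a.u.).
#' @slot spacing voxel spacing (mm); @slot origin grid corner (mm).
#' @slot wavelengths nm; @slot frameTimes s.
#' @slot provenance list recording the reconstruction configuration and seed.
#' @export
setClass("VolumeStack",
  representation(volumes = "array", spacing = "numeric", origin = "numeric",
                 wavelengths = "numeric", frameTimes = "numeric",
                 provenance = "list"))

setValidity("VolumeStack", function(object) {
  d <- dim(object@volumes)
  if (length(d) != 5L) return("volumes must be 5D [x,y,z,wl,frame]")
  if (d[4] != length(object@wavelengths)) return("wavelength count mismatch")
  if (d[5] != length(object@frameTimes)) return("frame count mismatch")
  if (any(!is.finite(object@volumes))) return("volumes must be finite")
  TRUE
})

#' Per-component abundance volumes from spectral unmixing
#'
#' @slot components ordered chromophore names.
#' @slot maps named list, one 4D array [x,y,z,frame] per component (a.u.).
#' @slot wavelengthsUsed wavelengths entering the fit (nm).
#' @slot residual 4D array of per-voxel residual sum of squares.
#' @slot frameTimes frame times (s).
#' @export
setClass("AbundanceMaps",
  representation(components = "character", maps = "list",
                 wavelengthsUsed = "numeric", residual = "array",
                 frameTimes = "numeric"))

setValidity("AbundanceMaps", function(object) {
  if (!identical(sort(names(object@maps)), sort(object@components)))
    return("one map per component required")
  TRUE
})

#' Probe spectrum extracted from differential bolus images
#'
#' @slot wavelengths nm.
#' @slot values absorption values normalized to unit maximum.
#' @slot seedPoints matrix of voxel indices (rows) the spectrum was averaged
#'   over.
#' @slot timeWindow numeric(2), bolus window in seconds.
#' @export
setClass("ExtractedSpectrum",
  representation(wavelengths = "numeric", values = "numeric",
                 seedPoints = "matrix", timeWindow = "numeric"))

setValidity("ExtractedSpectrum", function(object) {
  if (length(object@values) != length(object@wavelengths))
    return("one value per wavelength required")
  if (abs(max(object@values) - 1) > 1e-12) return("values must be normalized to unit maximum")
  if (nrow(object@seedPoints) < 1L) return("at least one seed point required")
  TRUE
})

#' Gaussian profile fit for resolution characterization
#'
#' @slot positions sample positions along the profile (um).
#' @slot values sampled image values (a.u.).
#' @slot params named numeric: amplitude, center, sigma, offset.
#' @slot fwhm full width at half maximum, \code{2*sqrt(2*log(2))*sigma} (um).
#' @slot rSquared coefficient of determination of the fit.
#' @export
setClass("ProfileFit",
  representation(positions = "numeric", values = "numeric",
                 params = "numeric", fwhm = "numeric", rSquared = "numeric"))

setValidity("ProfileFit", function(object) {
  s <- object@params[["sigma"]]
  if (!is.finite(s) || s <= 0) return("sigma must be > 0")
  if (abs(object@fwhm - 2 * sqrt(2 * log(2)) * s) > 1e-6 * object@fwhm)
    return("fwhm must equal 2*sqrt(2*log(2))*sigma")
  TRUE
})

#' Regional mean intensities per frame
#'
#' Rows are named brain regions (extracranial label 0 never contributes),
#' columns acquisition frames.
#'
#' @slot values matrix region x frame of mean in-VOI intensity (a.u.).
#' @slot regionVolumes named numeric, voxels per region.
#' @slot frameTimes frame times (s).
#' @slot group group label (e.g. genotype); @slot rater rater/run tag.
#' @export
setClass("VOIReport",
  representation(values = "matrix", regionVolumes = "numeric",
                 frameTimes = "numeric", group = "character",
                 rater = "character"))

setValidity("VOIReport", function(object) {
  if (ncol(object@values) != length(object@frameTimes)) return("frame count mismatch")
  if (is.null(rownames(object@values))) return("rows must be named by region")
  TRUE
})

#' Competitive displacement dataset
#'
#' @slot conc competitor concentrations (M), increasing, > 0.
#' @slot bound matrix concentration x replicate of bound signal (a.u.).
#' @slot radioligandConc radioligand concentration [L] (M), default 5e-9.
#' @slot nonspecificLevel signal at saturating competitor (a.u.).
#' @export
setClass("BindingDataset",
  representation(conc = "numeric", bound = "matrix",
                 radioligandConc = "numeric", nonspecificLevel = "numeric"))

setValidity("BindingDataset", function(object) {
  if (any(object@conc <= 0)) return("concentrations must be > 0")
  if (any(diff(object@conc) <= 0)) return("concentrations must be increasing")
  if (nrow(object@bound) != length(object@conc)) return("one row of replicates per concentration")
  if (ncol(object@bound) < 2L) return("at least 2 replicates required")
  if (object@radioligandConc <= 0) return("radioligand concentration must be > 0")
  TRUE
})

#' Competition-fit report
#'
#' @slot model "one-site" or "two-site".
#' @slot coef named numeric: b0, ns, logIC50 (and logIC50_2, fraction for the
#'   two-site model; shared-plateau parameterization).
#' @slot ki inhibition constant(s) in M (NA until converted).
#' @slot rSquared,sse,dof fit statistics.
#' @export
setClass("FitReport",
  representation(model = "character", coef = "numeric", ki = "numeric",
                 rSquared = "numeric", sse = "numeric", dof = "numeric"))

setValidity("FitReport", function(object) {
  if (!object@model %in% c("one-site", "two-site")) return("unknown model")
  if (is.finite(object@rSquared) &&
      (object@rSquared < -1e-9 || object@rSquared > 1 + 1e-9))
    return("rSquared must lie in [0, 1]")
  if (object@model == "two-site") {
    f <- object@coef[["fraction"]]
    if (!is.finite(f) || f <= 0 || f >= 1) return("two-site fraction must lie in (0,1)")
  }
  TRUE
})
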