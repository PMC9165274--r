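#' Construct a spectral library
#'
#' @param wavelengths strictly increasing wavelengths (nm) within 400--900.
#' @param spectra matrix (wavelength x chromophore) of nonnegative absorption
#'   values with chromophore column names, or a named list of numeric vectors.
#' @param unitsTag free-text unit label; spectra are in arbitrary consistent
#'   units, so downstream abundances are reported in a.u.
#' @param sourceTag named character vector of provenance strings per
#'   chromophore (recycled if a single string).
#' @return a validated \linkS4class{SpectralLibrary}.
#' @export
SpectralLibrary <- function(wavelengths, spectra, unitsTag = "a.u.",
                            sourceTag = character()) {
  if (is.list(spectra)) spectra <- do.call(cbind, spectra)
  storage.mode(spectra) <- "double"
  if (length(sourceTag) == 0L)
    sourceTag <- setNames(rep("unspecified", ncol(spectra)), colnames(spectra))
  if (is.null(names(sourceTag)) && length(sourceTag) == 1L)
    sourceTag <- setNames(rep(sourceTag, ncol(spectra)), colnames(spectra))
  new("SpectralLibrary", wavelengths = as.numeric(wavelengths),
      spectra = spectra, unitsTag = unitsTag, sourceTag = sourceTag)
}

#' Load a chromophore spectral library from CSV
#'
#' Reads a table whose first column is the wavelength in nm and whose
#' remaining columns are per-chromophore absorption values. The whole file is
#' validated; malformed rows raise an error rather than being dropped.
#'
#' @param path CSV file; header like \code{wavelength_nm,HbO,HbR,PBB5}.
#' @param required chromophore names that must be present (default
#'   \code{c("HbO", "PBB5")}, the in vivo unmixing pair).
#' @param sourceTag provenance string(s) recorded per chromophore.
#' @return a \linkS4class{SpectralLibrary}.
#' @examples
#' lib <- loadSpectralLibrary(bundledSpectraPath())
#' peakWavelength(lib, "PBB5", c(550, 660))
#' @export
loadSpectralLibrary <- function(path, required = c("HbO", "PBB5"),
                                sourceTag = paste("loaded from", basename(path))) {
  if (!file.exists(path)) stop("spectral table not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE)
  if (ncol(tab) < 2L) stop("spectral table needs a wavelength column plus >= 1 chromophore")
  wl <- tab[[1]]
  if (any(!is.finite(wl))) stop("non-numeric wavelength entries")
  if (any(diff(wl) <= 0)) stop("non-monotone grid: wavelengths must be strictly increasing")
  spec <- as.matrix(tab[, -1, drop = FALSE])
  if (any(!is.finite(spec))) stop("non-numeric absorption entries")
  if (any(spec < 0)) stop("negative absorption values in spectral table")
  missing <- setdiff(required, colnames(spec))
  if (length(missing))
    stop("missing chromophore: ", paste(missing, collapse = ", "))
  SpectralLibrary(wl, spec, sourceTag = sourceTag)
}

#' Path to the bundled reference spectra
#'
#' Hemoglobin values are tabulated from an approximate literature compilation
#' (normalized to unit maximum); the PBB5 spectrum is synthetic — a skewed
#' Gaussian peaking at 630 nm with half-maximum span of about 590--690 nm —
#' since no numerical tabulation of the measured probe spectrum is available.
#' @return file path of the shipped CSV.
#' @export
bundledSpectraPath <- function() {
  system.file("extdata", "chromophore_spectra.csv", package = "vmsot",
              mustWork = TRUE)
}

#' Bundled spectral library
#' @inheritParams loadSpectralLibrary
#' @return a \linkS4class{SpectralLibrary} with HbO, HbR and a synthetic PBB5.
#' @export
bundledSpectralLibrary <- function(required = c("HbO", "PBB5")) {
  loadSpectralLibrary(bundledSpectraPath(), required = required,
                      sourceTag = c(HbO = "approximate literature compilation, unit-max normalized",
                                    HbR = "approximate literature compilation, unit-max normalized",
                                    PBB5 = "synthetic skewed Gaussian (peak 630 nm, half-max ~590-690 nm)"))
}

#' Interpolate a chromophore spectrum
#'
#' Linear interpolation on the library grid; queries at grid points return the
#' stored values exactly, and extrapolation is refused.
#'
#' @param lib a \linkS4class{SpectralLibrary}.
#' @param chromophore chromophore name.
#' @param queryNm wavelengths (nm) to evaluate, all inside the grid range.
#' @return numeric vector of absorption values.
#' @export
interpolateSpectrum <- function(lib, chromophore, queryNm) {
  stopifnot(is(lib, "SpectralLibrary"))
  if (!chromophore %in% colnames(lib@spectra))
    stop("unknown chromophore: ", chromophore)
  w <- lib@wavelengths
  bad <- queryNm < min(w) | queryNm > max(w)
  if (any(bad))
    stop("query wavelength outside library range: ",
         paste(queryNm[bad], collapse = ", "), " nm")
  exact <- match(queryNm, w)
  out <- numeric(length(queryNm))
  hit <- !is.na(exact)
  out[hit] <- lib@spectra[exact[hit], chromophore]
  if (any(!hit))
    out[!hit] <- stats::approx(w, lib@spectra[, chromophore],
                               xout = queryNm[!hit])$y
  out
}

#' Wavelength of maximum absorption within a window
#'
#' Returns the grid wavelength with the largest stored absorption inside the
#' window; ties break toward the lower wavelength.
#'
#' @param lib a \linkS4class{SpectralLibrary}.
#' @param chromophore chromophore name.
#' @param windowNm numeric(2) window in nm, inside the grid range.
#' @return the peak wavelength (nm).
#' @export
peakWavelength <- function(lib, chromophore, windowNm = range(lib@wavelengths)) {
  stopifnot(is(lib, "SpectralLibrary"))
  if (!chromophore %in% colnames(lib@spectra))
    stop("unknown chromophore: ", chromophore)
  w <- lib@wavelengths
  sel <- which(w >= windowNm[1] & w <= windowNm[2])
  if (length(sel) == 0L) stop("empty window: no grid points in [",
                              windowNm[1], ", ", windowNm[2], "] nm")
  v <- lib@spectra[sel, chromophore]
  w[sel][which.max(v)]   # which.max returns the first (lowest-wavelength) tie
}

# design matrix of component spectra at the requested wavelengths;
# components may be chromophore names (resolved against lib) or an
# ExtractedSpectrum / numeric vector supplied via the `extra` list
spectralDesign <- function(lib, components, wavelengthsNm, extra = list()) {
  M <- sapply(components, function(cn) {
    if (cn %in% names(extra)) {
      ex <- extra[[cn]]
      if (is(ex, "ExtractedSpectrum")) {
        stats::approx(ex@wavelengths, ex@values, xout = wavelengthsNm)$y
      } else as.numeric(ex)
    } else interpolateSpectrum(lib, cn, wavelengthsNm)
  })
  M <- matrix(M, nrow = length(wavelengthsNm),
              dimnames = list(NULL, components))
  M
}
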