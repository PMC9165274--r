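# File interfaces: NIfTI volumes (via RNifti), a flat binary sinogram
# container (JSON header + little-endian float64 payload), and VOI reports
# as commented CSV.

.writeNii <- function(arr, path, spacingMm) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(spacingMm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Export a phantom as NIfTI volumes with JSON sidecars
#'
#' Writes \code{labels.nii.gz}, \code{hbo.nii.gz}, \code{vessel.nii.gz}, a
#' \code{regions.json} sidecar (label -> name) and \code{config.json}
#' (spacing, origin, seed; voxel centers at origin + (i - 0.5) * spacing).
#'
#' @param p a \linkS4class{BrainPhantom}; @param dir output directory.
#' @return the directory, invisibly.
#' @export
exportPhantom <- function(p, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .writeNii(p@labels, file.path(dir, "labels.nii.gz"), p@spacing)
  .writeNii(p@hboMap, file.path(dir, "hbo.nii.gz"), p@spacing)
  .writeNii(p@vesselMask + 0, file.path(dir, "vessel.nii.gz"), p@spacing)
  jsonlite::write_json(as.list(p@regionNames),
                       file.path(dir, "regions.json"), auto_unbox = TRUE)
  jsonlite::write_json(list(spacing_mm = p@spacing, origin_mm = p@origin,
                            dims = p@dims, seed = p@seed),
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Export a frame series (per-frame probe maps) as NIfTI
#'
#' @param fs a \linkS4class{FrameSeries}; @param dir output directory.
#' @return the directory, invisibly.
#' @export
exportFrameSeries <- function(fs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- fs@phantom
  for (i in seq_along(fs@frameTimes))
    .writeNii(fs@pbb5Maps[[i]],
              file.path(dir, sprintf("pbb5_t%06.0fs.nii.gz",
                                     fs@frameTimes[i])), p@spacing)
  jsonlite::write_json(list(frame_times_s = fs@frameTimes,
                            genotype = fs@genotype,
                            dose_scale = fs@doseScale),
                       file.path(dir, "frames.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Write a sinogram container
#'
#' Self-describing flat container: \code{header.json} lists the datasets
#' (/signals, /energies, /wavelengths_nm, /frame_times_s,
#' /geometry/positions) with shapes, plus the attributes speed_of_sound,
#' sample_rate and noise_sigma; \code{signals.bin} holds the trace array as
#' little-endian float64 in column-major order.
#'
#' @param s a \linkS4class{Sinogram}; @param dir output directory.
#' @return the directory, invisibly.
#' @export
writeSinogram <- function(s, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(dir, "signals.bin"), "wb")
  writeBin(as.numeric(s@signals), con, size = 8, endian = "little")
  close(con)
  g <- s@geometry
  jsonlite::write_json(list(
    datasets = list(
      signals = list(file = "signals.bin", shape = dim(s@signals),
                     dtype = "float64-le"),
      energies = s@energies,
      wavelengths_nm = s@wavelengths,
      frame_times_s = s@frameTimes,
      geometry = list(positions = g@positions, weights = g@weights)),
    attributes = list(speed_of_sound_mm_us = g@speedOfSound,
                      sample_rate_mhz = g@sampleRateMHz,
                      n_samples = g@nSamples,
                      center_freq_mhz = g@centerFreqMHz,
                      fractional_bandwidth = g@fractionalBandwidth,
                      noise_sigma = s@noiseSigma)),
    file.path(dir, "header.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a sinogram container written by \code{\link{writeSinogram}}
#'
#' @param dir container directory.
#' @return a \linkS4class{Sinogram}.
#' @export
readSinogram <- function(dir) {
  h <- jsonlite::read_json(file.path(dir, "header.json"),
                           simplifyVector = TRUE)
  shape <- as.integer(h$datasets$signals$shape)
  con <- file(file.path(dir, "signals.bin"), "rb")
  sig <- readBin(con, "double", n = prod(shape), size = 8,
                 endian = "little")
  close(con)
  at <- h$attributes
  geom <- new("ArrayGeometry",
              positions = as.matrix(h$datasets$geometry$positions),
              speedOfSound = at$speed_of_sound_mm_us,
              sampleRateMHz = at$sample_rate_mhz,
              nSamples = as.integer(at$n_samples),
              centerFreqMHz = at$center_freq_mhz,
              fractionalBandwidth = at$fractional_bandwidth,
              weights = as.numeric(h$datasets$geometry$weights))
  new("Sinogram", signals = array(sig, shape),
      energies = as.matrix(h$datasets$energies), geometry = geom,
      wavelengths = as.numeric(h$datasets$wavelengths_nm),
      frameTimes = as.numeric(h$datasets$frame_times_s),
      noiseSigma = at$noise_sigma)
}

#' Export a volume stack as one NIfTI per (wavelength, frame)
#'
#' Writes \code{vol_wXXX_fYY.nii.gz} files plus an \code{index.json} with
#' grid metadata and provenance.
#'
#' @param stack a \linkS4class{VolumeStack}; @param dir output directory.
#' @return the directory, invisibly.
#' @export
exportVolumeStack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (w in seq_along(stack@wavelengths)) for (f in seq_along(stack@frameTimes))
    .writeNii(stack@volumes[, , , w, f],
              file.path(dir, sprintf("vol_w%03d_f%02d.nii.gz",
                                     round(stack@wavelengths[w]), f)),
              stack@spacing)
  jsonlite::write_json(list(wavelengths_nm = stack@wavelengths,
                            frame_times_s = stack@frameTimes,
                            spacing_mm = stack@spacing,
                            origin_mm = stack@origin,
                            provenance = stack@provenance),
                       file.path(dir, "index.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Write a VOI report as commented CSV
#'
#' Metadata lines prefixed with '#' (frame times, group, rater, region
#' volumes), then a CSV matrix with regions as rows and frames as columns.
#'
#' @param report a \linkS4class{VOIReport}; @param path output file.
#' @return the path, invisibly.
#' @export
writeVOIReport <- function(report, path) {
  con <- file(path, "w")
  writeLines(c(
    paste0("# frame_times_s: ", paste(report@frameTimes, collapse = ",")),
    paste0("# group: ", report@group),
    paste0("# rater: ", report@rater),
    paste0("# region_volumes: ",
           paste(sprintf("%s=%g", names(report@regionVolumes),
                         report@regionVolumes), collapse = ","))), con)
  df <- data.frame(region = rownames(report@values), report@values,
                   check.names = FALSE)
  colnames(df)[-1] <- sprintf("frame%02d", seq_len(ncol(report@values)))
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}

#' Read a VOI report written by \code{\link{writeVOIReport}}
#'
#' @param path CSV file.
#' @return a \linkS4class{VOIReport}.
#' @export
readVOIReport <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  getMeta <- function(key) sub(paste0("^# ", key, ": "), "",
                               grep(paste0("^# ", key, ":"), meta,
                                    value = TRUE)[1])
  ft <- as.numeric(strsplit(getMeta("frame_times_s"), ",")[[1]])
  rv <- strsplit(strsplit(getMeta("region_volumes"), ",")[[1]], "=")
  vols <- setNames(as.numeric(vapply(rv, `[`, "", 2)),
                   vapply(rv, `[`, "", 1))
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$region
  new("VOIReport", values = m, regionVolumes = vols, frameTimes = ft,
      group = getMeta("group"), rater = getMeta("rater"))
}
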