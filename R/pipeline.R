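# High-level study drivers tying the modules together. Problem sizes default
# to desk scale (32^3 voxels at 0.4 mm, 128 detectors) so a full
# multi-wavelength bolus study runs in well under five minutes.

#' Run the default in silico bolus imaging study
#'
#' Builds a phantom, renders the bolus/retention frame series, simulates the
#' multi-wavelength sinogram (600--640 nm, 10 nm step) over a reduced frame
#' schedule (pre-injection, bolus, the 3--7 min validation window, and the
#' 60-min retention frame), and reconstructs the volume stack. Returns the
#' pieces the downstream unmixing and quantification operate on, together
#' with the frame-window bookkeeping.
#'
#' @param seed study seed (phantom anatomy, energy jitter, noise).
#' @param dims,spacing reconstruction/simulation grid (default 32^3, 0.4 mm).
#' @param nDetectors detector count (default 128).
#' @param genotype "P301L" or "WT"; @param doseScale dose multiplier.
#' @param wavelengthsNm acquisition wavelengths.
#' @param noiseRel relative additive noise level (default 0.02).
#' @param tauLoadScale global multiplier on the regional tau load (used for
#'   inter-subject variability in cohort studies).
#' @param acqTimes acquisition frame times (s); must be a subset of the
#'   kinetics schedule.
#' @param lib spectral library used for simulation.
#' @return list with phantom, kinetics, frameSeries, sinogram, stack,
#'   frame-window indices (pre, bolus, val37, ret60) and the library.
#' @export
runBolusStudy <- function(seed = 1L, dims = c(32, 32, 32), spacing = 0.4,
                          nDetectors = 128L, genotype = "P301L",
                          doseScale = 1,
                          wavelengthsNm = seq(600, 640, by = 10),
                          noiseRel = 0.02, tauLoadScale = 1,
                          acqTimes = c(5, 25, 90, 120, 150, 180, 240, 330,
                                       420, 3600),
                          lib = bundledSpectralLibrary()) {
  p <- makePhantom(dims = dims, spacing = spacing, seed = seed)
  k <- kineticsConfig(genotype = genotype, doseScale = doseScale)
  k@tauLoad <- k@tauLoad * tauLoadScale
  stopifnot(all(acqTimes %in% k@frameTimes))
  fs <- renderFrames(p, k)
  frames <- match(acqTimes, k@frameTimes)
  center <- dims * spacing / 2
  geom <- makeArrayGeometry(center, nDetectors = nDetectors)
  s <- simulateSinogram(fs, lib, geom, wavelengthsNm = wavelengthsNm,
                        frames = frames, noiseRel = noiseRel, seed = seed)
  stack <- reconstructStack(s, dims, spacing)
  tA <- s@frameTimes
  tI <- k@tInject
  list(phantom = p, kinetics = k, frameSeries = fs, sinogram = s,
       stack = stack, lib = lib,
       windows = list(pre = which(tA < tI),
                      bolus = which(tA >= tI + 30 & tA <= tI + 160),
                      val37 = which(tA >= tI + 180 & tA <= tI + 420),
                      ret60 = which.min(abs(tA - 3600))),
       frames = frames)
}

#' Ground-truth probe map resampled to acquisition frames
#'
#' @param study a \code{\link{runBolusStudy}} result.
#' @param frame index into the acquired frames.
#' @return the generating probe concentration volume for that frame.
#' @export
truthPBB5 <- function(study, frame) {
  study$frameSeries@pbb5Maps[[study$frames[frame]]]
}

#' Simulate a two-genotype imaging cohort and quantify retention
#'
#' For each animal: a per-seed phantom (anatomical jitter), a subject-level
#' tau-load factor (log-normal, CV \code{subjectCv}), the acoustic forward
#' model and reconstruction at the 60-min retention frame, least-squares
#' HbO/PBB5 unmixing, and VOI means of the probe map. Group sizes default to
#' n = 3 per genotype.
#'
#' @param nPerGroup animals per genotype.
#' @param seed cohort seed.
#' @param dims,spacing,nDetectors acoustic problem size (default 24^3 at
#'   0.5 mm, 64 detectors for cohort throughput).
#' @param subjectCv inter-subject tau-load coefficient of variation.
#' @param noiseRel relative sinogram noise.
#' @return data.frame with columns value, group, region, subject.
#' @export
simulateCohort <- function(nPerGroup = 3L, seed = 1L,
                           dims = c(24, 24, 24), spacing = 0.5,
                           nDetectors = 64L, subjectCv = 0.1,
                           noiseRel = 0.02) {
  lib <- bundledSpectralLibrary()
  rows <- list()
  subj <- 0L
  for (g in c("P301L", "WT")) for (i in seq_len(nPerGroup)) {
    subj <- subj + 1L
    sseed <- seed * 1000L + subj
    tls <- withSeed(sseed + 500L, exp(stats::rnorm(1, 0, subjectCv)))
    st <- runBolusStudy(seed = sseed, dims = dims, spacing = spacing,
                        nDetectors = nDetectors, genotype = g,
                        noiseRel = noiseRel, tauLoadScale = tls,
                        acqTimes = c(5, 3600), lib = lib)
    ab <- unmixLSQ(st$stack, lib, frames = 2L)
    rep <- voiTimecourse(ab@maps[["PBB5"]], st$phantom@labels,
                         st$phantom@regionNames, ab@frameTimes, group = g)
    ret <- retention(rep, 3600)
    rows[[subj]] <- data.frame(value = unname(ret), group = g,
                               region = names(ret),
                               subject = sprintf("m%02d", subj))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
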