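#' Default kinetics configuration
#'
#' Defaults emulate the in vivo acquisition timeline on a single continuous
#' clock: injection starts at 30 s, frames cover a short pre-injection window,
#' the bolus/injection period, the 3--7 min validation window and the 20, 40,
#' 60, 90 and 120 min retention sessions. The gamma-variate bolus
#' (shape 3, scale 30 s) peaks 90 s after injection; parenchymal retention is
#' a two-compartment uptake from the vascular pool with slow washout. The
#' kinetic rate constants are stand-ins chosen to reproduce the qualitative
#' curve shapes (fast vascular transit, slow parenchymal accumulation that is
#' still present at 60 min), not fitted values.
#'
#' @param tInject injection start (s).
#' @param frameTimes acquisition frame times (s), increasing.
#' @param doseScale dose multiplier; 1 corresponds to the 25 mg/kg analogue,
#'   0.2 and 2 to the 5 and 50 mg/kg analogues.
#' @param vascularShape,vascularScale gamma-variate bolus shape/scale (s).
#' @param uptakeRate,washoutRate two-compartment rates (1/s).
#' @param genotype "P301L" or "WT".
#' @param tauLoad named region multipliers; cerebellum 0 (reference region),
#'   cortex/hippocampus 1, thalamus 0.8, remaining regions 0.3.
#' @param wtFraction fraction of tau load retained in wild-type animals
#'   (emulates non-specific binding).
#' @return a \linkS4class{KineticsConfig}.
#' @export
kineticsConfig <- function(tInject = 30,
                           frameTimes = c(5, 15, 25, 60, 90, 120, 150, 180,
                                          240, 330, 420, 600, 1200, 2400,
                                          3600, 5400, 7200),
                           doseScale = 1,
                           vascularShape = 3, vascularScale = 30,
                           uptakeRate = 5e-3, washoutRate = 2e-4,
                           genotype = "P301L",
                           tauLoad = c(cortex = 1, hippocampus = 1,
                                       thalamus = 0.8, cerebellum = 0,
                                       striatum = 0.3, olfactory_bulb = 0.3,
                                       brainstem = 0.3, midbrain = 0.3),
                           wtFraction = 0.35) {
  new("KineticsConfig", tInject = tInject, frameTimes = frameTimes,
      doseScale = doseScale, vascularShape = vascularShape,
      vascularScale = vascularScale, uptakeRate = uptakeRate,
      washoutRate = washoutRate, genotype = genotype, tauLoad = tauLoad,
      wtFraction = wtFraction)
}

# ellipsoid membership helper: squared normalized radius
.ellipsoidRho2 <- function(X, center, semi) {
  ((X[, 1] - center[1]) / semi[1])^2 + ((X[, 2] - center[2]) / semi[2])^2 +
    ((X[, 3] - center[3]) / semi[3])^2
}

#' Build an atlas-labelled brain phantom
#'
#' Deterministic (given \code{seed}) geometric stand-in for the MRI mouse
#' atlas: a brain ellipsoid subdivided into eight named regions (cortex as a
#' dorsal shell, paired hippocampi, central thalamus, posterior cerebellum,
#' paired striata, olfactory bulb, brainstem and a midbrain remainder), a
#' vessel mask including a superior sagittal sinus tube on the dorsal midline
#' with two transverse branches, and an HbO concentration map that is high in
#' vessels and moderate in parenchyma. The seed jitters region centers and
#' brain axes slightly to emulate inter-subject anatomy.
#'
#' @param dims integer(3) grid size, each <= 96.
#' @param spacing isotropic voxel spacing (mm), in [0.1, 0.5].
#' @param seed integer seed.
#' @param hboVessel,hboParenchyma HbO concentration (a.u.) in vessels and
#'   brain tissue.
#' @return a \linkS4class{BrainPhantom}.
#' @examples
#' p <- makePhantom(dims = c(32, 32, 32), spacing = 0.4, seed = 1)
#' table(p@labels[p@labels > 0])
#' @export
makePhantom <- function(dims = c(48, 48, 48), spacing = 0.25, seed = 1L,
                        hboVessel = 5, hboParenchyma = 0.5) {
  dims <- as.integer(dims)
  if (any(dims > 96L)) stop("grid too large: each dimension must be <= 96")
  if (spacing < 0.1 || spacing > 0.5) stop("spacing out of range [0.1, 0.5] mm")
  withSeed(seed, {
    fov <- dims * spacing
    ctr <- fov / 2
    X <- voxelCoordMatrix(dims, spacing)
    # brain ellipsoid semi-axes (mm), capped to fit the grid and the 15 mm FOV
    semi <- pmin(c(4.5, 5.5, 4.0) * stats::runif(3, 0.98, 1.02),
                 fov / 2 - 2 * spacing, 7.4)
    jit <- function(mu) mu + stats::rnorm(length(mu), 0, 0.1)
    rho2 <- .ellipsoidRho2(X, ctr, semi)
    brain <- rho2 <= 1
    rel <- sweep(X, 2, ctr)            # coordinates relative to brain center
    lab <- integer(nrow(X))
    regionNames <- c(`1` = "cortex", `2` = "hippocampus", `3` = "thalamus",
                     `4` = "cerebellum", `5` = "striatum",
                     `6` = "olfactory_bulb", `7` = "brainstem",
                     `8` = "midbrain")
    cereb <- brain & rel[, 2] < -0.55 * semi[2]
    olf <- brain & !cereb & rel[, 2] > 0.78 * semi[2]
    hipL <- .ellipsoidRho2(rel, jit(c(-1.8, -0.5, 0.6)), c(1.2, 1.5, 0.9)) <= 1
    hipR <- .ellipsoidRho2(rel, jit(c(1.8, -0.5, 0.6)), c(1.2, 1.5, 0.9)) <= 1
    hip <- brain & !cereb & !olf & (hipL | hipR)
    thal <- brain & !cereb & !olf & !hip &
      .ellipsoidRho2(rel, jit(c(0, -0.8, -0.2)), c(1.6, 1.3, 1.2)) <= 1
    strL <- .ellipsoidRho2(rel, jit(c(-1.8, 1.5, -0.2)), c(1.1, 1.3, 1.1)) <= 1
    strR <- .ellipsoidRho2(rel, jit(c(1.8, 1.5, -0.2)), c(1.1, 1.3, 1.1)) <= 1
    stri <- brain & !cereb & !olf & !hip & !thal & (strL | strR)
    stem <- brain & !cereb & !olf & !hip & !thal & !stri &
      rel[, 3] < -0.45 * semi[3] & rel[, 2] < 0
    cortex <- brain & !cereb & !olf & !hip & !thal & !stri & !stem &
      rho2 > 0.55 & rel[, 3] > -0.1 * semi[3]
    rest <- brain & !cereb & !olf & !hip & !thal & !stri & !stem & !cortex
    lab[cortex] <- 1L; lab[hip] <- 2L; lab[thal] <- 3L; lab[cereb] <- 4L
    lab[stri] <- 5L; lab[olf] <- 6L; lab[stem] <- 7L; lab[rest] <- 8L
    labels <- array(lab, dims)

    # superior sagittal sinus: dorsal midline tube following the brain surface
    zTop <- ctr[3] + semi[3] * sqrt(pmax(0, 1 - ((X[, 2] - ctr[2]) / semi[2])^2))
    sss <- lab > 0L & abs(X[, 1] - ctr[1]) <= max(0.35, 0.75 * spacing) &
      X[, 3] > zTop - 1.0 & rel[, 2] > -0.55 * semi[2]
    # two transverse surface branches
    zTopX <- ctr[3] + semi[3] * sqrt(pmax(0, 1 - ((X[, 1] - ctr[1]) / semi[1])^2))
    br <- lab > 0L & X[, 3] > pmin(zTop, zTopX) - 1.0 &
      (abs(X[, 2] - (ctr[2] + 1.5)) <= max(0.3, 0.6 * spacing) |
       abs(X[, 2] - (ctr[2] - 1.5)) <= max(0.3, 0.6 * spacing))
    vessel <- array(sss | br, dims)

    hbo <- numeric(nrow(X))
    hbo[lab > 0L] <- hboParenchyma * stats::runif(sum(lab > 0L), 0.9, 1.1)
    hbo[c(vessel)] <- hboVessel * stats::runif(sum(vessel), 0.95, 1.05)
    new("BrainPhantom", dims = dims, spacing = spacing, origin = c(0, 0, 0),
        labels = labels, regionNames = regionNames, vesselMask = vessel,
        hboMap = array(hbo, dims), seed = as.integer(seed))
  })
}

#' Probe concentration in a compartment at time t
#'
#' Vascular pool: gamma-variate bolus \eqn{dose \cdot ((\tau/\alpha\beta)^\alpha
#' e^{\alpha - \tau/\beta})} with \eqn{\tau = t - t_{inject}} (unit peak at
#' \eqn{\tau = \alpha\beta}). Parenchymal regions: two-compartment uptake from
#' the vascular pool, \eqn{k_{in} \cdot tauLoad \cdot \int_0^\tau C_v(s)
#' e^{-k_{out}(\tau - s)} ds}, evaluated in closed form via the incomplete
#' gamma function. Both are zero before the injection and scale linearly with
#' the dose. Wild-type genotype multiplies the tau load by \code{wtFraction}.
#'
#' @param k a \linkS4class{KineticsConfig}.
#' @param t time(s) in seconds (vectorized).
#' @param compartment "vascular" or a region name present in \code{tauLoad}.
#' @return concentration(s) in a.u.
#' @export
bolusConcentration <- function(k, t, compartment = "vascular") {
  stopifnot(is(k, "KineticsConfig"))
  a <- k@vascularShape; b <- k@vascularScale
  tau <- pmax(0, t - k@tInject)
  gv <- ifelse(tau > 0, (tau / (a * b))^a * exp(a - tau / b), 0)
  if (identical(compartment, "vascular")) return(k@doseScale * gv)
  if (!compartment %in% names(k@tauLoad))
    stop("unknown compartment: ", compartment)
  load <- k@tauLoad[[compartment]] *
    (if (k@genotype == "WT") k@wtFraction else 1)
  if (load == 0) return(rep(0, length(t)))
  kout <- k@washoutRate
  r <- 1 / b - kout
  # \int_0^tau s^a exp(-r s) ds scaled by the gamma-variate prefactor
  if (r > 0) {
    integral <- exp(a) * (a * b)^(-a) * exp(-kout * tau) *
      gamma(a + 1) * stats::pgamma(r * tau, a + 1) / r^(a + 1)
  } else {
    integral <- vapply(tau, function(tt) {
      if (tt <= 0) return(0)
      stats::integrate(function(s) (s / (a * b))^a * exp(a - s / b) *
                         exp(-kout * (tt - s)), 0, tt)$value
    }, numeric(1))
  }
  k@doseScale * k@uptakeRate * load * integral
}

#' Render per-frame probe concentration maps
#'
#' Vessel voxels carry the vascular bolus concentration; voxels of each
#' labelled region carry that region's parenchymal concentration. All maps
#' are zero before the injection time.
#'
#' @param p a \linkS4class{BrainPhantom}.
#' @param k a \linkS4class{KineticsConfig}.
#' @return a \linkS4class{FrameSeries}.
#' @export
renderFrames <- function(p, k) {
  stopifnot(is(p, "BrainPhantom"), is(k, "KineticsConfig"))
  labs <- as.integer(names(p@regionNames))
  maps <- lapply(k@frameTimes, function(t) {
    m <- array(0, p@dims)
    for (l in labs) {
      nm <- p@regionNames[[as.character(l)]]
      if (!nm %in% names(k@tauLoad)) next
      cp <- bolusConcentration(k, t, nm)
      if (cp > 0) m[p@labels == l] <- cp
    }
    m[p@vesselMask] <- bolusConcentration(k, t, "vascular")
    m
  })
  new("FrameSeries", phantom = p, frameTimes = k@frameTimes, pbb5Maps = maps,
      genotype = k@genotype, doseScale = k@doseScale)
}

#' Planar epi-fluorescence analogue readout
#'
#' Depth-weighted sum of the probe concentration over the dorsal cortical
#' shell, with exponential depth weighting from the dorsal brain surface —
#' a surface-weighted scalar analogue of the epi-fluorescence channel.
#'
#' @param fs a \linkS4class{FrameSeries}.
#' @param lengthConstantMm exponential depth length constant (mm), default 1.
#' @return numeric vector, one readout per frame (a.u.).
#' @export
planarFluorescenceReadout <- function(fs, lengthConstantMm = 1) {
  p <- fs@phantom
  cortexLab <- as.integer(names(p@regionNames)[p@regionNames == "cortex"])
  sel <- which(p@labels == cortexLab)
  if (length(sel) == 0L) stop("phantom has no cortex label")
  zc <- voxelCenters(p@dims, p@spacing, p@origin)[[3]]
  zIdx <- ((sel - 1L) %/% (p@dims[1] * p@dims[2])) + 1L
  zTop <- max(zc[((which(p@labels > 0L) - 1L) %/%
                    (p@dims[1] * p@dims[2])) + 1L])
  w <- exp(-(zTop - zc[zIdx]) / lengthConstantMm)
  vapply(fs@pbb5Maps, function(m) sum(m[sel] * w), numeric(1))
}

#' Pick vessel seed voxels for probe-spectrum extraction
#'
#' Deterministically selects dorsal vessel voxels (the superior sagittal
#' sinus region), spread along the anterior-posterior axis.
#'
#' @param p a \linkS4class{BrainPhantom}.
#' @param n number of seed voxels.
#' @return integer matrix n x 3 of voxel indices.
#' @export
suggestVesselSeeds <- function(p, n = 5L) {
  idx <- which(p@vesselMask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("phantom has an empty vessel mask")
  # dorsal-most quarter of vessel voxels, spread along y
  ord <- order(idx[, 3], decreasing = TRUE)
  top <- idx[ord[seq_len(max(n, ceiling(nrow(idx) / 4)))], , drop = FALSE]
  top <- top[order(top[, 2]), , drop = FALSE]
  pick <- unique(round(seq(1, nrow(top), length.out = min(n, nrow(top)))))
  unname(top[pick, , drop = FALSE])
}
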