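#' Baseline-subtracted differential image
#'
#' Mean over the post-injection frame window minus mean over the
#' pre-injection window, at one wavelength.
#'
#' @param stack a \linkS4class{VolumeStack}.
#' @param preWindow,postWindow non-empty, disjoint frame index vectors.
#' @param wavelength wavelength (nm) present in the stack.
#' @return a 3D differential volume.
#' @export
baselineSubtract <- function(stack, preWindow, postWindow,
                             wavelength = stack@wavelengths[1]) {
  stopifnot(is(stack, "VolumeStack"))
  if (length(preWindow) == 0L || length(postWindow) == 0L)
    stop("empty frame window")
  if (length(intersect(preWindow, postWindow)))
    stop("pre and post windows must be disjoint")
  wi <- match(wavelength, stack@wavelengths)
  if (is.na(wi)) stop("wavelength not in stack: ", wavelength)
  pre <- apply(stack@volumes[, , , wi, preWindow, drop = FALSE], 1:3, mean)
  post <- apply(stack@volumes[, , , wi, postWindow, drop = FALSE], 1:3, mean)
  post - pre
}

#' Extract the probe spectrum from bolus-phase vessel voxels
#'
#' For every wavelength, averages the baseline-subtracted image over the
#' bolus frames and the supplied vessel seed voxels, then normalizes the
#' resulting spectrum to unit maximum — the data-driven estimate of the
#' circulating probe's absorption spectrum.
#'
#' @param stack a \linkS4class{VolumeStack}.
#' @param preWindow,bolusWindow frame index vectors (disjoint, non-empty).
#' @param seeds integer matrix (n x 3) of vessel voxel indices.
#' @return an \linkS4class{ExtractedSpectrum}.
#' @export
extractProbeSpectrum <- function(stack, preWindow, bolusWindow, seeds) {
  stopifnot(is(stack, "VolumeStack"), nrow(seeds) >= 1L)
  vals <- vapply(stack@wavelengths, function(wl) {
    dv <- baselineSubtract(stack, preWindow, bolusWindow, wl)
    mean(dv[seeds])
  }, numeric(1))
  mx <- max(vals)
  if (mx <= 0) stop("extracted spectrum is non-positive; cannot normalize")
  new("ExtractedSpectrum", wavelengths = stack@wavelengths,
      values = vals / mx, seedPoints = seeds,
      timeWindow = range(stack@frameTimes[bolusWindow]))
}

# exact small-K nonnegative least squares by active-set enumeration;
# M is W x K, Y is W x n; returns K x n coefficients
.nnlsSmall <- function(M, Y) {
  K <- ncol(M)
  n <- ncol(Y)
  best <- matrix(0, K, n)
  bestSSE <- colSums(Y^2)        # all-zero solution
  subsets <- lapply(seq_len(2^K - 1), function(b) which(bitwAnd(b, 2^(seq_len(K) - 1)) > 0))
  for (sub in subsets) {
    Ms <- M[, sub, drop = FALSE]
    A <- tryCatch(solve(crossprod(Ms), crossprod(Ms, Y)),
                  error = function(e) NULL)
    if (is.null(A)) next
    feas <- colSums(A < -1e-12) == 0
    if (!any(feas)) next
    R <- Y - Ms %*% A
    sse <- colSums(R^2)
    upd <- feas & sse < bestSSE - 1e-15
    if (any(upd)) {
      bestSSE[upd] <- sse[upd]
      best[, upd] <- 0
      best[sub, upd] <- pmax(A[, upd, drop = FALSE], 0)
    }
  }
  best
}

#' Per-voxel linear least-squares spectral unmixing
#'
#' Fits every voxel's multi-wavelength signal as a linear combination of the
#' component spectra (default: HbO and PBB5 over 600--640 nm). The solution
#' is the unconstrained least-squares estimate by default; negative
#' abundances are reported, not clipped. An optional nonnegativity constraint
#' is available. The design matrix must be well conditioned (condition
#' number below \code{maxCondition}); a rank-deficient design is an error.
#'
#' @param stack a \linkS4class{VolumeStack}.
#' @param lib a \linkS4class{SpectralLibrary} (or NULL if all components are
#'   supplied via \code{extra}).
#' @param components component names, default \code{c("HbO", "PBB5")}.
#' @param wavelengthsNm wavelength subset used for the fit (>= 2), default
#'   the stack wavelengths within 600--640 nm.
#' @param frames frames to unmix (default all).
#' @param extra named list mapping a component name to an
#'   \linkS4class{ExtractedSpectrum} (or numeric vector on
#'   \code{wavelengthsNm}) overriding the library spectrum.
#' @param nonneg use nonnegative least squares instead.
#' @param maxCondition condition-number threshold for the design (1e6).
#' @return an \linkS4class{AbundanceMaps} with per-voxel residual SSE.
#' @export
unmixLSQ <- function(stack, lib = bundledSpectralLibrary(),
                     components = c("HbO", "PBB5"),
                     wavelengthsNm = NULL, frames = seq_along(stack@frameTimes),
                     extra = list(), nonneg = FALSE, maxCondition = 1e6) {
  stopifnot(is(stack, "VolumeStack"))
  if (is.null(wavelengthsNm))
    wavelengthsNm <- stack@wavelengths[stack@wavelengths >= 600 &
                                         stack@wavelengths <= 640]
  if (length(wavelengthsNm) < 2L) stop("need at least 2 wavelengths")
  wi <- match(wavelengthsNm, stack@wavelengths)
  if (anyNA(wi))
    stop("wavelength outside stack: ",
         paste(wavelengthsNm[is.na(wi)], collapse = ", "))
  M <- spectralDesign(lib, components, wavelengthsNm, extra)
  kap <- kappa(M, exact = TRUE)
  if (!is.finite(kap) || kap > maxCondition)
    stop("rank-deficient design: component spectra are not linearly ",
         "independent on the chosen wavelengths (condition number ",
         format(kap, digits = 3), ")")
  d <- dim(stack@volumes)[1:3]
  nvox <- prod(d)
  mapArr <- lapply(components, function(cn) array(0, c(d, length(frames))))
  names(mapArr) <- components
  resid <- array(0, c(d, length(frames)))
  MtMinv <- solve(crossprod(M))
  for (fi in seq_along(frames)) {
    Y <- t(matrix(stack@volumes[, , , wi, frames[fi]], nrow = nvox))
    A <- if (nonneg) .nnlsSmall(M, Y) else MtMinv %*% crossprod(M, Y)
    R <- Y - M %*% A
    for (ci in seq_along(components))
      mapArr[[ci]][, , , fi] <- A[ci, ]
    resid[, , , fi] <- colSums(R^2)
  }
  new("AbundanceMaps", components = components, maps = mapArr,
      wavelengthsUsed = wavelengthsNm, residual = resid,
      frameTimes = stack@frameTimes[frames])
}

# ---- Vertex Component Analysis ------------------------------------------

# VCA endmember extraction on an L x N data matrix (bands x pixels),
# following the SNR-adaptive projective/PCA subspace construction and
# iterative orthogonal-projection vertex selection; RNG use is confined to
# the random direction vectors and is seeded by the caller.
.vca <- function(Y, p, seed = 1L) {
  L <- nrow(Y); N <- ncol(Y)
  if (p > L) stop("more endmembers than bands")
  svFull <- svd(Y, nu = 0, nv = 0)
  if (sum(svFull$d > max(svFull$d) * 1e-9) < p)
    stop("rank deficient: data do not support ", p, " endmembers")
  rMean <- rowMeans(Y)
  Y0 <- Y - rMean
  sv0 <- svd(Y0, nu = min(p, L), nv = 0)
  Udc <- sv0$u[, seq_len(min(p, ncol(sv0$u))), drop = FALSE]
  # SNR estimate from the energy captured by the p-dim signal subspace
  Pr <- sum(Y^2) / N
  Prp <- sum((crossprod(Udc, Y0))^2) / N + sum(rMean^2)
  snr <- 10 * log10(max((Prp - p / L * Pr), .Machine$double.eps) /
                      max(Pr - Prp, .Machine$double.eps))
  snrTh <- 15 + 10 * log10(p)
  if (snr > snrTh) {
    # high SNR: project onto the p-dim subspace of the *uncentered* data,
    # then projective (conic-to-simplex) scaling
    d <- p
    Ud <- svd(Y, nu = p, nv = 0)$u
    X <- crossprod(Ud, Y)
    u <- rowMeans(X)
    denom <- colSums(X * u)
    denom[abs(denom) < .Machine$double.eps] <- .Machine$double.eps
    ysel <- X / rep(denom, each = d)
  } else {
    # low SNR: (p-1)-dim centered subspace plus a constant coordinate
    d <- max(p - 1L, 1L)
    Ud <- sv0$u[, seq_len(d), drop = FALSE]
    X <- crossprod(Ud, Y0)
    cmax <- sqrt(max(colSums(X^2)))
    ysel <- rbind(X, cmax)
  }
  dd <- nrow(ysel)
  A <- matrix(0, dd, p)
  A[dd, 1] <- 1
  indices <- integer(p)
  withSeed(seed, {
    for (i in seq_len(p)) {
      wdir <- stats::rnorm(dd)
      f <- wdir - A %*% MASS_ginv(A) %*% wdir
      nf <- sqrt(sum(f^2))
      if (nf < .Machine$double.eps) f <- wdir else f <- f / nf
      v <- crossprod(ysel, f)
      indices[i] <- which.max(abs(v))
      A[, i] <- ysel[, indices[i]]
    }
  })
  list(indices = indices, endmembers = Y[, indices, drop = FALSE], snr = snr)
}

# minimal Moore-Penrose pseudoinverse (avoids importing MASS for one call)
MASS_ginv <- function(A, tol = sqrt(.Machine$double.eps)) {
  s <- svd(A)
  pos <- s$d > max(tol * s$d[1], 0)
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, pos, drop = FALSE] %*% ((1 / s$d[pos]) * t(s$u[, pos, drop = FALSE]))
}

#' Blind endmember extraction by vertex component analysis
#'
#' Extracts \code{n} endmember spectra from a single-frame multiwavelength
#' volume under the pure-pixel assumption (VCA: SNR-adaptive subspace
#' projection and iterative orthogonal-projection vertex selection), then
#' estimates abundances by least squares against the extracted endmembers.
#' Used for the ex vivo analysis over 600--655 nm (5 nm step).
#'
#' @param stack a \linkS4class{VolumeStack}.
#' @param n number of endmembers (2--4), at most the number of wavelengths.
#' @param wavelengthsNm wavelength subset (default all stack wavelengths).
#' @param frame frame index (default 1).
#' @param seed RNG seed for the random projection directions.
#' @return list with \code{endmembers} (matrix wavelength x n),
#'   \code{indices} (pure-pixel voxel indices), \code{snrDb}, and
#'   \code{abundances} (an \linkS4class{AbundanceMaps} with components
#'   "EM1"..."EMn").
#' @export
unmixVCA <- function(stack, n = 2L, wavelengthsNm = stack@wavelengths,
                     frame = 1L, seed = 1L) {
  stopifnot(is(stack, "VolumeStack"))
  n <- as.integer(n)
  if (n < 2L || n > 4L) stop("n must be 2-4")
  wi <- match(wavelengthsNm, stack@wavelengths)
  if (anyNA(wi)) stop("wavelength outside stack")
  if (n > length(wi)) stop("more endmembers than wavelengths")
  d <- dim(stack@volumes)[1:3]
  Y <- t(matrix(stack@volumes[, , , wi, frame], nrow = prod(d)))
  res <- .vca(Y, n, seed = seed)
  comp <- paste0("EM", seq_len(n))
  M <- res$endmembers
  colnames(M) <- comp
  A <- solve(crossprod(M), crossprod(M, Y))
  R <- Y - M %*% A
  mapArr <- lapply(seq_len(n), function(i) array(A[i, ], c(d, 1L)))
  names(mapArr) <- comp
  ab <- new("AbundanceMaps", components = comp, maps = mapArr,
            wavelengthsUsed = wavelengthsNm,
            residual = array(colSums(R^2), c(d, 1L)),
            frameTimes = stack@frameTimes[frame])
  list(endmembers = M, indices = res$indices, snrDb = res$snr,
       abundances = ab)
}

#' Spectral angle between two spectra
#'
#' @param a,b numeric vectors on a common wavelength grid.
#' @return angle in radians (scale-invariant).
#' @export
spectralAngle <- function(a, b) {
  acos(pmin(1, pmax(-1, sum(a * b) / sqrt(sum(a^2) * sum(b^2)))))
}

#' Correlate the unmixed probe map against the differential image
#'
#' The validation logic for the unmixing configuration: Pearson correlation,
#' over in-mask voxels, between the unmixed probe abundance averaged over a
#' time window and the baseline-subtracted single-wavelength (640 nm) image
#' averaged over the same window.
#'
#' @param pbb5Avg averaged unmixed probe volume.
#' @param diff640Avg averaged differential 640 nm volume (same shape).
#' @param brainMask logical volume of in-brain voxels.
#' @return Pearson correlation coefficient.
#' @export
crosscheckUnmixing <- function(pbb5Avg, diff640Avg, brainMask) {
  stopifnot(identical(dim(pbb5Avg), dim(diff640Avg)),
            identical(dim(pbb5Avg), dim(brainMask)))
  x <- pbb5Avg[brainMask]; y <- diff640Avg[brainMask]
  if (length(x) == 0L) stop("empty brain mask")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  stats::cor(x, y)
}
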