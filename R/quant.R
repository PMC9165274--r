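#' Sample a straight-line image profile
#'
#' Trilinear sampling of a volume along the segment from \code{startMm} to
#' \code{endMm} at a fixed step; used for resolution characterization.
#'
#' @param volume 3D array.
#' @param startMm,endMm segment endpoints in mm (must lie inside the volume).
#' @param spacingMm voxel spacing (mm); @param origin grid corner (mm).
#' @param stepUm sampling step along the segment in micrometers.
#' @return list with \code{positionsUm} (length \code{floor(L/step)+1}) and
#'   \code{values}.
#' @export
extractProfile <- function(volume, startMm, endMm, spacingMm,
                           origin = c(0, 0, 0), stepUm = 25) {
  d <- dim(volume)
  toIdx <- function(p) (p - origin) / spacingMm + 0.5
  for (p in list(startMm, endMm)) {
    i <- toIdx(p)
    if (any(i < 0.5) || any(i > d + 0.5))
      stop("profile endpoint outside volume: ", paste(p, collapse = ", "))
  }
  lenUm <- sqrt(sum((endMm - startMm)^2)) * 1000
  nSteps <- floor(lenUm / stepUm)
  tfrac <- (0:nSteps) * stepUm / lenUm
  pts <- outer(tfrac, endMm - startMm) + matrix(startMm, nSteps + 1, 3,
                                                byrow = TRUE)
  idx <- (pts - matrix(origin, nSteps + 1, 3, byrow = TRUE)) / spacingMm + 0.5
  list(positionsUm = (0:nSteps) * stepUm, values = trilinear(volume, idx))
}

#' Gaussian fit of a profile and its full width at half maximum
#'
#' Nonlinear least squares of \eqn{A \exp(-(x - \mu)^2 / 2\sigma^2) + c},
#' initialized from the profile maximum, argmax, second-moment width and
#' minimum. The spatial resolution estimate is
#' \eqn{FWHM = 2\sqrt{2 \ln 2}\,\hat\sigma \approx 2.3548\,\hat\sigma}.
#'
#' @param positionsUm,values the profile (>= 5 samples, non-constant).
#' @return a \linkS4class{ProfileFit}.
#' @export
fitFWHM <- function(positionsUm, values) {
  if (length(values) < 5L) stop("need at least 5 profile samples")
  if (stats::sd(values) == 0) stop("constant profile: nothing to fit")
  x <- as.numeric(positionsUm); y <- as.numeric(values)
  off0 <- min(y); amp0 <- max(y) - off0
  mu0 <- x[which.max(y)]
  wts <- pmax(y - off0, 0)
  sig0 <- sqrt(sum(wts * (x - sum(wts * x) / sum(wts))^2) / sum(wts))
  if (!is.finite(sig0) || sig0 <= 0) sig0 <- diff(range(x)) / 6
  fit <- minpack.lm::nlsLM(
    y ~ A * exp(-(x - mu)^2 / (2 * sigma^2)) + off,
    start = list(A = amp0, mu = mu0, sigma = sig0, off = off0),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  sigma <- abs(cf[["sigma"]])
  sse <- sum(stats::resid(fit)^2)
  r2 <- 1 - sse / sum((y - mean(y))^2)
  new("ProfileFit", positions = x, values = y,
      params = c(amplitude = cf[["A"]], center = cf[["mu"]], sigma = sigma,
                 offset = cf[["off"]]),
      fwhm = 2 * sqrt(2 * log(2)) * sigma, rSquared = r2)
}

#' Regional mean time courses over atlas VOIs
#'
#' Per region and frame, the mean intensity over in-region voxels. The
#' extracranial background (label \code{excludeLabel}, default 0) never
#' contributes, implementing the atlas-mask removal of extracranial signal.
#'
#' @param maps 4D array [x, y, z, frame] (e.g. a component of
#'   \linkS4class{AbundanceMaps}) or a list of 3D arrays.
#' @param labels integer VOI label volume matching the grid.
#' @param regionNames named character (label -> region name).
#' @param frameTimes frame times (s).
#' @param excludeLabel background label, default 0.
#' @param group,rater metadata tags.
#' @return a \linkS4class{VOIReport}.
#' @export
voiTimecourse <- function(maps, labels, regionNames, frameTimes,
                          excludeLabel = 0L, group = "NA", rater = "run1") {
  if (is.list(maps)) {
    d <- dim(maps[[1]])
    maps <- array(unlist(maps), c(d, length(maps)))
  }
  stopifnot(identical(dim(maps)[1:3], dim(labels)))
  nf <- dim(maps)[4]
  labs <- as.integer(names(regionNames))
  labs <- labs[labs != excludeLabel]
  vals <- matrix(0, length(labs), nf,
                 dimnames = list(regionNames[as.character(labs)], NULL))
  vols <- setNames(numeric(length(labs)), regionNames[as.character(labs)])
  flat <- matrix(maps, ncol = nf)
  for (i in seq_along(labs)) {
    sel <- which(labels == labs[i])
    if (length(sel) == 0L)
      stop("empty region: ", regionNames[as.character(labs[i])])
    vols[i] <- length(sel)
    vals[i, ] <- colMeans(flat[sel, , drop = FALSE])
  }
  new("VOIReport", values = vals, regionVolumes = vols,
      frameTimes = as.numeric(frameTimes), group = group, rater = rater)
}

#' Regional retention values at a stated time
#'
#' Values of the frame nearest to \code{tS} (within \code{toleranceS}).
#'
#' @param report a \linkS4class{VOIReport}.
#' @param tS target time (s), e.g. 3600 for the 60-min retention.
#' @param toleranceS maximal allowed |frame time - tS| (default 300 s).
#' @param ratioTo optional reference region name (e.g. "cerebellum"); when
#'   given, values are divided by that region's retention. Absolute a.u. is
#'   the default.
#' @return named numeric, region -> retention value (a.u., or ratio).
#' @export
retention <- function(report, tS, toleranceS = 300, ratioTo = NULL) {
  stopifnot(is(report, "VOIReport"))
  dt <- abs(report@frameTimes - tS)
  i <- which.min(dt)
  if (dt[i] > toleranceS)
    stop("no frame within ", toleranceS, " s of t = ", tS, " s")
  out <- setNames(report@values[, i], rownames(report@values))
  if (!is.null(ratioTo)) {
    if (!ratioTo %in% names(out)) stop("reference region not in report: ", ratioTo)
    if (out[[ratioTo]] == 0) stop("reference region retention is zero")
    out <- out / out[[ratioTo]]
  }
  out
}

#' Two-way ANOVA with Bonferroni post hoc group comparisons
#'
#' Fixed-effects two-factor analysis of variance (group, region,
#' interaction) on a balanced subjects-within-cell design, followed by
#' per-region pooled-variance two-sample t tests whose p values are
#' Bonferroni-multiplied by the number of regions (capped at 1). Unbalanced
#' designs are a hard error so the sums-of-squares decomposition stays
#' unambiguous.
#'
#' @param data data.frame with columns \code{value}, \code{group} (2 levels)
#'   and \code{region} (>= 2 levels), >= 2 subjects per cell.
#' @return list with \code{anova} (data.frame of effects: df, sum of
#'   squares, F, p) and \code{posthoc} (data.frame region, meanDiff, t, p,
#'   pAdjusted).
#' @export
twoWayAnovaBonferroni <- function(data) {
  stopifnot(all(c("value", "group", "region") %in% names(data)))
  data$group <- factor(data$group); data$region <- factor(data$region)
  if (nlevels(data$group) < 2L || nlevels(data$region) < 2L)
    stop("need >= 2 groups and >= 2 regions")
  tab <- table(data$group, data$region)
  if (length(unique(c(tab))) != 1L)
    stop("unbalanced design: equal subjects per cell required")
  if (tab[1] < 2L) stop("need >= 2 subjects per cell")
  fit <- stats::aov(value ~ group * region, data = data)
  sm <- summary(fit)[[1]]
  an <- data.frame(effect = trimws(rownames(sm)), df = sm$Df,
                   sumsq = sm$`Sum Sq`, F = sm$`F value`, p = sm$`Pr(>F)`,
                   row.names = NULL)
  regions <- levels(data$region)
  g <- levels(data$group)
  ph <- do.call(rbind, lapply(regions, function(r) {
    x <- data$value[data$group == g[1] & data$region == r]
    y <- data$value[data$group == g[2] & data$region == r]
    if (stats::sd(c(x, y)) == 0) {
      data.frame(region = r, meanDiff = 0, t = 0, p = 1, pAdjusted = 1)
    } else {
      tt <- stats::t.test(x, y, var.equal = TRUE)
      data.frame(region = r, meanDiff = mean(x) - mean(y),
                 t = unname(tt$statistic), p = tt$p.value,
                 pAdjusted = min(1, tt$p.value * length(regions)))
    }
  }))
  list(anova = an, posthoc = ph)
}

#' Two-tailed pooled-variance t test
#'
#' @param x,y numeric samples (n >= 2 each).
#' @return list with \code{t} and \code{p}.
#' @export
tTestTwoTailed <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::sd(c(x, y)) == 0) return(list(t = 0, p = 1))
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Pearson (or Spearman) correlation with p value
#'
#' The in vivo comparisons use Pearson's linear correlation; a Spearman
#' option is provided.
#'
#' @param x,y numeric vectors, non-constant.
#' @param method "pearson" (default) or "spearman".
#' @return list with \code{r} and \code{p}.
#' @export
pearsonCorrelation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Test-retest / interrater reliability of the VOI analysis
#'
#' Pearson correlation between two reports' regional values over their
#' shared regions (all frames pooled). At least 3 shared regions are
#' required.
#'
#' @param reportA,reportB \linkS4class{VOIReport}s on matching frames.
#' @return list with \code{r}, \code{p} and \code{regions}.
#' @export
reliability <- function(reportA, reportB) {
  shared <- intersect(rownames(reportA@values), rownames(reportB@values))
  if (length(shared) < 3L) stop("need >= 3 shared regions")
  a <- c(reportA@values[shared, , drop = FALSE])
  b <- c(reportB@values[shared, , drop = FALSE])
  res <- pearsonCorrelation(a, b)
  c(res, list(regions = shared))
}

#' Jitter VOI labels to emulate a second rater
#'
#' Erodes (or dilates) every region mask by whole voxels; eroded voxels fall
#' back to background. Re-running \code{\link{voiTimecourse}} with the
#' jittered labels provides the perturbation harness behind the
#' interrater-reliability analysis.
#'
#' @param labels integer label volume.
#' @param mode "erode" or "dilate"; @param iterations voxel count.
#' @return jittered label volume.
#' @export
jitterLabels <- function(labels, mode = c("erode", "dilate"),
                         iterations = 1L) {
  mode <- match.arg(mode)
  out <- array(0L, dim(labels))
  for (l in sort(unique(labels[labels > 0L]))) {
    m <- labels == l
    m2 <- if (mode == "erode") erodeMask(m, iterations) else
      dilateMask(m, iterations) & (labels == 0L | labels == l)
    out[m2] <- l
  }
  # keep every region non-empty: fall back to the original mask if erosion
  # removed a region entirely
  for (l in sort(unique(labels[labels > 0L])))
    if (!any(out == l)) out[labels == l] <- l
  out
}
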