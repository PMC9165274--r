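#' Simulate a competitive displacement dataset
#'
#' One-site model: \eqn{B(c) = NS + (B_0 - NS) / (1 + c/IC_{50})}; two-site:
#' fraction-weighted sum of two such terms with shared plateaus. Replicates
#' receive multiplicative Gaussian noise of coefficient of variation
#' \code{noiseCv}; deterministic per seed. Defaults emulate the in vitro
#' assay: 12 competitor concentrations spanning 1e-11 to 5e-7 M,
#' quadruplicates, 5 nM radioligand.
#'
#' @param b0,ns top (total binding) and bottom (non-specific) plateaus (a.u.).
#' @param ic50 IC50 in M (length 1 for one-site, 2 for two-site).
#' @param fraction high-affinity site fraction (two-site only).
#' @param conc competitor concentrations (M), increasing.
#' @param replicates number of replicates per concentration (default 4).
#' @param noiseCv multiplicative noise CV (>= 0).
#' @param radioligandConc radioligand concentration [L] in M (default 5e-9).
#' @param seed RNG seed.
#' @return a \linkS4class{BindingDataset}.
#' @export
simulateDisplacement <- function(b0 = 100, ns = 10, ic50 = 1e-7,
                                 fraction = NA_real_,
                                 conc = 10^seq(log10(1e-11), log10(5e-7),
                                               length.out = 12),
                                 replicates = 4L, noiseCv = 0.05,
                                 radioligandConc = 5e-9, seed = 1L) {
  if (noiseCv < 0) stop("noiseCv must be >= 0")
  mu <- displacementModel(conc, b0, ns, ic50, fraction)
  bound <- withSeed(seed, {
    noise <- matrix(stats::rnorm(length(conc) * replicates, 0, noiseCv),
                    length(conc), replicates)
    mu * (1 + noise)
  })
  new("BindingDataset", conc = conc, bound = bound,
      radioligandConc = radioligandConc, nonspecificLevel = ns)
}

#' Competition-model mean response
#'
#' @inheritParams simulateDisplacement
#' @param conc concentrations (M).
#' @return expected bound signal at each concentration.
#' @export
displacementModel <- function(conc, b0, ns, ic50, fraction = NA_real_) {
  if (length(ic50) == 1L) {
    ns + (b0 - ns) / (1 + conc / ic50)
  } else {
    if (!is.finite(fraction) || fraction <= 0 || fraction >= 1)
      stop("two-site model needs fraction in (0,1)")
    ns + (b0 - ns) * (fraction / (1 + conc / ic50[1]) +
                        (1 - fraction) / (1 + conc / ic50[2]))
  }
}

# single nlsLM attempt for a given model/starts; returns NULL on failure
.fitAttempt <- function(lc, y, model, start) {
  fml <- if (model == "one-site") {
    y ~ ns + (b0 - ns) / (1 + 10^(lc - p1))
  } else {
    y ~ ns + (b0 - ns) * (f / (1 + 10^(lc - p1)) +
                            (1 - f) / (1 + 10^(lc - p2)))
  }
  lower <- if (model == "one-site") c(-Inf, -Inf, min(lc) - 4) else
    c(-Inf, -Inf, min(lc) - 4, min(lc) - 4, 1e-3)
  upper <- if (model == "one-site") c(Inf, Inf, max(lc) + 4) else
    c(Inf, Inf, max(lc) + 4, max(lc) + 4, 1 - 1e-3)
  tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      fml, start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 300))),
    error = function(e) NULL)
}

#' Fit a competitive-binding model
#'
#' Nonlinear least squares in log10-concentration space with multi-start
#' initialization (a grid of candidate log IC50 values spanning the data
#' range). The two-site model shares the top/bottom plateaus between sites.
#'
#' @param d a \linkS4class{BindingDataset} (>= 5 concentrations for
#'   one-site, >= 7 for two-site).
#' @param model "one-site" or "two-site".
#' @param nStarts number of IC50 starting values (default 8).
#' @return a \linkS4class{FitReport} (Ki is NA until
#'   \code{\link{chengPrusoff}} is applied).
#' @export
fitCompetition <- function(d, model = c("one-site", "two-site"),
                           nStarts = 8L) {
  model <- match.arg(model)
  stopifnot(is(d, "BindingDataset"))
  minConc <- if (model == "one-site") 5L else 7L
  if (length(d@conc) < minConc)
    stop("need >= ", minConc, " concentrations for the ", model, " model")
  lc <- rep(log10(d@conc), times = ncol(d@bound))
  y <- c(d@bound)
  rng <- range(log10(d@conc))
  if (diff(range(y)) < 1e-9 * max(abs(y), 1))
    stop("degenerate input: flat displacement curve, IC50 unidentifiable")
  b00 <- max(y); ns0 <- min(y)
  starts <- seq(rng[1] + 0.2, rng[2] - 0.2, length.out = nStarts)
  best <- NULL
  for (s in starts) {
    st <- if (model == "one-site") list(b0 = b00, ns = ns0, p1 = s) else
      list(b0 = b00, ns = ns0, p1 = s - 1, p2 = min(s + 1, rng[2] + 2),
           f = 0.5)
    fit <- .fitAttempt(lc, y, model, st)
    if (!is.null(fit)) {
      sse <- sum(stats::resid(fit)^2)
      if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
    }
  }
  if (is.null(best)) stop("non-convergence after all starts")
  cf <- stats::coef(best$fit)
  n <- length(y)
  nPar <- if (model == "one-site") 3L else 5L
  r2 <- 1 - best$sse / sum((y - mean(y))^2)
  coefOut <- if (model == "one-site") {
    c(b0 = unname(cf[["b0"]]), ns = unname(cf[["ns"]]),
      logIC50 = unname(cf[["p1"]]))
  } else {
    # order the sites so logIC50 is the high-affinity one
    p <- sort(c(cf[["p1"]], cf[["p2"]]))
    f <- if (cf[["p1"]] <= cf[["p2"]]) cf[["f"]] else 1 - cf[["f"]]
    c(b0 = unname(cf[["b0"]]), ns = unname(cf[["ns"]]), logIC50 = p[1],
      logIC50_2 = p[2], fraction = unname(f))
  }
  new("FitReport", model = model, coef = coefOut, ki = NA_real_,
      rSquared = max(0, min(1, r2)), sse = best$sse, dof = n - nPar)
}

#' Cheng-Prusoff conversion from IC50 to Ki
#'
#' \eqn{K_i = IC_{50} / (1 + [L]/K_d)}: monotone increasing in IC50 and
#' decreasing in the radioligand concentration [L].
#'
#' @param ic50 IC50 (M); @param L radioligand concentration (M);
#' @param Kd radioligand dissociation constant (M). All > 0.
#' @return Ki in M.
#' @export
chengPrusoff <- function(ic50, L, Kd) {
  if (any(c(ic50, L, Kd) <= 0)) stop("all inputs must be > 0")
  ic50 / (1 + L / Kd)
}

#' Homologous-competition Ki
#'
#' When the competitor and radioligand are the same compound (Kd = Ki), the
#' Cheng-Prusoff relation rearranges to \eqn{K_i = IC_{50} - [L]}.
#'
#' @param ic50 IC50 (M); @param L radioligand concentration (M), < IC50.
#' @return Ki in M.
#' @export
kiHomologous <- function(ic50, L) {
  if (ic50 <= L) stop("homologous Ki requires IC50 > [L]")
  ic50 - L
}

#' Extra-sum-of-squares F test between nested competition fits
#'
#' \eqn{F = ((SSE_1 - SSE_2)/(df_1 - df_2)) / (SSE_2/df_2)}; the two-site
#' model is selected iff p < alpha. If the two-site fit has the larger SSE
#' (numerical artifact), the one-site model is selected with a flag.
#'
#' @param one,two \linkS4class{FitReport}s of the one- and two-site fits on
#'   the same data.
#' @param alpha selection level (default 0.05).
#' @return list with \code{selected}, \code{f}, \code{p}, \code{flag}.
#' @export
fTestSelect <- function(one, two, alpha = 0.05) {
  stopifnot(one@model == "one-site", two@model == "two-site")
  dfDiff <- one@dof - two@dof
  if (two@dof <= 0 || dfDiff <= 0) stop("invalid degrees of freedom")
  if (two@sse > one@sse + 1e-12 * one@sse)
    return(list(selected = "one-site", f = 0, p = 1,
                flag = "two-site SSE exceeds one-site SSE"))
  f <- ((one@sse - two@sse) / dfDiff) / (two@sse / two@dof)
  p <- stats::pf(f, dfDiff, two@dof, lower.tail = FALSE)
  list(selected = if (p < alpha) "two-site" else "one-site", f = f, p = p,
       flag = NA_character_)
}
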