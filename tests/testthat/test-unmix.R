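test_that("baseline subtraction is windowed frame arithmetic", {
  wl <- c(600, 640)
  # frames 1,2 are all 1s; frame 3 all 3s; frame 4 all 5s
  d <- c(2, 2, 2)
  vol <- array(0, c(d, 2, 4))
  vol[, , , , 1] <- 1; vol[, , , , 2] <- 1
  vol[, , , , 3] <- 3; vol[, , , , 4] <- 5
  stk <- new("VolumeStack", volumes = vol, spacing = 0.2, origin = c(0, 0, 0),
             wavelengths = wl, frameTimes = c(0, 10, 100, 200),
             provenance = list())
  expect_true(all(baselineSubtract(stk, 1, 2, 600) == 0))
  expect_true(all(baselineSubtract(stk, 1:2, 3:4, 640) == 3))  # mean(3,5)-1
  zeroPre <- stk; zeroPre@volumes[, , , , 1:2] <- 0
  expect_true(all(baselineSubtract(zeroPre, 1, 3, 600) == 3))
  expect_error(baselineSubtract(stk, integer(0), 3), "empty")
  expect_error(baselineSubtract(stk, 1:2, 2:3), "disjoint")
})

test_that("probe-spectrum extraction recovers a constant differential spectrum exactly", {
  lib <- tinyLibrary()
  wl <- wavelengths(lib)
  truth <- interpolateSpectrum(lib, "PBB5", wl)
  d <- c(4, 4, 4)
  vol <- array(0, c(d, length(wl), 2))
  for (i in seq_along(wl)) vol[, , , i, 2] <- truth[i] * 0.7
  stk <- new("VolumeStack", volumes = vol, spacing = 0.2, origin = c(0, 0, 0),
             wavelengths = wl, frameTimes = c(0, 120), provenance = list())
  seeds <- matrix(c(1, 1, 1, 2, 3, 4), 2, 3, byrow = TRUE)
  ex <- extractProbeSpectrum(stk, 1, 2, seeds)
  expect_equal(ex@values, truth / max(truth))
  allZero <- stk; allZero@volumes[] <- 0
  expect_error(extractProbeSpectrum(allZero, 1, 2, seeds), "normalize")
})

test_that("least-squares unmixing matches pure components, brute force, and round trips", {
  lib <- tinyLibrary()
  wl <- wavelengths(lib)
  mH <- interpolateSpectrum(lib, "HbO", wl)
  mP <- interpolateSpectrum(lib, "PBB5", wl)
  d <- c(5, 5, 4)
  nv <- prod(d)
  # pure-component voxel
  Ypure <- matrix(rep(2 * mH, nv), length(wl))
  ab <- unmixLSQ(stackFromMatrix(Ypure, wl, d), lib, wavelengthsNm = wl)
  expect_equal(c(ab@maps$HbO), rep(2, nv), tolerance = 1e-12)
  expect_lt(max(abs(ab@maps$PBB5)), 1e-10)

  # brute-force SSE grid oracle on random noisy voxels
  set.seed(21)
  aT <- runif(nv, 0.2, 4.5); bT <- runif(nv, 0.2, 4.5)
  Y <- outer(mH, aT) + outer(mP, bT) +
    matrix(rnorm(length(wl) * nv, 0, 0.05), length(wl))
  abN <- unmixLSQ(stackFromMatrix(Y, wl, d), lib, wavelengthsNm = wl)
  grid <- seq(0, 5, by = 0.01)
  g11 <- sum(mH^2); g22 <- sum(mP^2); g12 <- sum(mH * mP)
  for (v in sample(nv, 20)) {
    t1 <- sum(mH * Y[, v]); t2 <- sum(mP * Y[, v])
    sse <- outer(grid^2 * g11 - 2 * grid * t1,
                 grid^2 * g22 - 2 * grid * t2, `+`) +
      2 * outer(grid, grid) * g12
    best <- which(sse == min(sse), arr.ind = TRUE)[1, ]
    expect_lte(abs(c(abN@maps$HbO)[v] - grid[best[1]]), 0.0101)
    expect_lte(abs(c(abN@maps$PBB5)[v] - grid[best[2]]), 0.0101)
  }

  # noiseless round trip to < 1e-6 relative error
  Yc <- outer(mH, aT) + outer(mP, bT)
  abC <- unmixLSQ(stackFromMatrix(Yc, wl, d), lib, wavelengthsNm = wl)
  expect_lt(max(abs(c(abC@maps$HbO) - aT) / aT), 1e-6)
  expect_lt(max(abs(c(abC@maps$PBB5) - bT) / bT), 1e-6)
  expect_lt(max(abC@residual), 1e-12)

  # scale equivariance
  ab2 <- unmixLSQ(stackFromMatrix(3 * Yc, wl, d), lib, wavelengthsNm = wl)
  expect_equal(c(ab2@maps$PBB5), 3 * c(abC@maps$PBB5), tolerance = 1e-10)

  # degenerate design and bad wavelengths are hard errors
  dup <- SpectralLibrary(wl, list(HbO = mH, PBB5 = mH * 2))
  expect_error(unmixLSQ(stackFromMatrix(Yc, wl, d), dup, wavelengthsNm = wl),
               "rank-deficient")
  expect_error(unmixLSQ(stackFromMatrix(Yc, wl, d), lib,
                        wavelengthsNm = c(600, 700)), "outside")
})

test_that("nonnegative unmixing clips optimally rather than naively", {
  lib <- tinyLibrary()
  wl <- wavelengths(lib)
  mH <- interpolateSpectrum(lib, "HbO", wl)
  mP <- interpolateSpectrum(lib, "PBB5", wl)
  d <- c(4, 4, 2)
  set.seed(8)
  # spectra that force negative unconstrained coefficients for some voxels
  Y <- outer(mH, runif(prod(d), -0.5, 1)) + outer(mP, runif(prod(d), -0.5, 1))
  abU <- unmixLSQ(stackFromMatrix(Y, wl, d), lib, wavelengthsNm = wl)
  abN <- unmixLSQ(stackFromMatrix(Y, wl, d), lib, wavelengthsNm = wl,
                  nonneg = TRUE)
  expect_true(all(abN@maps$HbO >= 0) && all(abN@maps$PBB5 >= 0))
  # NNLS residual is never better than unconstrained, never worse than
  # clipping the unconstrained solution at zero
  clipSSE <- vapply(seq_len(prod(d)), function(v) {
    a <- pmax(c(abU@maps$HbO)[v], 0); b <- pmax(c(abU@maps$PBB5)[v], 0)
    sum((Y[, v] - a * mH - b * mP)^2)
  }, numeric(1))
  expect_true(all(abN@residual <= clipSSE + 1e-10))
  expect_true(all(abN@residual >= abU@residual - 1e-10))
})

test_that("VCA recovers pure-pixel endmembers and rejects rank-deficient data", {
  fx <- vcaFixture(noiseSd = 0)
  res <- unmixVCA(fx$stack, 2, seed = 7)
  ang <- vapply(list(fx$e1, fx$e2), function(e)
    min(apply(res$endmembers, 2, spectralAngle, e)), numeric(1))
  expect_lt(max(ang), 1e-6)
  # abundances of the noiseless mixture reproduce the data
  expect_lt(max(res$abundances@residual), 1e-20)
  expect_error(unmixVCA(fx$stack, 4, seed = 1), "rank deficient")

  fxN <- vcaFixture(noiseSd = 0.01, seed = 101)
  resN <- unmixVCA(fxN$stack, 2, seed = 7)
  angN <- vapply(list(fx$e1, fx$e2), function(e)
    min(apply(resN$endmembers, 2, spectralAngle, e)), numeric(1))
  expect_lt(max(angN), 0.05)
})

test_that("unmixing crosscheck correlation behaves like Pearson r", {
  set.seed(3)
  v <- array(rnorm(64), c(4, 4, 4))
  mask <- array(TRUE, c(4, 4, 4))
  expect_equal(crosscheckUnmixing(v, v, mask), 1)
  expect_equal(crosscheckUnmixing(v, -v, mask), -1)
  expect_error(crosscheckUnmixing(array(1, c(4, 4, 4)), v, mask), "constant")
})
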