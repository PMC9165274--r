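test_that("absorption maps are the spectral mixture of concentration maps", {
  lib <- tinyLibrary()
  d <- c(4, 4, 4)
  zero <- list(HbO = array(0, d), PBB5 = array(0, d))
  expect_true(all(absorptionMap(zero, lib, 620) == 0))
  one <- list(HbO = array(0, d))
  one$HbO[2, 3, 1] <- 2
  expect_equal(absorptionMap(one, lib, 620)[2, 3, 1], 2 * 2)  # eps_HbO(620)=2
  # additivity against a direct-sum oracle on random maps
  set.seed(1)
  a <- list(HbO = array(runif(64), d), PBB5 = array(runif(64), d))
  b <- list(HbO = array(runif(64), d), PBB5 = array(runif(64), d))
  ab <- Map(`+`, a, b)
  expect_equal(absorptionMap(ab, lib, 630),
               absorptionMap(a, lib, 630) + absorptionMap(b, lib, 630))
  expect_error(absorptionMap(list(ICG = array(1, d)), lib, 620), "absent")
})

test_that("fluence follows the diffusion-theory effective attenuation", {
  d <- c(6, 6, 10)
  of0 <- fluenceField(array(0, d), 10, spacingMm = 0.2)
  expect_true(all(of0@muEff == 0))
  expect_true(all(of0@fluence == 1))
  # homogeneous medium: mu_eff = sqrt(3 * 0.2 * 10.2)
  of <- fluenceField(array(0.2, d), 10, spacingMm = 0.2)
  expect_equal(unique(c(of@muEff)), sqrt(3 * 0.2 * 10.2), tolerance = 1e-12)
  # exponential composition: fluence at depth 2m equals (fluence at m)^2
  fl <- of@fluence[3, 3, ]
  k <- d[3]
  expect_equal(fl[k - 4], fl[k - 2]^2, tolerance = 1e-12)
  expect_equal(fl[k], 1)
  expect_error(fluenceField(array(-1, d), 10, 0.2), "negative")
})

test_that("initial pressure is the Grueneisen-scaled absorbed energy", {
  d <- c(3, 3, 3)
  muA <- array(2, d)
  expect_equal(initialPressure(muA, array(1, d)), muA)
  expect_equal(initialPressure(muA, array(1, d), gamma = 2), 2 * muA)
  expect_equal(initialPressure(array(3, c(1, 1, 1)), array(0.5, c(1, 1, 1)))[1],
               1.5)
})

test_that("projection bins impulses at the acoustic time of flight with 1/r amplitude", {
  dims <- c(5, 5, 5); sp <- 0.2
  geom <- makeArrayGeometry(c(0.5, 0.5, -5), nDetectors = 64)
  # overwrite detector 1 and 2 with hand-placed positions
  geom@positions[1, ] <- c(0.5, 0.5, 10.5)   # 10 mm above voxel (3,3,3)
  geom@positions[2, ] <- c(0.5, 0.5, 5.5)    # 5 mm above it
  p0 <- array(0, dims); p0[3, 3, 3] <- 1
  expect_true(all(projectVolume(array(0, dims), geom, sp) == 0))
  tr <- projectVolume(p0, geom, sp, derivative = FALSE)
  # 10 / (1.5 * 0.025) = 266.7 -> 0-based sample 267 (1-based index 268)
  expect_equal(which(tr[1, ] != 0), 268)
  expect_equal(tr[1, 268], sp^3 / (4 * pi * 10))
  # two detectors at d and 2d: peak amplitudes in ratio 2:1
  expect_equal(max(tr[2, ]) / max(tr[1, ]), 2)
})

test_that("the forward chain is linear in the initial pressure", {
  dims <- c(8, 8, 8); sp <- 0.3
  geom <- makeArrayGeometry(dims * sp / 2, nDetectors = 64, nSamples = 512L)
  set.seed(5)
  a <- array(runif(prod(dims)), dims)
  b <- array(runif(prod(dims)), dims)
  expect_equal(projectVolume(a + b, geom, sp),
               projectVolume(a, geom, sp) + projectVolume(b, geom, sp),
               tolerance = 1e-12)
})

test_that("degradation: identity config, band-center preservation, out-of-band rejection", {
  geom <- makeArrayGeometry(c(0, 0, 0), nDetectors = 64, nSamples = 512L)
  tr <- array(rnorm(64 * 512), c(64, 512, 1, 1))
  geomAll <- geom; geomAll@fractionalBandwidth <- Inf
  s <- degradeSinogram(tr, geomAll, 600, 0)
  expect_equal(s@signals, tr)

  # sinusoid exactly on an FFT bin at the center frequency: gain within 1%
  fs <- geom@sampleRateMHz; n <- geom@nSamples
  kc <- round(geom@centerFreqMHz / fs * n)
  tone <- sin(2 * pi * kc * (0:(n - 1)) / n)
  trTone <- array(rep(tone, each = 64), c(64, n, 1, 1))
  sTone <- degradeSinogram(trTone, geom, 600, 0)
  expect_equal(max(abs(sTone@signals[1, , 1, 1])), 1, tolerance = 0.01)

  # tone at 4x center frequency attenuated by >= 20 dB
  k4 <- round(4 * geom@centerFreqMHz / fs * n)
  tone4 <- sin(2 * pi * k4 * (0:(n - 1)) / n)
  s4 <- degradeSinogram(array(rep(tone4, each = 64), c(64, n, 1, 1)),
                        geom, 600, 0)
  expect_lt(max(abs(s4@signals[1, , 1, 1])), 0.1)

  # noise is deterministic under a fixed seed
  s1 <- degradeSinogram(tr, geomAll, 600, 0, noiseSigma = 0.1, seed = 3)
  s2 <- degradeSinogram(tr, geomAll, 600, 0, noiseSigma = 0.1, seed = 3)
  expect_identical(s1@signals, s2@signals)
})
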