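test_that("phantom generation is deterministic and anatomically valid", {
  p1 <- makePhantom(dims = c(32, 32, 32), spacing = 0.4, seed = 7)
  p2 <- makePhantom(dims = c(32, 32, 32), spacing = 0.4, seed = 7)
  expect_identical(p1@labels, p2@labels)
  expect_identical(p1@hboMap, p2@hboMap)
  p3 <- makePhantom(dims = c(32, 32, 32), spacing = 0.4, seed = 8)
  expect_false(identical(p1@hboMap, p3@hboMap))

  counts <- table(p1@labels[p1@labels > 0])
  for (nm in c("cortex", "hippocampus", "thalamus", "cerebellum")) {
    lab <- names(p1@regionNames)[p1@regionNames == nm]
    expect_gt(counts[[lab]], 0)
  }
  idx <- which(p1@labels > 0, arr.ind = TRUE)
  ext <- (apply(idx, 2, max) - apply(idx, 2, min) + 1) * p1@spacing
  expect_true(all(ext <= 15))
  expect_gt(sum(p1@vesselMask), 0)
  expect_true(all(p1@hboMap[p1@vesselMask] > 0))

  expect_error(makePhantom(dims = c(128, 64, 64)), "too large")
  expect_error(makePhantom(spacing = 0.05), "spacing")
})

test_that("bolus kinetics: zero before injection, gamma-variate peak, dose linearity", {
  k <- kineticsConfig()
  for (cmp in c("vascular", "cortex", "cerebellum"))
    expect_equal(bolusConcentration(k, 10, cmp), 0)
  # gamma-variate mode at tInject + shape*scale, checked numerically
  tPeakAnalytic <- k@tInject + k@vascularShape * k@vascularScale
  tGrid <- seq(k@tInject, k@tInject + 600, by = 0.5)
  cv <- bolusConcentration(k, tGrid, "vascular")
  expect_lt(abs(tGrid[which.max(cv)] - tPeakAnalytic), 1)
  # parenchymal closed form matches numerical convolution
  tq <- c(120, 600, 3600)
  numeric_cp <- vapply(tq, function(tt) {
    integrate(function(s) bolusConcentration(k, s, "vascular") *
                exp(-k@washoutRate * (tt - s)), k@tInject, tt,
              rel.tol = 1e-10)$value * k@uptakeRate * k@tauLoad[["cortex"]]
  }, numeric(1))
  expect_equal(bolusConcentration(k, tq, "cortex"), numeric_cp,
               tolerance = 1e-7)
  # exact linearity in dose
  k2 <- kineticsConfig(doseScale = 2)
  for (cmp in c("vascular", "cortex", "thalamus"))
    expect_equal(bolusConcentration(k2, c(100, 3600), cmp),
                 2 * bolusConcentration(k, c(100, 3600), cmp))
  expect_error(bolusConcentration(k, 100, "spleen"), "unknown compartment")
})

test_that("rendered frames respect injection timing, reference region and genotype", {
  p <- makePhantom(dims = c(32, 32, 32), spacing = 0.4, seed = 3)
  kP <- kineticsConfig(genotype = "P301L")
  kW <- kineticsConfig(genotype = "WT")
  fsP <- renderFrames(p, kP)
  fsW <- renderFrames(p, kW)
  pre <- which(kP@frameTimes < kP@tInject)
  for (i in pre) expect_true(all(fsP@pbb5Maps[[i]] == 0))
  i60 <- which(kP@frameTimes == 3600)
  cerebLab <- as.integer(names(p@regionNames)[p@regionNames == "cerebellum"])
  cereb <- p@labels == cerebLab & !p@vesselMask
  expect_true(all(fsP@pbb5Maps[[i60]][cereb] == 0))
  ctxLab <- as.integer(names(p@regionNames)[p@regionNames == "cortex"])
  ctx <- p@labels == ctxLab
  expect_gt(mean(fsP@pbb5Maps[[i60]][ctx]), mean(fsW@pbb5Maps[[i60]][ctx]))
  # wild-type parenchyma is exactly the wtFraction-scaled transgenic signal
  par <- ctx & !p@vesselMask
  expect_equal(fsW@pbb5Maps[[i60]][par],
               kW@wtFraction * fsP@pbb5Maps[[i60]][par])
})

test_that("retention-window signal is monotone in dose and group direction holds per seed", {
  for (seed in 1:5) {
    p <- makePhantom(dims = c(24, 24, 24), spacing = 0.5, seed = seed)
    ctxLab <- as.integer(names(p@regionNames)[p@regionNames == "cortex"])
    ret <- vapply(c(0.2, 1, 2), function(ds) {
      k <- kineticsConfig(doseScale = ds)
      mean(renderFrames(p, k)@pbb5Maps[[15]][p@labels == ctxLab])
    }, numeric(1))
    expect_true(all(diff(ret) > 0))
    for (reg in c("cortex", "hippocampus", "thalamus")) {
      lab <- as.integer(names(p@regionNames)[p@regionNames == reg])
      mP <- mean(renderFrames(p, kineticsConfig(genotype = "P301L"))@pbb5Maps[[15]][p@labels == lab])
      mW <- mean(renderFrames(p, kineticsConfig(genotype = "WT"))@pbb5Maps[[15]][p@labels == lab])
      expect_gt(mP, mW)
    }
  }
})

test_that("planar fluorescence readout is linear and tracks the cortical time course", {
  p <- makePhantom(dims = c(32, 32, 32), spacing = 0.4, seed = 2)
  fs <- renderFrames(p, kineticsConfig())
  pf <- planarFluorescenceReadout(fs)
  zero <- fs
  zero@pbb5Maps <- lapply(fs@pbb5Maps, function(m) array(0, dim(m)))
  expect_true(all(planarFluorescenceReadout(zero) == 0))
  dbl <- fs
  dbl@pbb5Maps <- lapply(fs@pbb5Maps, function(m) 2 * m)
  expect_equal(planarFluorescenceReadout(dbl), 2 * pf)
  ctxLab <- as.integer(names(p@regionNames)[p@regionNames == "cortex"])
  ctx <- vapply(fs@pbb5Maps, function(m) mean(m[p@labels == ctxLab]),
                numeric(1))
  expect_gt(cor(pf, ctx), 0.9)
})
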