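test_that("profile extraction samples trilinearly with the right length", {
  d <- c(10, 10, 10); sp <- 0.2
  vol <- array(2, d)
  pr <- extractProfile(vol, c(0.3, 1, 1), c(1.7, 1, 1), sp, stepUm = 25)
  expect_true(all(pr$values == 2))
  expect_length(pr$values, floor(1400 / 25) + 1)
  # a single bright voxel peaks the profile at that voxel's center
  vol2 <- array(0, d); vol2[5, 5, 5] <- 1   # center x = 0.9 mm
  pr2 <- extractProfile(vol2, c(0.1, 0.9, 0.9), c(1.7, 0.9, 0.9), sp,
                        stepUm = 10)
  expect_equal(pr2$positionsUm[which.max(pr2$values)], 800)  # 0.9 - 0.1 mm
  expect_error(extractProfile(vol, c(-5, 1, 1), c(1, 1, 1), sp), "outside")
})

test_that("Gaussian FWHM estimation is analytic, invariant, and noise-robust", {
  x <- seq(0, 1000, by = 10)
  y <- 2 * exp(-(x - 480)^2 / (2 * 50^2))
  expected <- 2 * sqrt(2 * log(2)) * 50
  f <- fitFWHM(x, y)
  expect_equal(f@fwhm, expected, tolerance = 1e-3)
  # amplitude scaling and x-shift leave the width unchanged
  f2 <- fitFWHM(x + 250, 7 * y)
  expect_equal(f2@fwhm, f@fwhm, tolerance = 1e-8)
  # offset + 2% noise: within 5%
  set.seed(3)
  yN <- y + 0.2 + rnorm(length(y), 0, 0.02 * max(y))
  fN <- fitFWHM(x, yN)
  expect_lt(abs(fN@fwhm - expected) / expected, 0.05)
  expect_error(fitFWHM(x, rep(1, length(x))), "constant")
  expect_error(fitFWHM(1:3, c(1, 2, 1)), "at least 5")
})

test_that("VOI time courses average in-region voxels and mask extracranial signal", {
  d <- c(4, 4, 1)
  labels <- array(0L, d)
  labels[1:2, 1, 1] <- 1L; labels[3:4, 1, 1] <- 2L
  rn <- c(`1` = "cortex", `2` = "cerebellum")
  maps <- array(0, c(d, 2))
  maps[1:2, 1, 1, 1] <- c(1, 3); maps[3:4, 1, 1, 1] <- c(2, 6)
  maps[, , , 2] <- 10 * maps[, , , 1]
  rep1 <- voiTimecourse(maps, labels, rn, c(0, 60))
  expect_equal(rep1@values["cortex", ], c(2, 20))
  expect_equal(rep1@values["cerebellum", ], c(4, 40))
  # constant map: every region reports the constant
  repC <- voiTimecourse(array(7, c(d, 1)), labels, rn, 0)
  expect_true(all(repC@values == 7))
  # extracranial voxels never contribute (bit-exact masking contract)
  maps2 <- maps
  maps2[labels == 0L] <- 1e6
  maps2[, , , 2][labels == 0L] <- 1e6
  rep2 <- voiTimecourse(maps2, labels, rn, c(0, 60))
  expect_identical(rep2@values, rep1@values)
  # linearity in the input map
  rep3 <- voiTimecourse(3 * maps, labels, rn, c(0, 60))
  expect_equal(rep3@values, 3 * rep1@values)
  expect_error(voiTimecourse(maps, array(0L, d), rn, c(0, 60)), "empty region")
})

test_that("retention picks the nearest frame within tolerance", {
  rep1 <- new("VOIReport",
              values = matrix(1:6, 3, 2,
                              dimnames = list(c("a", "b", "c"), NULL)),
              regionVolumes = c(a = 1, b = 1, c = 1),
              frameTimes = c(1200, 3590), group = "g", rater = "r")
  expect_equal(unname(retention(rep1, 3600)["b"]), 5)
  expect_equal(unname(retention(rep1, 1200)["a"]), 1)
  expect_error(retention(rep1, 7200), "no frame within")
  # reference-region ratio output
  expect_equal(unname(retention(rep1, 3600, ratioTo = "a")), c(1, 5 / 4, 6 / 4))
  expect_error(retention(rep1, 3600, ratioTo = "zzz"), "not in report")
})

test_that("two-way ANOVA matches the sums-of-squares decomposition oracle", {
  # balanced 2 groups x 2 regions x n = 3
  set.seed(12)
  df <- expand.grid(subject = 1:3, group = c("G1", "G2"),
                    region = c("cortex", "thalamus"))
  df$value <- rnorm(nrow(df)) + 2 * (df$group == "G1") +
    0.5 * (df$region == "cortex") +
    1 * (df$group == "G1" & df$region == "cortex")
  res <- twoWayAnovaBonferroni(df)
  # textbook cell-means sums of squares
  n <- 3; a <- 2; b <- 2
  gm <- mean(df$value)
  mG <- tapply(df$value, df$group, mean)
  mR <- tapply(df$value, df$region, mean)
  mC <- tapply(df$value, list(df$group, df$region), mean)
  ssG <- n * b * sum((mG - gm)^2)
  ssR <- n * a * sum((mR - gm)^2)
  ssC <- n * sum((outer(mG - gm, mR - gm, `+`) + gm - mC)^2)
  ssE <- sum((df$value - mC[cbind(as.character(df$group),
                                  as.character(df$region))])^2)
  fG <- (ssG / (a - 1)) / (ssE / (a * b * (n - 1)))
  expect_equal(res$anova$sumsq, c(ssG, ssR, ssC, ssE), tolerance = 1e-8)
  expect_equal(res$anova$F[1], fG, tolerance = 1e-8)
  expect_equal(res$anova$p[1],
               pf(fG, a - 1, a * b * (n - 1), lower.tail = FALSE),
               tolerance = 1e-8)
  # Bonferroni is raw p times the number of regions, capped at 1
  expect_equal(res$posthoc$pAdjusted,
               pmin(1, res$posthoc$p * length(unique(df$region))))

  # identical groups: F = 0, p = 1, all adjusted p = 1
  df0 <- df
  half <- df0$group == "G1"
  df0$value[half] <- df0$value[!half]
  res0 <- twoWayAnovaBonferroni(df0)
  expect_equal(res0$anova$F[1], 0)
  expect_equal(res0$anova$p[1], 1)
  expect_true(all(res0$posthoc$pAdjusted == 1))

  expect_error(twoWayAnovaBonferroni(df[-1, ]), "unbalanced")
})

test_that("t test and correlation wrappers handle the canonical cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(tTestTwoTailed(x, x), list(t = 0, p = 1))
  expect_equal(pearsonCorrelation(x, x)$r, 1)
  expect_equal(pearsonCorrelation(x, -x)$r, -1)
  expect_equal(pearsonCorrelation(x, c(2, 4, 6, 8))$r, 1)
  expect_equal(pearsonCorrelation(x, rev(x), method = "spearman")$r, -1)
  expect_error(pearsonCorrelation(x, rep(1, 4)), "constant")
})

test_that("reliability: self-correlation is 1 and jittered masks stay concordant", {
  p <- makePhantom(dims = c(24, 24, 24), spacing = 0.5, seed = 4)
  fs <- renderFrames(p, kineticsConfig())
  maps <- array(fs@pbb5Maps[[15]], c(p@dims, 1))
  r1 <- voiTimecourse(maps, p@labels, p@regionNames, 3600)
  expect_equal(reliability(r1, r1)$r, 1)
  lab2 <- jitterLabels(p@labels, "erode", 1)
  r2 <- voiTimecourse(maps, lab2, p@regionNames, 3600, rater = "rater2")
  expect_gt(reliability(r1, r2)$r, 0.95)
  rSmall <- new("VOIReport",
                values = matrix(1:2, 2, 1,
                                dimnames = list(c("x", "y"), NULL)),
                regionVolumes = c(x = 1, y = 1), frameTimes = 0,
                group = "g", rater = "r")
  expect_error(reliability(r1, rSmall), "shared regions")
})
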