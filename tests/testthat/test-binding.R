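test_that("displacement model has the right asymptotes and midpoint", {
  expect_equal(displacementModel(1e-15, 100, 10, 1e-7), 100, tolerance = 1e-6)
  expect_equal(displacementModel(1e3, 100, 10, 1e-7), 10, tolerance = 1e-6)
  expect_equal(displacementModel(1e-7, 100, 10, 1e-7), 55)
  # two-site midpoints compose by fraction
  expect_equal(displacementModel(1e-15, 100, 10, c(1e-9, 1e-7), 0.3), 100,
               tolerance = 1e-5)
  expect_error(displacementModel(1e-8, 100, 10, c(1e-9, 1e-7), 1.5),
               "fraction")
})

test_that("noiseless fits recover the generating parameters", {
  d1 <- simulateDisplacement(b0 = 100, ns = 10, ic50 = 10^-7.74,
                             noiseCv = 0, seed = 1)
  f1 <- fitCompetition(d1, "one-site")
  expect_equal(f1@coef[["logIC50"]], -7.74, tolerance = 1e-4)
  expect_equal(f1@coef[["b0"]], 100, tolerance = 1e-4)
  expect_equal(f1@coef[["ns"]], 10, tolerance = 1e-4)
  expect_gt(f1@rSquared, 1 - 1e-9)

  d2 <- simulateDisplacement(b0 = 100, ns = 10, ic50 = c(1e-9, 3e-7),
                             fraction = 0.4, noiseCv = 0, seed = 1)
  f2 <- fitCompetition(d2, "two-site")
  expect_equal(f2@coef[["logIC50"]], -9, tolerance = 1e-3)
  expect_equal(f2@coef[["logIC50_2"]], log10(3e-7), tolerance = 1e-3)
  expect_equal(f2@coef[["fraction"]], 0.4, tolerance = 1e-3)

  flat <- simulateDisplacement(b0 = 50, ns = 50, noiseCv = 0, seed = 1)
  expect_error(fitCompetition(flat, "one-site"), "degenerate|unidentifiable")
})

test_that("fits are invariant to multiplicative rescaling of the signal", {
  d <- simulateDisplacement(ic50 = 1e-8, noiseCv = 0.05, seed = 5)
  dScaled <- new("BindingDataset", conc = d@conc, bound = 10 * d@bound,
                 radioligandConc = d@radioligandConc,
                 nonspecificLevel = 10 * d@nonspecificLevel)
  f <- fitCompetition(d, "one-site")
  fS <- fitCompetition(dScaled, "one-site")
  expect_equal(fS@coef[["logIC50"]], f@coef[["logIC50"]], tolerance = 1e-6)
  expect_equal(fS@rSquared, f@rSquared, tolerance = 1e-8)
})

test_that("Cheng-Prusoff conversion and its homologous rearrangement", {
  expect_equal(chengPrusoff(1e-8, 5e-9, 5e-9), 5e-9)
  expect_equal(chengPrusoff(1e-8, 1e-15, 5e-9), 1e-8, tolerance = 1e-6)
  # monotone: increasing in IC50, decreasing in L
  ics <- c(1e-9, 1e-8, 1e-7)
  expect_true(all(diff(chengPrusoff(ics, 5e-9, 5e-9)) > 0))
  Ls <- c(1e-9, 5e-9, 2e-8)
  expect_true(all(diff(chengPrusoff(1e-8, Ls, 5e-9)) < 0))
  expect_error(chengPrusoff(-1e-8, 5e-9, 5e-9), "> 0")
  expect_equal(kiHomologous(7e-9, 5e-9), 2e-9)
  # algebraic rearrangement checked numerically: with Kd = Ki the
  # Cheng-Prusoff identity IC50 = Ki + L holds
  ki <- kiHomologous(7e-9, 5e-9)
  expect_equal(chengPrusoff(7e-9, 5e-9, ki), ki * (7e-9) / (ki + 5e-9),
               tolerance = 1e-12)
})

test_that("extra-sum-of-squares F test selects the supported model", {
  one <- new("FitReport", model = "one-site", coef = c(logIC50 = -8),
             ki = NA_real_, rSquared = 0.9, sse = 10, dof = 45)
  twoSame <- new("FitReport", model = "two-site",
                 coef = c(logIC50 = -8, logIC50_2 = -7, fraction = 0.5),
                 ki = NA_real_, rSquared = 0.9, sse = 10, dof = 43)
  resSame <- fTestSelect(one, twoSame)
  expect_equal(resSame$f, 0)
  expect_equal(resSame$selected, "one-site")
  # strongly biphasic data select the two-site model
  d <- simulateDisplacement(ic50 = c(1e-9, 3e-7), fraction = 0.5,
                            noiseCv = 0.03, seed = 11)
  sel <- fTestSelect(fitCompetition(d, "one-site"),
                     fitCompetition(d, "two-site"))
  expect_equal(sel$selected, "two-site")
  expect_lt(sel$p, 0.05)
  bad <- new("FitReport", model = "two-site",
             coef = c(logIC50 = -8, logIC50_2 = -7, fraction = 0.5),
             ki = NA_real_, rSquared = 0.9, sse = 10, dof = 50)
  expect_error(fTestSelect(one, bad), "degrees of freedom")
})
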