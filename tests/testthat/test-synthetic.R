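test_that("the frozen defaults reproduce the characteristic dynamic signatures", {
  ct <- defaultScenario("control")
  ox <- defaultScenario("h2o2")
  rc <- simulatePathway(ct$params, ct$init)
  rh <- simulatePathway(ox$params, ox$init)
  cg <- trajectory(rc, "cGMP")
  peak <- max(cg); tpeak <- simTime(rc)[which.max(cg)]
  ## abrupt rise: peak within 40 s
  expect_lte(tpeak, 40)
  ## return to baseline: at or below 10% of peak through the window's tail
  tail <- simTime(rc) >= 180
  expect_true(all(cg[tail] <= 0.1 * peak))
  ## ~6-fold suppression of peak cGMP by 500 uM H2O2
  fold <- peak / max(trajectory(rh, "cGMP"))
  expect_gte(fold, 5); expect_lte(fold, 7)
  ## activity-ratio constraint baked into the defaults
  k <- rateConstants(ct$params)
  expect_identical(unname(k["k9"] / k["k8"]), 200)
})

test_that("scenarios are frozen constants", {
  a <- defaultScenario("h2o2"); b <- defaultScenario("h2o2")
  expect_identical(rateConstants(a$params), rateConstants(b$params))
  expect_identical(speciesConcentrations(a$init),
                   speciesConcentrations(b$init))
  expect_equal(unname(speciesConcentrations(a$init)["H2O2"]), 500)
  expect_equal(unname(speciesConcentrations(
    defaultScenario("control")$init)["H2O2"]), 0)
})

test_that("parameter sampling is seeded, bounded, and ratio-preserving", {
  expect_identical(rateConstants(sampleParameters(42)),
                   rateConstants(sampleParameters(42)))
  expect_false(identical(rateConstants(sampleParameters(1)),
                         rateConstants(sampleParameters(2))))
  k0 <- rateConstants(defaultParameters())
  draws <- t(vapply(1:100, function(s)
    rateConstants(sampleParameters(s, spread = 0.5)), k0))
  ## every constant within +/- 0.5 decades of its default (k9 follows k8)
  ratio <- sweep(draws[, -9], 2, k0[-9], "/")
  expect_true(all(ratio >= 10^-0.5 - 1e-12 & ratio <= 10^0.5 + 1e-12))
  expect_equal(unname(draws[, "k9"] / draws[, "k8"]), rep(200, 100))
  ## zero spread recovers the defaults
  expect_equal(rateConstants(sampleParameters(7, spread = 1e-12)), k0,
               tolerance = 1e-9)
})

test_that("noisy time courses are seeded and exact at sigma = 0", {
  sc <- defaultScenario("control")
  res <- simulatePathway(sc$params, sc$init)
  clean <- noisyTimecourse(res, sigma = 0, seed = 1)
  expect_identical(clean$cgmp, unname(trajectory(res, "cGMP")))
  n1 <- noisyTimecourse(res, sigma = 0.05, seed = 9)
  n2 <- noisyTimecourse(res, sigma = 0.05, seed = 9)
  expect_identical(n1, n2)
  expect_false(identical(n1$cgmp, clean$cgmp))
  expect_error(noisyTimecourse(res, sigma = -0.1), "sigma")
})

test_that("peak time survives assay-level noise in Monte-Carlo replicates", {
  sc <- defaultScenario("control")
  res <- simulatePathway(sc$params, sc$init)
  truePeak <- simTime(res)[which.max(trajectory(res, "cGMP"))]
  est <- vapply(1:200, function(s) {
    tc <- noisyTimecourse(res, sigma = 0.05, seed = s)
    ## simple smoothing estimator: 5-point running mean before the argmax
    sm <- stats::filter(tc$cgmp, rep(1 / 5, 5), sides = 2)
    tc$time[which.max(sm)]
  }, 1.0)
  expect_lt(abs(mean(est) - truePeak), 2)
})
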