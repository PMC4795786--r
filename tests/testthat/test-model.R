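test_that("derivatives vanish without species or without rate constants", {
  zeroState <- InitialState(stats::setNames(numeric(12), speciesNames()))
  expect_equal(unname(pathwayDerivatives(zeroState, defaultParameters())),
               numeric(12))
  anyState <- defaultInitialState()
  zeroParams <- soloParams("k1", 0)
  expect_equal(unname(pathwayDerivatives(anyState, zeroParams)), numeric(12))
})

test_that("derivatives match hand evaluation of the oxidation step", {
  st <- InitialState(H2O2 = 1, sGC = 1)
  d <- pathwayDerivatives(st, soloParams("k1", 0.01))
  expect_equal(unname(d["H2O2"]), -0.01)
  expect_equal(unname(d["sGC"]), -0.01)
  expect_equal(unname(d["sGC_H2O2"]), 0.01)
  expect_equal(sum(abs(d)), 0.03)
})

test_that("derivatives reject malformed or negative states in strict mode", {
  expect_error(pathwayDerivatives(numeric(5), defaultParameters()),
               "12 species")
  bad <- stats::setNames(numeric(12), speciesNames())
  bad["cGMP"] <- -1
  expect_error(pathwayDerivatives(bad, defaultParameters()), "negative")
  expect_silent(pathwayDerivatives(bad, defaultParameters(), strict = FALSE))
})

test_that("no substrate means no cGMP is ever synthesized", {
  init <- InitialState(sGC = 0.2, PDE = 0.1)  # NO = H2O2 = GTP = 0
  res <- simulatePathway(defaultParameters(), init, tEnd = 50, nPoints = 51)
  expect_equal(max(trajectory(res, "cGMP")), 0)
})

test_that("the simulated bimolecular step matches its analytic solution", {
  ## only k1 active: H2O2 + sGC -> sGC_H2O2 is a closed two-species system
  init <- InitialState(H2O2 = 2, sGC = 1)
  res <- simulatePathway(soloParams("k1", 0.05), init, tEnd = 40,
                         nPoints = 81)
  expected <- bimolecularA(simTime(res), a0 = 2, b0 = 1, k = 0.05)
  expect_equal(trajectory(res, "H2O2"), expected, tolerance = 1e-6)
  ## stoichiometry: product mirrors consumed reactant
  expect_equal(trajectory(res, "sGC_H2O2"), 2 - expected, tolerance = 1e-6)
})

test_that("the first trajectory row is exactly the initial state", {
  sc <- defaultScenario("h2o2")
  res <- simulatePathway(sc$params, sc$init, tEnd = 10, nPoints = 11)
  expect_identical(trajectory(res)[1L, ], speciesConcentrations(sc$init))
})

test_that("simulation rejects degenerate windows", {
  sc <- defaultScenario("control")
  expect_error(simulatePathway(sc$params, sc$init, tEnd = -1), "tEnd")
  expect_error(simulatePathway(sc$params, sc$init, nPoints = 1), "nPoints")
})

test_that("moiety conservation holds along default trajectories", {
  for (cond in c("control", "h2o2")) {
    sc <- defaultScenario(cond)
    res <- simulatePathway(sc$params, sc$init)
    sums <- moietySums(res)
    expect_lt(relDrift(sums$sgc), 1e-6)
    expect_lt(relDrift(sums$nucleotide), 1e-6)
    expect_lt(relDrift(sums$pde), 1e-6)
  }
})

test_that("H2O2 and GTP are non-increasing (no source terms)", {
  sc <- defaultScenario("h2o2")
  res <- simulatePathway(sc$params, sc$init)
  expect_true(all(diff(trajectory(res, "H2O2")) <= 1e-12))
  expect_true(all(diff(trajectory(res, "GTP")) <= 1e-12))
})

test_that("adaptive solver agrees with the fixed-step RK4 reference", {
  sc <- defaultScenario("h2o2")
  res <- simulatePathway(sc$params, sc$init, tEnd = 1, nPoints = 2)
  ref <- cgmpScreen:::.rk4Reference(sc$params, sc$init, tEnd = 1, dt = 1e-4)
  adaptive <- trajectory(res)[2L, ]
  scale <- pmax(abs(ref), 1e-6)
  expect_lt(max(abs(adaptive - ref) / scale), 1e-4)
})

test_that("peak cGMP is non-increasing in the oxidant dose", {
  sc <- defaultScenario("control")
  peaks <- vapply(c(0, 100, 250, 500, 1000), function(dose) {
    init <- applyOxidativeStress(sc$init, dose)
    max(trajectory(simulatePathway(sc$params, init), "cGMP"))
  }, 1.0)
  expect_true(all(diff(peaks) <= 1e-10))
})

test_that("trajectory export is tidy and round-trips through TSV", {
  sc <- defaultScenario("control")
  res <- simulatePathway(sc$params, sc$init, tEnd = 5, nPoints = 6)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTrajectory(res, path)
  back <- utils::read.delim(path, check.names = FALSE)
  expect_identical(names(back), c("time", speciesNames()))
  expect_equal(back$cGMP, unname(trajectory(res, "cGMP")), tolerance = 1e-12)
})
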