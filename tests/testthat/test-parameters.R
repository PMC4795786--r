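test_that("ParameterSet enforces completeness, names, and non-negativity", {
  k <- rateConstants(defaultParameters())
  expect_s4_class(ParameterSet(k), "ParameterSet")
  expect_error(ParameterSet(k[-13]), "missing k13")
  k2 <- c(k, kX = 1)
  expect_error(ParameterSet(k2), "unknown kX")
  k["k3"] <- -1
  expect_error(ParameterSet(k), "negative")
})

test_that("InitialState defaults unmentioned species to zero and validates", {
  st <- InitialState(NO = 0.5, GTP = 50)
  conc <- speciesConcentrations(st)
  expect_equal(unname(conc["NO"]), 0.5)
  expect_equal(sum(conc != 0), 2L)
  expect_error(InitialState(XYZ = 1), "unknown species")
  expect_error(InitialState(NO = -1), "negative")
})

test_that("oxidant challenge replaces H2O2 and leaves everything else", {
  init <- defaultInitialState()
  ox <- applyOxidativeStress(init, 500)
  expect_equal(unname(speciesConcentrations(ox)["H2O2"]), 500)
  others <- setdiff(speciesNames(), "H2O2")
  expect_identical(speciesConcentrations(ox)[others],
                   speciesConcentrations(init)[others])
  ## replacement, not addition
  ox2 <- applyOxidativeStress(applyOxidativeStress(init, 100), 500)
  expect_identical(speciesConcentrations(ox2), speciesConcentrations(ox))
  ## zero dose is the identity
  expect_identical(speciesConcentrations(applyOxidativeStress(init, 0)),
                   speciesConcentrations(init))
  expect_error(applyOxidativeStress(init, -5), "non-negative")
})

test_that("the default set satisfies the 200-fold activity-ratio constraint", {
  k <- rateConstants(defaultParameters())
  expect_identical(unname(k["k9"] / k["k8"]), 200)
})
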