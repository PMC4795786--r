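test_that("dose vectors are 11-point descending grids with exact endpoints", {
  v <- makeDoseVector(1, 0.1)
  expect_length(v, 11L)
  expect_equal(v[1L], 1.0)
  expect_equal(v[11L], 0.1)
  expect_equal(unique(round(diff(v), 10)), -0.09)
  v2 <- makeDoseVector(3, 0.5)
  expect_equal(range(v2), c(0.5, 1.0))
  expect_equal(unique(round(diff(v2), 10)), -0.05)
  ## degenerate narrow range is still strictly decreasing
  v3 <- makeDoseVector(2, 0.999)
  expect_true(all(diff(v3) < 0))
  expect_error(makeDoseVector(1, 1.0), "rhoMin")
  expect_error(makeDoseVector(0, 0.5), "target")
})

test_that("a flat dose vector reproduces the unperturbed response", {
  sc <- defaultScenario("h2o2")
  df <- doseResponse(sc$params, sc$init, 3, ratios = rep(1, 3))
  expect_equal(df$relative_cgmp_T, rep(1, 3), tolerance = 1e-9)
})

test_that("dose response equals the manual perturb-simulate-integrate chain", {
  sc <- defaultScenario("h2o2")
  df <- doseResponse(sc$params, sc$init, 10, ratios = 0.1)
  manual <- integrateCGMP(simulatePathway(
    applyPerturbation(sc$params, PerturbationSpec(10, 0.1)), sc$init))
  expect_identical(df$cgmp_T, manual)
})

test_that("Bliss prediction obeys its closed forms and input contracts", {
  expect_equal(blissPredict(0, 0.4), 0.4)     # null inhibitor
  expect_equal(blissPredict(0.5, 0.5), 0.75)
  expect_equal(blissPredict(1, 0.3), 1)
  expect_equal(blissPredict(0.1, 0.1, mode = "ratio-product"), 0.01)
  expect_error(blissPredict(1.2, 0.5), "\\[0, 1\\]")
  expect_error(blissPredict(0, 0.5, mode = "ratio-product"), "\\(0, 1\\]")
})

test_that("the independent two-channel oracle is exactly Bliss", {
  ## deficit factorizes across channels, so observed == predicted everywhere
  base <- independentLossResponse(1, 1)
  ctrl <- 10
  span <- ctrl - base
  for (r1 in c(0.15, 0.4, 0.8)) for (r2 in c(0.25, 0.6, 1)) {
    e1 <- (independentLossResponse(r1, 1) - base) / span
    e2 <- (independentLossResponse(1, r2) - base) / span
    obs <- (independentLossResponse(r1, r2) - base) / span
    expect_equal(obs, blissPredict(e1, e2), tolerance = 1e-12)
  }
})

test_that("paired perturbations of the pathway exceed the Bliss prediction", {
  sc <- defaultScenario("h2o2"); ct <- defaultScenario("control")
  for (pr in list(c(1, 3), c(1, 10), c(3, 10))) {
    cmp <- blissComparison(sc$params, sc$init, ct$init, pr, rho = 0.3)
    expect_gt(cmp$excess, 0)
    expect_true(all(cmp$effects >= 0 & cmp$effects <= 1))
  }
  ## identity pair at rho = 1: no effect, no excess
  cmp1 <- blissComparison(sc$params, sc$init, ct$init, c(1, 3), rho = 1)
  expect_equal(cmp1$excess, 0, tolerance = 1e-9)
  expect_equal(unname(cmp1$cgmp_T["pair"]), unname(cmp1$cgmp_T["baseline"]),
               tolerance = 1e-9)
})

test_that("surface corners, edges, and symmetry are exact", {
  sc <- defaultScenario("h2o2")
  surf <- buildSurface(sc$params, sc$init, c(1, 3), nPoints = 4)
  v <- surfaceValues(surf)
  expect_identical(dim(v), c(4L, 4L))
  ## corner (1, 1) is the unperturbed reference
  expect_equal(v[1L, 1L], surf@reference, tolerance = 1e-12)
  ## edge reproduces the 1-D dose response bit-for-bit
  edge <- doseResponse(sc$params, sc$init, 1,
                       ratios = surfaceDoses(surf)[[1L]])
  expect_identical(unname(v[, 1L]), edge$cgmp_T)
  ## transposed axis order gives the transposed surface
  surfT <- buildSurface(sc$params, sc$init, c(3, 1), nPoints = 4)
  expect_identical(surfaceValues(surfT), t(v))
})

test_that("synthetic isobole oracles classify as constructed", {
  addv <- classifyIsoboles(syntheticSurface("additive"))
  expect_true(all(addv$classification == "additive"))
  expect_true(all(abs(addv$index) < 1e-10))
  syn <- classifyIsoboles(syntheticSurface("potentiation"))
  expect_true(all(syn$classification[syn$level >= 0.5] == "synergistic"))
  ant <- classifyIsoboles(syntheticSurface("antagonistic"))
  expect_true(all(ant$classification[ant$level >= 0.5] == "antagonistic"))
  expect_error(classifyIsoboles(syntheticSurface("additive"), levels = 1.5),
               "fractions")
})

test_that("long-format surface export matches the grid", {
  sc <- defaultScenario("h2o2")
  surf <- buildSurface(sc$params, sc$init, c(1, 3), nPoints = 3)
  df <- asSurfaceFrame(surf)
  expect_equal(nrow(df), 9L)
  expect_identical(names(df), c("rho_1", "rho_2", "cgmp_T",
                                "relative_cgmp_T"))
  expect_equal(df$cgmp_T[df$rho_1 == 1 & df$rho_2 == 1], surf@reference)
})
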