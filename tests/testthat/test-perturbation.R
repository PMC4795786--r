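test_that("enumeration matches the bitmask oracle and the closed form", {
  ## tiny case checked element-wise against an independent enumerator
  got <- enumeratePerturbations(4, 2)
  oracle <- bitmaskSubsets(4, 2)
  expect_equal(length(got), length(oracle))  # 10
  key <- function(x) paste(sort(x), collapse = ",")
  expect_setequal(vapply(got, key, ""), vapply(oracle, key, ""))
  ## full-size counts
  expect_length(enumeratePerturbations(13, 1), 13L)
  full <- enumeratePerturbations(13, 3)
  sizes <- table(vapply(full, length, 1L))
  expect_equal(unname(c(sizes)), c(13L, 78L, 286L))
  expect_length(full, 377L)
  ## deterministic lexicographic order within each size class
  expect_identical(full[[1L]], 1L)
  expect_identical(full[[14L]], c(1L, 2L))
  expect_error(enumeratePerturbations(13, 14), "maxOrder")
})

test_that("perturbation specs validate targets and ratios", {
  expect_error(PerturbationSpec(c(1, 1), 0.1), "distinct")
  expect_error(PerturbationSpec(14, 0.1), "1..13")
  expect_error(PerturbationSpec(1, 0), "\\(0, 1\\]")
  expect_error(PerturbationSpec(1, 1.5), "\\(0, 1\\]")
  ## targets stored sorted with ratios following
  sp <- PerturbationSpec(c(10, 1), c(0.2, 0.8))
  expect_identical(sp@targets, c(1L, 10L))
  expect_identical(sp@ratios, c(0.8, 0.2))
})

test_that("applying perturbations scales targets and composes by product", {
  p0 <- defaultParameters()
  p1 <- applyPerturbation(p0, PerturbationSpec(10, 0.1))
  expect_equal(unname(rateConstants(p1)["k10"]),
               unname(0.1 * rateConstants(p0)["k10"]))
  expect_identical(rateConstants(p1)[-10], rateConstants(p0)[-10])
  ## rho = 1 is the identity
  expect_identical(
    rateConstants(applyPerturbation(p0, PerturbationSpec(1:3, 1.0))),
    rateConstants(p0))
  ## applying {k1, k3} at 0.5 twice == direct multiplication by 0.25
  sp <- PerturbationSpec(c(1, 3), 0.5)
  twice <- applyPerturbation(applyPerturbation(p0, sp), sp)
  expect_equal(unname(rateConstants(twice)[c(1, 3)]),
               unname(rateConstants(p0)[c(1, 3)] * 0.25))
})

test_that("cGMP_T quadrature reproduces closed-form integrals", {
  tt <- seq(0, 200, length.out = 201)
  expect_equal(integrateCGMP(fakeCgmpResult(tt, rep(0, 201))), 0)
  expect_equal(integrateCGMP(fakeCgmpResult(tt, rep(2.5, 201))), 500)
  ## sin(pi t / 200) integrates to 400 / pi
  sine <- fakeCgmpResult(tt, sin(pi * tt / 200))
  expect_equal(integrateCGMP(sine), 400 / pi, tolerance = 1e-4)
  ## horizon must be covered by the grid
  expect_error(integrateCGMP(fakeCgmpResult(tt, tt), horizon = 300),
               "cannot integrate")
})

test_that("a rho = 1 screen is flat and complete", {
  sc <- defaultScenario("h2o2")
  df <- screenPerturbations(sc$params, sc$init, maxOrder = 1, rho = 1.0)
  expect_equal(nrow(df), 13L)
  expect_true(all(df$status == "ok"))
  expect_equal(df$relative_cgmp_T, rep(1, 13), tolerance = 1e-9)
  ## flat responses fall back to lexicographic order
  expect_identical(df$targets[1:3], c("1", "10", "11"))
})

test_that("screens are deterministic and ranked by descending cGMP_T", {
  sc <- defaultScenario("h2o2")
  a <- screenPerturbations(sc$params, sc$init, maxOrder = 1, rho = 0.1)
  b <- screenPerturbations(sc$params, sc$init, maxOrder = 1, rho = 0.1)
  expect_identical(a, b)
  ok <- a[a$status == "ok", ]
  expect_true(all(diff(ok$cgmp_T) <= 0))
  expect_error(screenPerturbations(sc$params, sc$init, rho = 0), "rho")
})
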