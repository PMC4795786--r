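## Calibrated default parameter set and initial state.
##
## No measured constants exist for this lumped pathway as a whole, so the
## package ships a surrogate set calibrated against the characteristic
## dynamic signatures of the system: control cGMP peaking within
## 40 s and back at baseline well before 200 s, a ~6-fold peak reduction
## under 500 uM H2O2, a 200-fold activity ratio of NO-bound over basal sGC
## (k9 = 200 k8), dominance of the k1/k3/k10/k12 single perturbations, and
## the k3 > k1, k10 dose sensitivity ordering. Values are frozen; see the
## methods vignette for the calibration rationale.
.DEFAULT_K <- c(k1 = 0.04,  k2 = 8,    k3 = 0.1,  k4 = 5e-4, k5 = 0.01,
                k6 = 0.01,  k7 = 0.1,  k8 = 0.05, k9 = 10,   k10 = 2.5,
                k11 = 0.1,  k12 = 3,   k13 = 1.8)

.DEFAULT_INIT <- c(H2O2 = 0,   sGC = 0.2,  sGC_H2O2 = 0, NO = 0.5,
                   NO_sGC = 0, GTP = 50,   sGC_GTP = 0,  NO_sGC_GTP = 0,
                   cGMP = 0,   PDE = 0.08, cGMP_PDE = 0, GMP = 0)

#' The frozen default rate constants
#'
#' @return A [ParameterSet-class] with the calibrated defaults. The set
#'   satisfies k9 = 200 k8 (the NO-activated over basal sGC activity ratio).
#' @examples
#' rateConstants(defaultParameters())
#' @export
defaultParameters <- function() ParameterSet(.DEFAULT_K)

#' The frozen default initial concentrations
#'
#' NO is modeled as an initial bolus (the synthesis/diffusion step is not
#' resolved); sGC, GTP and PDE start free; all complexes and products start
#' at zero; H2O2 is zero until an oxidant challenge is applied.
#'
#' @return An [InitialState-class].
#' @examples
#' speciesConcentrations(defaultInitialState())
#' @export
defaultInitialState <- function() InitialState(.DEFAULT_INIT)

#' Standard simulation scenarios
#'
#' The two conditions used throughout: \code{"control"} (no oxidant) and
#' \code{"h2o2"} (500 uM H2O2 at t = 0). Both use the frozen default
#' parameters and the standard 200-s window.
#'
#' @param condition \code{"control"} or \code{"h2o2"}.
#' @param h2o2 Oxidant dose for the \code{"h2o2"} condition (uM).
#' @return List with elements \code{label}, \code{params}
#'   ([ParameterSet-class]), \code{init} ([InitialState-class]),
#'   \code{h2o2}, \code{tEnd}, \code{nPoints}.
#' @examples
#' sc <- defaultScenario("h2o2")
#' speciesConcentrations(sc$init)["H2O2"]
#' @export
defaultScenario <- function(condition = c("control", "h2o2"), h2o2 = 500) {
  condition <- match.arg(condition)
  init <- defaultInitialState()
  if (condition == "h2o2") init <- applyOxidativeStress(init, h2o2)
  list(label = condition, params = defaultParameters(), init = init,
       h2o2 = if (condition == "h2o2") h2o2 else 0,
       tEnd = 200, nPoints = 201L)
}

#' Sample a randomized parameter set around the defaults
#'
#' Each rate constant is drawn log-uniformly within +/- \code{spread}
#' decades of its default. The activity-ratio constraint is preserved by
#' construction: k8 is sampled and k9 set to 200 k8.
#'
#' @param seed Integer seed; identical seeds give identical sets.
#' @param spread Half-width of the log10 sampling interval (decades),
#'   default 0.5. \code{spread = 0} returns the defaults.
#' @return A [ParameterSet-class].
#' @examples
#' rateConstants(sampleParameters(1))["k9"] /
#'   rateConstants(sampleParameters(1))["k8"]   # 200
#' @export
sampleParameters <- function(seed, spread = 0.5) {
  if (spread < 0) stop("spread must be >= 0")
  set.seed(as.integer(seed))
  lk <- log10(.DEFAULT_K)
  u <- stats::runif(13L, -spread, spread)
  k <- 10^(lk + u)
  k["k9"] <- 200 * k["k8"]
  ParameterSet(k)
}

#' Noisy synthetic cGMP time course
#'
#' Deterministic cGMP trajectory of a scenario plus additive zero-mean
#' Gaussian noise with standard deviation \code{sigma} expressed as a
#' fraction of the noiseless peak. Values are deliberately not clamped, so
#' small negative readings occur, as they would in a background-subtracted
#' immunoassay. \code{sigma = 0} reproduces the deterministic trajectory
#' exactly.
#'
#' @param scenario A scenario list as returned by [defaultScenario()], or a
#'   [SimulationResult-class].
#' @param sigma Noise SD as a fraction of peak cGMP (>= 0).
#' @param seed Integer seed for reproducibility.
#' @return data.frame with columns \code{time} and \code{cgmp}; attributes
#'   \code{sigma} and \code{seed}.
#' @examples
#' tc <- noisyTimecourse(defaultScenario("control"), sigma = 0.05, seed = 1)
#' head(tc)
#' @export
noisyTimecourse <- function(scenario, sigma = 0.05, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  res <- if (is(scenario, "SimulationResult")) scenario
         else simulatePathway(scenario$params, scenario$init,
                              tEnd = scenario$tEnd, nPoints = scenario$nPoints)
  cg <- res@trajectory[, "cGMP"]
  set.seed(as.integer(seed))
  noise <- if (sigma > 0) stats::rnorm(length(cg), 0, sigma * max(cg)) else 0
  out <- data.frame(time = res@time, cgmp = cg + noise)
  attr(out, "sigma") <- sigma
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Synthetic combination surfaces with known additivity class
#'
#' Closed-form dose-response surfaces used as classification oracles, built
#' on the same container as simulated surfaces so [classifyIsoboles()] treats
#' them identically.
#'
#' \describe{
#'   \item{\code{"additive"}}{Exact dose additivity: the effect depends only
#'     on the combined normalized dose \eqn{d_1/D_1 + d_2/D_2}, giving
#'     straight isoboles by construction.}
#'   \item{\code{"potentiation"}}{Each agent boosts the effective dose of the
#'     other multiplicatively, bowing isoboles toward the origin (synergy).}
#'   \item{\code{"antagonistic"}}{Sub-additive interaction penalizing the
#'     joint dose, bowing isoboles away from the origin.}
#' }
#'
#' @param type Surface type (see Details).
#' @param nPoints Grid points per axis (default 11).
#' @param rhoMin Minimum ratio on both axes (default 0.3, the pair
#'   convention).
#' @param strength Interaction strength for the non-additive types
#'   (default 2).
#' @return A [CombinationSurface-class] (targets set to the placeholder
#'   pair 1, 2).
#' @examples
#' classifyIsoboles(syntheticSurface("potentiation"))
#' @export
syntheticSurface <- function(type = c("additive", "potentiation",
                                      "antagonistic"),
                             nPoints = 11L, rhoMin = 0.3, strength = 2) {
  type <- match.arg(type)
  rho <- makeDoseVector(1L, rhoMin, nPoints)
  d <- 1 - rho
  D <- max(d)
  f <- function(s) s / (0.6 + s)  # saturating effect curve of combined dose
  vals <- outer(d, d, function(d1, d2) {
    s <- d1 / D + d2 / D
    s <- switch(type,
                additive = s,
                potentiation = s + strength * (d1 / D) * (d2 / D),
                antagonistic = s - strength * 0.45 * (d1 / D) * (d2 / D))
    1 + f(s)   # baseline 1 uM*s, effect on top
  })
  new("CombinationSurface", targets = c(1L, 2L),
      doses = list(rho, rho), values = vals, reference = vals[1L, 1L])
}

#' Exactly Bliss-independent two-channel response oracle
#'
#' A constructed response model in which the cGMP deficit below control is
#' produced by two non-interacting loss channels; each perturbation ratio
#' scales only its own channel's survival, so the combined fractional effect
#' obeys Bliss independence exactly:
#' \eqn{1 - E_{12} = (1 - E_1)(1 - E_2)} with
#' \eqn{E_i = 1 - \rho_i^{\gamma_i}}.
#' Used as the null oracle for the Bliss comparison machinery.
#'
#' @param rho1,rho2 Perturbation ratios in (0, 1] (vectorized).
#' @param control Control-level response (default 10).
#' @param baseline Unperturbed (both channels fully active) response
#'   (default 2); must be below \code{control}.
#' @param gamma Per-channel survival exponents, length 2 (default c(1, 1.5)).
#' @return Numeric response on the same scale as \code{control}.
#' @examples
#' independentLossResponse(0.5, 1)   # single-channel perturbation
#' @export
independentLossResponse <- function(rho1, rho2, control = 10, baseline = 2,
                                    gamma = c(1, 1.5)) {
  if (any(c(rho1, rho2) <= 0) || any(c(rho1, rho2) > 1))
    stop("ratios must lie in (0, 1]")
  if (baseline >= control) stop("baseline must be below control")
  deficit <- (control - baseline) * rho1^gamma[1L] * rho2^gamma[2L]
  control - deficit
}
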