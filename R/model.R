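## Mass-action right-hand side of the 12-species NO-cGMP pathway.
##
## Reactions: H2O2 oxidizes free sGC irreversibly (k1); NO binds/dissociates
## sGC (k2/k3) and free NO is lost to oxidation (k13); both sGC and NO-sGC
## bind GTP (k4/k5, k6/k7) and catalyze cGMP formation (k8, k9; the NO-bound
## route is 200x more active); PDE binds cGMP (k10/k11) and hydrolyzes it to
## GMP (k12).
.rhs <- function(y, k) {
  v1 <- k[1L] * y[1L] * y[2L]            # H2O2 + sGC -> sGC_H2O2
  v2 <- k[2L] * y[4L] * y[2L]            # NO + sGC -> NO_sGC
  v3 <- k[3L] * y[5L]                    # NO_sGC -> NO + sGC
  v4 <- k[4L] * y[2L] * y[6L]            # sGC + GTP -> sGC_GTP
  v5 <- k[5L] * y[7L]                    # sGC_GTP -> sGC + GTP
  v6 <- k[6L] * y[6L] * y[5L]            # NO_sGC + GTP -> NO_sGC_GTP
  v7 <- k[7L] * y[8L]                    # NO_sGC_GTP -> NO_sGC + GTP
  v8 <- k[8L] * y[7L]                    # sGC_GTP -> sGC + cGMP
  v9 <- k[9L] * y[8L]                    # NO_sGC_GTP -> NO_sGC + cGMP
  v10 <- k[10L] * y[9L] * y[10L]         # cGMP + PDE -> cGMP_PDE
  v11 <- k[11L] * y[11L]                 # cGMP_PDE -> cGMP + PDE
  v12 <- k[12L] * y[11L]                 # cGMP_PDE -> GMP + PDE
  v13 <- k[13L] * y[4L]                  # NO -> NOx (oxidative loss)
  c(-v1,                                 # H2O2
    -v1 - v2 + v3 - v4 + v5 + v8,        # sGC
    v1,                                  # sGC_H2O2
    -v2 + v3 - v13,                      # NO
    v2 - v3 - v6 + v7 + v9,              # NO_sGC
    -v4 + v5 - v6 + v7,                  # GTP
    v4 - v5 - v8,                        # sGC_GTP
    v6 - v7 - v9,                        # NO_sGC_GTP
    v8 + v9 - v10 + v11,                 # cGMP
    -v10 + v11 + v12,                    # PDE
    v10 - v11 - v12,                     # cGMP_PDE
    v12)                                 # GMP
}

#' Time derivatives of the pathway state
#'
#' Evaluates the mass-action right-hand side d[species]/dt for all 12 species
#' at the given state. Exposed mainly for inspection and testing; the solver
#' calls an internal equivalent.
#'
#' @param state An [InitialState-class] or named numeric vector over the
#'   canonical species (uM).
#' @param params A [ParameterSet-class].
#' @param strict Reject negative concentrations (default TRUE).
#' @return Named numeric vector of derivatives (uM/s) in canonical order.
#' @examples
#' st <- InitialState(H2O2 = 1, sGC = 1)
#' ps <- ParameterSet(stats::setNames(c(0.01, rep(0, 12)), paste0("k", 1:13)))
#' pathwayDerivatives(st, ps)
#' @export
pathwayDerivatives <- function(state, params, strict = TRUE) {
  stopifnot(is(params, "ParameterSet"))
  y <- if (is(state, "InitialState")) state@conc else state
  if (length(y) != 12L)
    stop("state must have 12 species")
  if (!is.null(names(y)) && !identical(names(y), speciesNames()))
    stop("state names must follow the canonical species ordering")
  if (strict && any(y < 0))
    stop("negative concentrations in state: ",
         paste(speciesNames()[y < 0], collapse = ", "))
  stats::setNames(.rhs(as.numeric(y), params@k), speciesNames())
}

#' Simulate the NO-cGMP pathway
#'
#' Integrates the 12-ODE mass-action model with a stiff-capable solver
#' (deSolve's lsoda, the variable-order ode15s analog) and returns the
#' solution on a uniform time grid. Small negative undershoots within
#' 100 x \code{atol} of zero are clamped to zero; larger negative values
#' abort with an error since they indicate genuine instability.
#'
#' @param params A [ParameterSet-class].
#' @param init An [InitialState-class].
#' @param tEnd End of the simulation window (s), default 200.
#' @param nPoints Number of uniform grid points including t = 0, default 201
#'   (1-s resolution over the standard window).
#' @param rtol,atol Solver tolerances (defaults 1e-8 and 1e-10 uM).
#' @param method deSolve integration method, default \code{"lsoda"}.
#' @return A [SimulationResult-class].
#' @examples
#' sc <- defaultScenario("control")
#' res <- simulatePathway(sc$params, sc$init)
#' max(trajectory(res, "cGMP"))
#' @export
simulatePathway <- function(params, init, tEnd = 200, nPoints = 201L,
                            rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  stopifnot(is(params, "ParameterSet"), is(init, "InitialState"))
  if (!is.numeric(tEnd) || tEnd <= 0) stop("tEnd must be > 0")
  if (nPoints < 2L) stop("nPoints must be >= 2")
  times <- seq(0, tEnd, length.out = nPoints)
  k <- params@k
  deriv <- function(t, y, p) list(.rhs(y, k))
  sol <- deSolve::ode(y = init@conc, times = times, func = deriv,
                      parms = NULL, method = method, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop("ODE integration failed (istate = ", attr(sol, "istate")[1L],
         "); see deSolve diagnostics")
  traj <- unname(sol[, -1L, drop = FALSE])
  colnames(traj) <- speciesNames()
  low <- traj < 0
  if (any(low)) {
    if (min(traj[low]) < -100 * atol)
      stop("trajectory undershoot below -100*atol (min ",
           format(min(traj[low])), " uM): integration unstable")
    traj[low] <- 0
  }
  traj[1L, ] <- init@conc  # first row is the initial state exactly
  new("SimulationResult", time = times, trajectory = traj,
      params = params, init = init,
      solver = list(method = method, rtol = rtol, atol = atol))
}

#' @rdname simTime
setMethod("simTime", "SimulationResult", function(object) object@time)

#' @rdname trajectory
setMethod("trajectory", "SimulationResult", function(object, species = NULL) {
  if (is.null(species)) return(object@trajectory)
  bad <- setdiff(species, speciesNames())
  if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
  object@trajectory[, species]
})

setMethod("show", "SimulationResult", function(object) {
  cat(sprintf("SimulationResult: %d time points over [0, %g] s (%s, rtol %g)\n",
              length(object@time), max(object@time),
              object@solver$method, object@solver$rtol))
  cg <- object@trajectory[, "cGMP"]
  cat(sprintf("  peak cGMP %.4g uM at t = %g s; final %.4g uM\n",
              max(cg), object@time[which.max(cg)], cg[length(cg)]))
})

#' Tidy data frame of a trajectory
#'
#' @param result A [SimulationResult-class].
#' @return data.frame with column \code{time} plus the 12 species.
#' @export
asTrajectoryFrame <- function(result) {
  stopifnot(is(result, "SimulationResult"))
  data.frame(time = result@time, result@trajectory, check.names = FALSE)
}

## Classical fixed-step RK4 integrator: the reference oracle used to verify
## the adaptive solver on short horizons. Not exported.
.rk4Reference <- function(params, init, tEnd, dt) {
  k <- params@k
  y <- init@conc
  nstep <- round(tEnd / dt)
  for (i in seq_len(nstep)) {
    f1 <- .rhs(y, k)
    f2 <- .rhs(y + dt / 2 * f1, k)
    f3 <- .rhs(y + dt / 2 * f2, k)
    f4 <- .rhs(y + dt * f3, k)
    y <- y + dt / 6 * (f1 + 2 * f2 + 2 * f3 + f4)
  }
  y
}
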