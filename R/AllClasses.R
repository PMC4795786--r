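#' @import methods
NULL

#' Canonical species ordering of the pathway model
#'
#' The 12 molecular species of the NO-cGMP pathway in the fixed order used by
#' every state vector, trajectory matrix, and parameter file in the package:
#' H2O2, sGC, sGC_H2O2, NO, NO_sGC, GTP, sGC_GTP, NO_sGC_GTP, cGMP, PDE,
#' cGMP_PDE, GMP. Concentrations are in micromolar throughout.
#'
#' @return Character vector of the 12 species names.
#' @examples
#' speciesNames()
#' @export
speciesNames <- function() {
  c("H2O2", "sGC", "sGC_H2O2", "NO", "NO_sGC", "GTP",
    "sGC_GTP", "NO_sGC_GTP", "cGMP", "PDE", "cGMP_PDE", "GMP")
}

.RATE_NAMES <- paste0("k", 1:13)

## bimolecular constants have units 1/(uM s); the rest 1/s
.BIMOLECULAR <- c("k1", "k2", "k4", "k6", "k10")

#' ParameterSet: the 13 mass-action rate constants
#'
#' Container for the rate constants k1..k13 of the NO-cGMP pathway model.
#' Bimolecular constants (k1, k2, k4, k6, k10) are in 1/(uM*s); unimolecular
#' constants in 1/s. All values must be finite and non-negative.
#'
#' @slot k Named numeric vector of length 13 (names \code{k1..k13}).
#' @seealso [ParameterSet()], [defaultParameters()], [rateConstants()]
#' @export
setClass("ParameterSet", representation(k = "numeric"))

setValidity("ParameterSet", function(object) {
  k <- object@k
  msgs <- character()
  if (length(k) != 13L || !identical(names(k), .RATE_NAMES))
    msgs <- c(msgs, "k must be a named numeric vector k1..k13 in order")
  if (any(!is.finite(k)))
    msgs <- c(msgs, paste("non-finite rate constants:",
                          paste(names(k)[!is.finite(k)], collapse = ", ")))
  else if (any(k < 0))
    msgs <- c(msgs, paste("negative rate constants:",
                          paste(names(k)[k < 0], collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' InitialState: concentrations of the 12 molecular species
#'
#' Named concentration vector (uM) over the canonical species ordering
#' (see [speciesNames()]). All concentrations must be finite and
#' non-negative.
#'
#' @slot conc Named numeric vector of length 12 in canonical species order.
#' @seealso [InitialState()], [defaultInitialState()], [applyOxidativeStress()]
#' @export
setClass("InitialState", representation(conc = "numeric"))

setValidity("InitialState", function(object) {
  x <- object@conc
  msgs <- character()
  if (length(x) != 12L || !identical(names(x), speciesNames()))
    msgs <- c(msgs, "conc must be named over the canonical 12 species, in order")
  if (any(!is.finite(x)))
    msgs <- c(msgs, "non-finite concentrations")
  else if (any(x < 0))
    msgs <- c(msgs, paste("negative concentrations:",
                          paste(names(x)[x < 0], collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' SimulationResult: one ODE solve of the pathway model
#'
#' Holds the uniform time grid, the trajectory matrix (one row per time point,
#' one column per species in canonical order), the inputs that produced it,
#' and solver metadata (integration method and tolerances).
#'
#' @slot time Numeric time grid (s), strictly increasing, starting at 0.
#' @slot trajectory Numeric matrix, \code{length(time)} rows x 12 columns.
#' @slot params The [ParameterSet-class] used.
#' @slot init The [InitialState-class] used.
#' @slot solver List with entries \code{method}, \code{rtol}, \code{atol}.
#' @seealso [simulatePathway()], [trajectory()], [integrateCGMP()]
#' @export
setClass("SimulationResult",
         representation(time = "numeric", trajectory = "matrix",
                        params = "ParameterSet", init = "InitialState",
                        solver = "list"))

setValidity("SimulationResult", function(object) {
  msgs <- character()
  if (nrow(object@trajectory) != length(object@time))
    msgs <- c(msgs, "trajectory row count must equal time grid length")
  if (!identical(colnames(object@trajectory), speciesNames()))
    msgs <- c(msgs, "trajectory columns must be the canonical species")
  if (length(object@time) >= 2L && any(diff(object@time) <= 0))
    msgs <- c(msgs, "time grid must be strictly increasing")
  if (length(msgs)) msgs else TRUE
})

#' PerturbationSpec: which rate constants to inhibit, and how strongly
#'
#' A perturbation multiplies 1-3 distinct rate constants by fractional
#' ratios rho in (0, 1], emulating concentration-dependent inhibition of the
#' corresponding reactions (rho = 0.1 models a strong inhibitor).
#'
#' @slot targets Integer indices in 1..13, distinct, sorted ascending.
#' @slot ratios Numeric multipliers in (0, 1], one per target.
#' @seealso [PerturbationSpec()], [applyPerturbation()], [screenPerturbations()]
#' @export
setClass("PerturbationSpec",
         representation(targets = "integer", ratios = "numeric"))

setValidity("PerturbationSpec", function(object) {
  t <- object@targets; r <- object@ratios
  msgs <- character()
  if (length(t) < 1L || length(t) > 13L)
    msgs <- c(msgs, "need between 1 and 13 targets")
  if (any(t < 1L | t > 13L)) msgs <- c(msgs, "targets must be in 1..13")
  if (anyDuplicated(t)) msgs <- c(msgs, "targets must be distinct")
  if (is.unsorted(t)) msgs <- c(msgs, "targets must be sorted ascending")
  if (length(r) != length(t))
    msgs <- c(msgs, "one ratio per target required")
  if (any(!is.finite(r)) || any(r <= 0) || any(r > 1))
    msgs <- c(msgs, "ratios must lie in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' CombinationSurface: cGMP_T over a 2-D or 3-D dose matrix
#'
#' Full-factorial evaluation of time-integrated cGMP over per-axis dose
#' vectors of perturbation ratios (11 points per axis by convention, from 1.0
#' down to the convention minimum). \code{values} holds raw cGMP_T (uM*s);
#' \code{reference} is the unperturbed-H2O2 cGMP_T used for normalization.
#'
#' @slot targets Integer vector of 2 or 3 rate-constant indices (axis order).
#' @slot doses List of per-axis ratio vectors (descending from 1.0).
#' @slot values Numeric array, one dimension per axis.
#' @slot reference Numeric scalar, cGMP_T at all ratios = 1.
#' @seealso [buildSurface()], [classifyIsoboles()], [surfaceValues()]
#' @export
setClass("CombinationSurface",
         representation(targets = "integer", doses = "list",
                        values = "array", reference = "numeric"))

setValidity("CombinationSurface", function(object) {
  msgs <- character()
  nax <- length(object@targets)
  if (nax < 2L || nax > 3L) msgs <- c(msgs, "2 or 3 axis targets required")
  if (length(object@doses) != nax)
    msgs <- c(msgs, "one dose vector per axis required")
  if (!identical(dim(object@values), vapply(object@doses, length, 1L)))
    msgs <- c(msgs, "values dimensions must match dose vector lengths")
  if (any(object@values < 0, na.rm = TRUE))
    msgs <- c(msgs, "cGMP_T values must be non-negative")
  if (length(msgs)) msgs else TRUE
})
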