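#' Extract or replace the rate constants of a ParameterSet
#'
#' @param object A [ParameterSet-class].
#' @param value Named numeric vector \code{k1..k13}.
#' @return Named numeric vector of the 13 rate constants.
#' @examples
#' rateConstants(defaultParameters())[c("k8", "k9")]
#' @export
setGeneric("rateConstants", function(object) standardGeneric("rateConstants"))

#' @rdname rateConstants
#' @export
setGeneric("rateConstants<-",
           function(object, value) standardGeneric("rateConstants<-"))

#' Extract the species concentrations of an InitialState
#'
#' @param object An [InitialState-class].
#' @return Named numeric vector (uM) over the canonical species.
#' @export
setGeneric("speciesConcentrations",
           function(object) standardGeneric("speciesConcentrations"))

#' Time grid of a simulation
#'
#' @param object A [SimulationResult-class].
#' @return Numeric vector of time points (s).
#' @export
setGeneric("simTime", function(object) standardGeneric("simTime"))

#' Trajectory matrix of a simulation
#'
#' @param object A [SimulationResult-class].
#' @param species Optional character vector selecting species columns.
#' @return Numeric matrix (time points x species), or a vector when a single
#'   species is selected.
#' @export
setGeneric("trajectory",
           function(object, species = NULL) standardGeneric("trajectory"))

#' Dose grid values of a combination surface
#'
#' @param object A [CombinationSurface-class].
#' @param relative Logical; return values normalized to the unperturbed
#'   reference instead of raw uM*s.
#' @return Numeric array (11x11 or 11x11x11 under default conventions).
#' @export
setGeneric("surfaceValues",
           function(object, relative = FALSE) standardGeneric("surfaceValues"))
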