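#' Construct a ParameterSet
#'
#' @param ... Either a single named numeric vector of the 13 rate constants,
#'   or individual \code{k1 = ..., ..., k13 = ...} arguments. All 13 must be
#'   supplied.
#' @return A validated [ParameterSet-class].
#' @examples
#' ps <- ParameterSet(rateConstants(defaultParameters()))
#' @export
ParameterSet <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.numeric(args[[1]]) && length(args[[1]]) > 1L) {
    k <- args[[1]]
  } else {
    k <- unlist(args)
  }
  missing <- setdiff(.RATE_NAMES, names(k))
  unknown <- setdiff(names(k), .RATE_NAMES)
  if (length(missing) || length(unknown))
    stop("ParameterSet: ",
         if (length(missing)) paste0("missing ", paste(missing, collapse = ", ")),
         if (length(missing) && length(unknown)) "; ",
         if (length(unknown)) paste0("unknown ", paste(unknown, collapse = ", ")))
  new("ParameterSet", k = as.numeric(k[.RATE_NAMES]) |> stats::setNames(.RATE_NAMES))
}

#' Construct an InitialState
#'
#' Species not mentioned default to 0 uM.
#'
#' @param ... Either a single named numeric vector, or individual
#'   \code{species = concentration} arguments (uM). Names must be canonical
#'   species names; see [speciesNames()].
#' @return A validated [InitialState-class].
#' @examples
#' InitialState(NO = 0.5, sGC = 0.2, GTP = 50, PDE = 0.03)
#' @export
InitialState <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.numeric(args[[1]]) && length(args[[1]]) > 1L) {
    x <- args[[1]]
  } else {
    x <- unlist(args)
  }
  unknown <- setdiff(names(x), speciesNames())
  if (length(unknown))
    stop("InitialState: unknown species: ", paste(unknown, collapse = ", "))
  conc <- stats::setNames(numeric(12), speciesNames())
  conc[names(x)] <- as.numeric(x)
  new("InitialState", conc = conc)
}

#' @rdname rateConstants
setMethod("rateConstants", "ParameterSet", function(object) object@k)

#' @rdname rateConstants
setReplaceMethod("rateConstants", "ParameterSet", function(object, value) {
  object@k <- value
  validObject(object)
  object
})

#' @rdname speciesConcentrations
setMethod("speciesConcentrations", "InitialState", function(object) object@conc)

setMethod("show", "ParameterSet", function(object) {
  cat("ParameterSet (13 mass-action rate constants)\n")
  k <- object@k
  units <- ifelse(.RATE_NAMES %in% .BIMOLECULAR, "1/(uM s)", "1/s")
  for (i in seq_along(k))
    cat(sprintf("  %-4s %12.6g  %s\n", names(k)[i], k[i], units[i]))
})

setMethod("show", "InitialState", function(object) {
  cat("InitialState (uM)\n")
  nz <- object@conc[object@conc != 0]
  if (length(nz)) for (i in seq_along(nz))
    cat(sprintf("  %-11s %10.4g\n", names(nz)[i], nz[i]))
  z <- names(object@conc)[object@conc == 0]
  if (length(z)) cat("  zero:", paste(z, collapse = ", "), "\n")
})

#' Set the oxidant dose of an initial state
#'
#' Returns a copy of \code{init} with the H2O2 concentration replaced (not
#' added) by \code{h2o2}; all other species are unchanged. The oxidant
#' challenge used throughout the package is 500 uM.
#'
#' @param init An [InitialState-class].
#' @param h2o2 Non-negative H2O2 concentration (uM).
#' @return A new [InitialState-class].
#' @examples
#' applyOxidativeStress(defaultInitialState(), 500)
#' @export
applyOxidativeStress <- function(init, h2o2) {
  stopifnot(is(init, "InitialState"))
  if (!is.numeric(h2o2) || length(h2o2) != 1L || !is.finite(h2o2) || h2o2 < 0)
    stop("h2o2 must be a single non-negative concentration (uM)")
  conc <- init@conc
  conc["H2O2"] <- h2o2
  new("InitialState", conc = conc)
}
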