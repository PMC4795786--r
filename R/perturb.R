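#' Construct a PerturbationSpec
#'
#' @param targets Integer rate-constant indices (1..13), 1 to 3 of them,
#'   distinct. Stored sorted ascending (ratios are reordered along).
#' @param ratios Fractional multipliers in (0, 1]; recycled to length of
#'   \code{targets} if scalar.
#' @return A validated [PerturbationSpec-class].
#' @examples
#' PerturbationSpec(c(1, 3, 10), 0.1)
#' @export
PerturbationSpec <- function(targets, ratios = 0.1) {
  targets <- as.integer(targets)
  if (length(ratios) == 1L) ratios <- rep(ratios, length(targets))
  o <- order(targets)
  new("PerturbationSpec", targets = targets[o], ratios = as.numeric(ratios)[o])
}

setMethod("show", "PerturbationSpec", function(object) {
  cat("PerturbationSpec:",
      paste(sprintf("k%d x %g", object@targets, object@ratios), collapse = ", "),
      "\n")
})

#' Enumerate all perturbation target sets
#'
#' All subsets of \{1..q\} of size 1..maxOrder in deterministic lexicographic
#' order (all singles, then all pairs, ...). For the model's q = 13 constants
#' and maxOrder = 3 this gives 13 + 78 + 286 = 377 sets.
#'
#' @param q Number of rate constants (default 13).
#' @param maxOrder Maximum perturbation order (default 3).
#' @return List of integer vectors (the target sets).
#' @examples
#' length(enumeratePerturbations(13, 3))  # 377
#' @export
enumeratePerturbations <- function(q = 13L, maxOrder = 3L) {
  q <- as.integer(q); maxOrder <- as.integer(maxOrder)
  if (q < 1L) stop("q must be >= 1")
  if (maxOrder < 1L || maxOrder > q)
    stop("maxOrder must be between 1 and q")
  out <- list()
  for (m in seq_len(maxOrder)) {
    cm <- utils::combn(q, m, simplify = FALSE)
    out <- c(out, lapply(cm, as.integer))
  }
  out
}

#' Apply a perturbation to a parameter set
#'
#' Returns a new [ParameterSet-class] with each targeted constant multiplied
#' by its ratio; the input is untouched.
#'
#' @param params A [ParameterSet-class].
#' @param spec A [PerturbationSpec-class].
#' @return A new [ParameterSet-class].
#' @examples
#' p <- applyPerturbation(defaultParameters(), PerturbationSpec(10, 0.1))
#' rateConstants(p)["k10"] / rateConstants(defaultParameters())["k10"]
#' @export
applyPerturbation <- function(params, spec) {
  stopifnot(is(params, "ParameterSet"), is(spec, "PerturbationSpec"))
  k <- params@k
  k[spec@targets] <- k[spec@targets] * spec@ratios
  new("ParameterSet", k = k)
}

#' Time-integrated cGMP (cGMP_T)
#'
#' Composite trapezoidal integral of the cGMP trajectory over [0, horizon],
#' the screening metric of the package (uM*s). The simulation grid must cover
#' the horizon.
#'
#' @param result A [SimulationResult-class].
#' @param horizon Upper integration limit T (s), default 200.
#' @return Numeric scalar, cGMP_T.
#' @export
integrateCGMP <- function(result, horizon = 200) {
  stopifnot(is(result, "SimulationResult"))
  tt <- result@time
  if (horizon <= 0) stop("horizon must be > 0")
  if (max(tt) < horizon - 1e-9)
    stop("time grid ends at ", max(tt), " s; cannot integrate to ", horizon)
  keep <- tt <= horizon + 1e-9
  pracma::trapz(tt[keep], result@trajectory[keep, "cGMP"])
}

## cGMP_T, peak and peak time for one perturbed parameter set; shared by the
## screen and the dose-response/surface builders so that identical inputs
## produce bit-identical numbers everywhere.
.responseAt <- function(params, init, targets, ratios, tEnd, nPoints, horizon) {
  spec <- PerturbationSpec(targets, ratios)
  res <- simulatePathway(applyPerturbation(params, spec), init,
                         tEnd = tEnd, nPoints = nPoints)
  cg <- res@trajectory[, "cGMP"]
  list(cgmpT = integrateCGMP(res, horizon),
       peak = max(cg), peakTime = res@time[which.max(cg)])
}

#' Screen all single, paired, and triple perturbations
#'
#' Enumerates every target set up to \code{maxOrder}, applies the uniform
#' inhibition ratio \code{rho} to each targeted constant, simulates the
#' oxidant-challenged system, and ranks the perturbations by time-integrated
#' cGMP. 377 simulations for the default q = 13, maxOrder = 3.
#'
#' Solver failures are recorded per spec (status \code{"failed"}, NA metrics)
#' with a warning and excluded from the ranking, never silently dropped.
#'
#' @param params A [ParameterSet-class] (unperturbed).
#' @param init An [InitialState-class]; pass the oxidant condition, e.g.
#'   \code{applyOxidativeStress(defaultInitialState(), 500)}.
#' @param maxOrder Maximum perturbation order (default 3).
#' @param rho Uniform fractional ratio applied to every target (default 0.1).
#' @param horizon Integration horizon T for cGMP_T (s, default 200).
#' @param tEnd,nPoints Simulation window and grid (defaults 200 s, 201).
#' @param controlInit Optional [InitialState-class] for the no-oxidant
#'   control; when supplied, a \code{relative_to_control} column is added.
#' @return data.frame with one row per perturbation, sorted by decreasing
#'   \code{cgmp_T} (ties broken lexicographically by target set): columns
#'   \code{targets} (comma-separated indices), \code{order}, \code{rho},
#'   \code{cgmp_T}, \code{relative_cgmp_T} (normalized to the unperturbed
#'   condition given by \code{init}), \code{peak_cgmp}, \code{peak_time},
#'   \code{status}, and optionally \code{relative_to_control}.
#' @examples
#' sc <- defaultScenario("h2o2")
#' head(screenPerturbations(sc$params, sc$init, maxOrder = 1))
#' @export
screenPerturbations <- function(params, init, maxOrder = 3L, rho = 0.1,
                                horizon = 200, tEnd = 200, nPoints = 201L,
                                controlInit = NULL) {
  if (!is.numeric(rho) || rho <= 0 || rho > 1)
    stop("rho must lie in (0, 1]")
  sets <- enumeratePerturbations(13L, maxOrder)
  base <- .responseAt(params, init, 1L, 1.0, tEnd, nPoints, horizon)
  rows <- lapply(sets, function(s) {
    r <- tryCatch(.responseAt(params, init, s, rho, tEnd, nPoints, horizon),
                  error = function(e) e)
    if (inherits(r, "error")) {
      list(targets = paste(s, collapse = ","), order = length(s),
           cgmp_T = NA_real_, peak_cgmp = NA_real_, peak_time = NA_real_,
           status = paste0("failed: ", conditionMessage(r)))
    } else {
      list(targets = paste(s, collapse = ","), order = length(s),
           cgmp_T = r$cgmpT, peak_cgmp = r$peak, peak_time = r$peakTime,
           status = "ok")
    }
  })
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(targets = r$targets, order = r$order, rho = rho,
               cgmp_T = r$cgmp_T, relative_cgmp_T = r$cgmp_T / base$cgmpT,
               peak_cgmp = r$peak_cgmp, peak_time = r$peak_time,
               status = r$status, stringsAsFactors = FALSE)))
  if (!is.null(controlInit)) {
    ctrl <- .responseAt(params, controlInit, 1L, 1.0, tEnd, nPoints, horizon)
    df$relative_to_control <- df$cgmp_T / ctrl$cgmpT
  }
  nfail <- sum(df$status != "ok")
  if (nfail > 0)
    warning(nfail, " perturbation(s) failed to integrate; ",
            "kept with status 'failed' and excluded from ranking")
  ok <- df$status == "ok"
  ## sort: failures last; descending cGMP_T; lexicographic target tie-break
  key <- df$targets
  o <- order(!ok, -ifelse(ok, df$cgmp_T, -Inf), key, method = "radix")
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  df
}
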