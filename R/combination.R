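#' Linearly spaced dose vector of perturbation ratios
#'
#' Eleven multipliers descending linearly from 1.0 (no inhibition) to
#' \code{rhoMin}. The convention minima are 0.1, 0.3, and 0.5 for single,
#' paired, and triple perturbations respectively (deeper inhibition is
#' explored when fewer reactions are hit, mimicking dose-limited toxicity of
#' combination therapy).
#'
#' @param target Rate-constant index in 1..13 (recorded as an attribute).
#' @param rhoMin Minimum ratio, in (0, 1).
#' @param nPoints Number of points (default 11).
#' @return Numeric vector of length \code{nPoints}, strictly decreasing from
#'   1.0 to \code{rhoMin}, with attribute \code{target}.
#' @examples
#' makeDoseVector(1, 0.1)   # 1.00, 0.91, ..., 0.10
#' @export
makeDoseVector <- function(target, rhoMin, nPoints = 11L) {
  target <- as.integer(target)
  if (length(target) != 1L || target < 1L || target > 13L)
    stop("target must be a single index in 1..13")
  if (!is.numeric(rhoMin) || rhoMin <= 0 || rhoMin >= 1)
    stop("rhoMin must lie strictly between 0 and 1")
  v <- seq(1, rhoMin, length.out = nPoints)
  attr(v, "target") <- target
  v
}

## convention: deeper minima for lower perturbation orders
.conventionRhoMin <- function(order) c(0.1, 0.3, 0.5)[order]

#' One-dimensional dose response of a single rate constant
#'
#' Simulates the system once per ratio in the dose vector and reports
#' absolute and relative responses. No monotonicity is implied or enforced.
#'
#' @param params A [ParameterSet-class].
#' @param init An [InitialState-class] (typically the oxidant condition).
#' @param target Rate-constant index in 1..13.
#' @param ratios Dose vector, default the 11-point single-perturbation
#'   convention vector down to 0.1.
#' @param horizon,tEnd,nPoints Simulation window controls.
#' @return data.frame with columns \code{target}, \code{rho}, \code{cgmp_T},
#'   \code{relative_cgmp_T} (to the rho = 1 unperturbed value),
#'   \code{peak_cgmp}, \code{peak_time}, \code{status}.
#' @examples
#' sc <- defaultScenario("h2o2")
#' doseResponse(sc$params, sc$init, 3, makeDoseVector(3, 0.5, 3))
#' @export
doseResponse <- function(params, init, target,
                         ratios = makeDoseVector(target, 0.1),
                         horizon = 200, tEnd = 200, nPoints = 201L) {
  target <- as.integer(target)
  rows <- lapply(ratios, function(rho) {
    r <- tryCatch(.responseAt(params, init, target, rho, tEnd, nPoints, horizon),
                  error = function(e) e)
    if (inherits(r, "error"))
      data.frame(target = target, rho = rho, cgmp_T = NA_real_,
                 peak_cgmp = NA_real_, peak_time = NA_real_,
                 status = paste0("failed: ", conditionMessage(r)))
    else
      data.frame(target = target, rho = rho, cgmp_T = r$cgmpT,
                 peak_cgmp = r$peak, peak_time = r$peakTime, status = "ok")
  })
  df <- do.call(rbind, rows)
  base <- .responseAt(params, init, target, 1.0, tEnd, nPoints, horizon)
  df$relative_cgmp_T <- df$cgmp_T / base$cgmpT
  df[, c("target", "rho", "cgmp_T", "relative_cgmp_T",
         "peak_cgmp", "peak_time", "status")]
}

#' Bliss-independence prediction for a combined effect
#'
#' Two modes are provided. \code{"response-product"} (default) is standard
#' Bliss independence on fractional effects in [0, 1]:
#' \deqn{E_{ij} = E_i + E_j - E_i E_j.}
#' \code{"ratio-product"} instead multiplies the two perturbation ratios
#' themselves (the combined ratio of a pair is the product of the individual
#' ratios), a literal reading of treating the joint perturbation as the
#' product of its parts. The effect-scale mode is the one used for the
#' observed-vs-predicted comparisons.
#'
#' @param effectI,effectJ Fractional effects (response-product mode, each in
#'   [0, 1]) or perturbation ratios (ratio-product mode, each in (0, 1]).
#' @param mode \code{"response-product"} or \code{"ratio-product"}.
#' @return Numeric scalar: predicted combined effect (or combined ratio).
#' @examples
#' blissPredict(0.5, 0.5)                       # 0.75
#' blissPredict(0.1, 0.1, "ratio-product")      # 0.01
#' @export
blissPredict <- function(effectI, effectJ,
                         mode = c("response-product", "ratio-product")) {
  mode <- match.arg(mode)
  if (mode == "response-product") {
    if (any(c(effectI, effectJ) < 0) || any(c(effectI, effectJ) > 1))
      stop("response-product mode expects fractional effects in [0, 1]")
    effectI + effectJ - effectI * effectJ
  } else {
    if (any(c(effectI, effectJ) <= 0) || any(c(effectI, effectJ) > 1))
      stop("ratio-product mode expects ratios in (0, 1]")
    effectI * effectJ
  }
}

#' Compare an observed pairwise perturbation with the Bliss prediction
#'
#' Simulates the two single perturbations and the pair, converts cGMP_T
#' responses to fractional effects on the span between the unperturbed
#' oxidant condition and the no-oxidant control, and reports the observed
#' combined effect against the Bliss-independent prediction. A positive
#' excess means the pair outperforms independent action of its parts.
#'
#' Effects are clipped into [0, 1] for the prediction only when
#' \code{clip = TRUE} (default FALSE raises an error if a single
#' perturbation already exceeds the control level).
#'
#' @param params A [ParameterSet-class].
#' @param init Oxidant-condition [InitialState-class].
#' @param controlInit No-oxidant control [InitialState-class]; defines the
#'   effect scale together with \code{init}.
#' @param pair Integer vector of 2 distinct rate-constant indices.
#' @param rho Ratio applied to each member (default 0.3, the pairwise
#'   dose-vector convention minimum).
#' @param horizon,tEnd,nPoints Simulation window controls.
#' @param clip Clip single effects into [0, 1] before prediction.
#' @return List with elements \code{pair}, \code{rho}, \code{effects} (the
#'   two single fractional effects), \code{predicted} and \code{observed}
#'   (fractional combined effects), \code{excess} (observed - predicted),
#'   \code{cgmp_T} (named: single i, single j, pair, baseline, control), and
#'   \code{predicted_cgmp_T}.
#' @examples
#' sc <- defaultScenario("h2o2"); ct <- defaultScenario("control")
#' cmp <- blissComparison(sc$params, sc$init, ct$init, c(1, 3), rho = 0.3)
#' cmp$excess > 0
#' @export
blissComparison <- function(params, init, controlInit, pair, rho = 0.3,
                            horizon = 200, tEnd = 200, nPoints = 201L,
                            clip = FALSE) {
  pair <- sort(as.integer(pair))
  if (length(pair) != 2L || anyDuplicated(pair))
    stop("pair must be 2 distinct rate-constant indices")
  base <- .responseAt(params, init, 1L, 1.0, tEnd, nPoints, horizon)$cgmpT
  ctrl <- .responseAt(params, controlInit, 1L, 1.0, tEnd, nPoints, horizon)$cgmpT
  span <- ctrl - base
  if (span <= 0)
    stop("control response does not exceed the oxidant baseline; ",
         "effect scale undefined")
  ri <- .responseAt(params, init, pair[1L], rho, tEnd, nPoints, horizon)$cgmpT
  rj <- .responseAt(params, init, pair[2L], rho, tEnd, nPoints, horizon)$cgmpT
  rij <- .responseAt(params, init, pair, rho, tEnd, nPoints, horizon)$cgmpT
  eff <- (c(ri, rj) - base) / span
  if (clip) eff <- pmin(pmax(eff, 0), 1)
  pred <- blissPredict(eff[1L], eff[2L])
  obs <- (rij - base) / span
  list(pair = pair, rho = rho,
       effects = stats::setNames(eff, paste0("k", pair)),
       predicted = pred, observed = obs, excess = obs - pred,
       cgmp_T = c(single_i = ri, single_j = rj, pair = rij,
                  baseline = base, control = ctrl),
       predicted_cgmp_T = base + pred * span)
}

#' Build a 2-D or 3-D combination dose surface
#'
#' Full-factorial simulation of cGMP_T over per-axis dose vectors (11 points
#' per axis by default: 121 solves for a pair, 1331 for a triple). The
#' convention minima are 0.3 (pairs) and 0.5 (triples) unless overridden.
#'
#' @param params A [ParameterSet-class].
#' @param init Oxidant-condition [InitialState-class].
#' @param targets 2 or 3 distinct rate-constant indices (axis order).
#' @param rhoMin Per-axis minimum ratio; scalar or one per axis. Defaults to
#'   the order convention.
#' @param nPoints Grid points per axis (default 11).
#' @param horizon,tEnd,nGrid Simulation window controls (\code{nGrid} is the
#'   time grid size per solve).
#' @return A [CombinationSurface-class].
#' @examples
#' sc <- defaultScenario("h2o2")
#' surf <- buildSurface(sc$params, sc$init, c(1, 3), nPoints = 3)
#' dim(surfaceValues(surf))
#' @export
buildSurface <- function(params, init, targets, rhoMin = NULL, nPoints = 11L,
                         horizon = 200, tEnd = 200, nGrid = 201L) {
  targets <- as.integer(targets)
  if (length(targets) < 2L || length(targets) > 3L || anyDuplicated(targets))
    stop("targets must be 2 or 3 distinct rate-constant indices")
  if (is.null(rhoMin)) rhoMin <- .conventionRhoMin(length(targets))
  rhoMin <- rep(rhoMin, length.out = length(targets))
  doses <- lapply(seq_along(targets), function(i)
    makeDoseVector(targets[i], rhoMin[i], nPoints))
  dims <- vapply(doses, length, 1L)
  grid <- as.matrix(expand.grid(lapply(doses, as.numeric),
                                KEEP.OUT.ATTRS = FALSE))
  vals <- apply(grid, 1L, function(rr)
    .responseAt(params, init, targets, rr, tEnd, nGrid, horizon)$cgmpT)
  arr <- array(vals, dim = dims)
  ref <- .responseAt(params, init, 1L, 1.0, tEnd, nGrid, horizon)$cgmpT
  new("CombinationSurface", targets = targets, doses = doses,
      values = arr, reference = ref)
}

#' @rdname surfaceValues
setMethod("surfaceValues", "CombinationSurface",
          function(object, relative = FALSE) {
  if (relative) object@values / object@reference else object@values
})

#' Axis targets of a combination surface
#' @param surface A [CombinationSurface-class].
#' @return Integer vector of rate-constant indices.
#' @export
surfaceTargets <- function(surface) surface@targets

#' Per-axis dose vectors of a combination surface
#' @param surface A [CombinationSurface-class].
#' @return List of numeric ratio vectors.
#' @export
surfaceDoses <- function(surface) surface@doses

setMethod("show", "CombinationSurface", function(object) {
  cat(sprintf("CombinationSurface: targets {%s}, grid %s\n",
              paste0("k", object@targets, collapse = ","),
              paste(dim(object@values), collapse = "x")))
  cat(sprintf("  cGMP_T range [%.4g, %.4g] uM*s; reference %.4g\n",
              min(object@values), max(object@values), object@reference))
})

#' Long-format data frame of a combination surface
#'
#' @param surface A [CombinationSurface-class].
#' @return data.frame with one row per grid cell: \code{rho_1},
#'   \code{rho_2} (and \code{rho_3} for triples), \code{cgmp_T},
#'   \code{relative_cgmp_T}.
#' @export
asSurfaceFrame <- function(surface) {
  stopifnot(is(surface, "CombinationSurface"))
  g <- expand.grid(lapply(surface@doses, as.numeric), KEEP.OUT.ATTRS = FALSE)
  names(g) <- paste0("rho_", seq_along(surface@doses))
  g$cgmp_T <- as.vector(surface@values)
  g$relative_cgmp_T <- g$cgmp_T / surface@reference
  g
}
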