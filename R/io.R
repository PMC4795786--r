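## Parameter-file reading/writing and the pipeline driver.
##
## Parameter files are flat YAML: a `units` block declaring concentration
## and time units, a `rate_constants` block (k1..k13), and an
## `initial_concentrations` block (the 12 canonical species). Values are
## converted to the internal uM/s convention on load.

.CONC_FACTORS <- c(uM = 1, mM = 1e3, M = 1e6, nM = 1e-3)
.TIME_FACTORS <- c(s = 1, min = 60, h = 3600)

#' Read a parameter file
#'
#' Validates completeness (every rate constant and species present exactly
#' once), rejects unknown keys, and reports all offending keys collectively.
#' Units are converted to uM and seconds: a bimolecular constant declared in
#' 1/(mM*min) becomes 1/(uM*s), concentrations in mM become uM, and so on.
#'
#' @param path Path to a YAML parameter file.
#' @return List with elements \code{params} ([ParameterSet-class]) and
#'   \code{init} ([InitialState-class]).
#' @seealso [writeParameterFile()]
#' @export
readParameterFile <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  doc <- yaml::read_yaml(path)
  for (block in c("units", "rate_constants", "initial_concentrations"))
    if (is.null(doc[[block]]))
      stop("parameter file missing block: ", block)
  cu <- doc$units$concentration; tu <- doc$units$time
  if (is.null(cu) || !cu %in% names(.CONC_FACTORS))
    stop("units$concentration must be one of: ",
         paste(names(.CONC_FACTORS), collapse = ", "))
  if (is.null(tu) || !tu %in% names(.TIME_FACTORS))
    stop("units$time must be one of: ",
         paste(names(.TIME_FACTORS), collapse = ", "))
  cf <- .CONC_FACTORS[[cu]]; tf <- .TIME_FACTORS[[tu]]

  k <- doc$rate_constants
  s <- doc$initial_concentrations
  problems <- character()
  missK <- setdiff(.RATE_NAMES, names(k))
  unkK <- setdiff(names(k), .RATE_NAMES)
  missS <- setdiff(speciesNames(), names(s))
  unkS <- setdiff(names(s), speciesNames())
  if (length(missK)) problems <- c(problems,
    paste("missing rate constants:", paste(missK, collapse = ", ")))
  if (length(unkK)) problems <- c(problems,
    paste("unknown rate constants:", paste(unkK, collapse = ", ")))
  if (length(missS)) problems <- c(problems,
    paste("missing species:", paste(missS, collapse = ", ")))
  if (length(unkS)) problems <- c(problems,
    paste("unknown species:", paste(unkS, collapse = ", ")))
  if (length(problems)) stop("invalid parameter file:\n  ",
                             paste(problems, collapse = "\n  "))
  kv <- suppressWarnings(vapply(k[.RATE_NAMES], function(x)
    as.numeric(x)[1L], 1.0))
  sv <- suppressWarnings(vapply(s[speciesNames()], function(x)
    as.numeric(x)[1L], 1.0))
  bad <- c(names(kv)[!is.finite(kv)], names(sv)[!is.finite(sv)])
  if (length(bad)) stop("non-numeric values for: ", paste(bad, collapse = ", "))
  neg <- c(names(kv)[kv < 0], names(sv)[sv < 0])
  if (length(neg)) stop("negative values for: ", paste(neg, collapse = ", "))

  ## unit conversion to uM, s: unimolecular k ~ 1/time; bimolecular
  ## k ~ 1/(conc*time); concentrations ~ conc
  kv <- kv / tf
  kv[.BIMOLECULAR] <- kv[.BIMOLECULAR] / cf
  sv <- sv * cf
  list(params = ParameterSet(kv), init = InitialState(sv))
}

#' Write a parameter file
#'
#' @param params A [ParameterSet-class].
#' @param init An [InitialState-class].
#' @param path Output path.
#' @param concUnit,timeUnit Units to declare (values are converted from the
#'   internal uM/s representation).
#' @return \code{path}, invisibly.
#' @export
writeParameterFile <- function(params, init, path,
                               concUnit = "uM", timeUnit = "s") {
  stopifnot(is(params, "ParameterSet"), is(init, "InitialState"))
  cf <- .CONC_FACTORS[[concUnit]]; tf <- .TIME_FACTORS[[timeUnit]]
  if (is.null(cf) || is.null(tf)) stop("unsupported units")
  k <- params@k * tf
  k[.BIMOLECULAR] <- k[.BIMOLECULAR] * cf
  s <- init@conc / cf
  doc <- list(units = list(concentration = concUnit, time = timeUnit),
              rate_constants = as.list(k),
              initial_concentrations = as.list(s))
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' Write a trajectory as tidy TSV
#'
#' @param result A [SimulationResult-class].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeTrajectory <- function(result, path) {
  utils::write.table(asTrajectoryFrame(result), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a pipeline run configuration
#'
#' @param paramsFile Optional parameter file; when NULL the frozen defaults
#'   are used.
#' @param outDir Output directory (created if needed).
#' @param h2o2 Oxidant dose (uM, default 500).
#' @param tEnd,nPoints Simulation window (defaults 200 s / 201 points).
#' @param maxOrder,rho Screen settings (defaults 3, 0.1).
#' @param pairTargets Pairs analyzed in the Bliss and isobole stages
#'   (list of integer pairs; default the k1/k3/k10 combinations).
#' @param surfacePoints Dose-grid points per axis (default 11).
#' @param blissRho Ratio used for the Bliss comparison (default 0.3).
#' @param isoboleLevels,isoboleThreshold Isobole classification settings.
#' @param seed Seed echoed into outputs (the pipeline itself is
#'   deterministic).
#' @return A \code{list} of class \code{"cgmpRunConfig"}.
#' @export
runConfig <- function(paramsFile = NULL, outDir = "cgmp-run",
                      h2o2 = 500, tEnd = 200, nPoints = 201L,
                      maxOrder = 3L, rho = 0.1,
                      pairTargets = list(c(1L, 3L), c(1L, 10L), c(3L, 10L)),
                      surfacePoints = 11L, blissRho = 0.3,
                      isoboleLevels = c(0.25, 0.5, 0.75),
                      isoboleThreshold = 0.05, seed = 1L) {
  cfg <- list(paramsFile = paramsFile, outDir = outDir, h2o2 = h2o2,
              tEnd = tEnd, nPoints = as.integer(nPoints),
              maxOrder = as.integer(maxOrder), rho = rho,
              pairTargets = lapply(pairTargets, as.integer),
              surfacePoints = as.integer(surfacePoints), blissRho = blissRho,
              isoboleLevels = isoboleLevels,
              isoboleThreshold = isoboleThreshold, seed = as.integer(seed))
  class(cfg) <- "cgmpRunConfig"
  cfg
}

.writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> screen -> dose-response -> Bliss -> isobole stages,
#' writing tidy TSVs, an echoed configuration, and a machine-readable JSON
#' summary into the output directory. Identical configurations reproduce
#' byte-identical outputs.
#'
#' Files written: \code{config.json}, \code{trajectory_control.tsv},
#' \code{trajectory_h2o2.tsv}, \code{screen.tsv}, \code{dose_response.tsv},
#' \code{bliss.tsv}, \code{isoboles.tsv}, \code{summary.json}.
#'
#' @param config A configuration from [runConfig()].
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with the in-memory stage results (elements
#'   \code{control}, \code{h2o2}, \code{screen}, \code{doseResponse},
#'   \code{bliss}, \code{isoboles}, \code{summary}).
#' @export
runPipeline <- function(config = runConfig(), quiet = FALSE) {
  stopifnot(inherits(config, "cgmpRunConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  if (is.null(config$paramsFile)) {
    params <- defaultParameters(); init0 <- defaultInitialState()
  } else {
    pf <- readParameterFile(config$paramsFile)
    params <- pf$params; init0 <- pf$init
  }
  jsonlite::write_json(config[setdiff(names(config), "pairTargets")],
                       file.path(config$outDir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  say("stage 1/5: simulating control and oxidant conditions")
  ctrlInit <- applyOxidativeStress(init0, 0)
  oxInit <- applyOxidativeStress(init0, config$h2o2)
  ctrl <- simulatePathway(params, ctrlInit, config$tEnd, config$nPoints)
  ox <- simulatePathway(params, oxInit, config$tEnd, config$nPoints)
  .writeTSV(asTrajectoryFrame(ctrl),
            file.path(config$outDir, "trajectory_control.tsv"))
  .writeTSV(asTrajectoryFrame(ox),
            file.path(config$outDir, "trajectory_h2o2.tsv"))

  say("stage 2/5: perturbation screen (maxOrder = ", config$maxOrder, ")")
  screen <- screenPerturbations(params, oxInit, maxOrder = config$maxOrder,
                                rho = config$rho, horizon = config$tEnd,
                                tEnd = config$tEnd, nPoints = config$nPoints,
                                controlInit = ctrlInit)
  .writeTSV(screen, file.path(config$outDir, "screen.tsv"))

  say("stage 3/5: single-target dose responses")
  drTargets <- sort(unique(unlist(config$pairTargets)))
  dr <- do.call(rbind, lapply(drTargets, function(tg)
    doseResponse(params, oxInit, tg,
                 makeDoseVector(tg, 0.1, config$surfacePoints),
                 horizon = config$tEnd, tEnd = config$tEnd,
                 nPoints = config$nPoints)))
  .writeTSV(dr, file.path(config$outDir, "dose_response.tsv"))

  say("stage 4/5: Bliss comparison of paired perturbations")
  bl <- do.call(rbind, lapply(config$pairTargets, function(pr) {
    b <- blissComparison(params, oxInit, ctrlInit, pr, rho = config$blissRho,
                         horizon = config$tEnd, tEnd = config$tEnd,
                         nPoints = config$nPoints)
    data.frame(pair = paste(b$pair, collapse = ","), rho = b$rho,
               effect_i = b$effects[1L], effect_j = b$effects[2L],
               predicted = b$predicted, observed = b$observed,
               excess = b$excess)
  }))
  .writeTSV(bl, file.path(config$outDir, "bliss.tsv"))

  say("stage 5/5: combination surfaces and isobole classification")
  iso <- do.call(rbind, lapply(config$pairTargets, function(pr) {
    surf <- buildSurface(params, oxInit, pr, nPoints = config$surfacePoints,
                         horizon = config$tEnd, tEnd = config$tEnd,
                         nGrid = config$nPoints)
    .writeTSV(asSurfaceFrame(surf),
              file.path(config$outDir,
                        paste0("surface_", paste(pr, collapse = "_"), ".tsv")))
    cls <- classifyIsoboles(surf, config$isoboleLevels,
                            config$isoboleThreshold)
    cbind(pair = paste(pr, collapse = ","), cls)
  }))
  .writeTSV(iso, file.path(config$outDir, "isoboles.tsv"))

  okScreen <- screen[screen$status == "ok", ]
  summary <- list(
    package_version = as.character(utils::packageVersion("cgmpScreen")),
    n_perturbations = nrow(screen),
    n_failed = sum(screen$status != "ok"),
    top_perturbations = utils::head(okScreen$targets, 5L),
    peak_cgmp_control = max(trajectory(ctrl, "cGMP")),
    peak_cgmp_h2o2 = max(trajectory(ox, "cGMP")),
    peak_fold_reduction = max(trajectory(ctrl, "cGMP")) /
      max(trajectory(ox, "cGMP")),
    bliss_excess = stats::setNames(bl$excess, bl$pair),
    isobole_classes = stats::setNames(iso$classification,
                                      paste(iso$pair, iso$level, sep = "@")),
    seed = config$seed)
  jsonlite::write_json(summary, file.path(config$outDir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(control = ctrl, h2o2 = ox, screen = screen,
                 doseResponse = dr, bliss = bl, isoboles = iso,
                 summary = summary))
}
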