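#' Plot cGMP time courses
#'
#' Base-graphics cGMP trajectories for one or more simulations on a common
#' axis.
#'
#' @param ... One or more [SimulationResult-class] objects (named arguments
#'   become legend labels).
#' @param species Species to plot (default "cGMP").
#' @param col Line colors, recycled.
#' @return Invisibly, NULL.
#' @export
plotTimecourse <- function(..., species = "cGMP",
                           col = c("black", "firebrick", "steelblue",
                                   "darkgreen")) {
  results <- list(...)
  stopifnot(length(results) >= 1L,
            all(vapply(results, is, TRUE, "SimulationResult")))
  labs <- names(results)
  if (is.null(labs)) labs <- paste("run", seq_along(results))
  ymax <- max(vapply(results, function(r) max(trajectory(r, species)), 1.0))
  col <- rep_len(col, length(results))
  graphics::plot(NA, xlim = range(results[[1L]]@time), ylim = c(0, ymax),
                 xlab = "time (s)", ylab = paste0("[", species, "] (uM)"))
  for (i in seq_along(results))
    graphics::lines(results[[i]]@time, trajectory(results[[i]], species),
                    col = col[i], lwd = 2)
  graphics::legend("topright", legend = labs, col = col, lwd = 2, bty = "n")
  invisible(NULL)
}

#' Contour plot of a pairwise combination surface
#'
#' Iso-cGMP_T contours in the dose plane (d = 1 - rho), the isobologram view
#' used for additivity assessment.
#'
#' @param surface A 2-axis [CombinationSurface-class].
#' @param relative Plot relative (normalized) cGMP_T (default TRUE).
#' @param nlevels Number of contour levels.
#' @return Invisibly, NULL.
#' @export
plotIsoboles <- function(surface, relative = TRUE, nlevels = 10L) {
  stopifnot(is(surface, "CombinationSurface"),
            length(surface@targets) == 2L)
  d1 <- 1 - surface@doses[[1L]]
  d2 <- 1 - surface@doses[[2L]]
  z <- surfaceValues(surface, relative = relative)
  graphics::contour(d1, d2, z, nlevels = nlevels,
                    xlab = sprintf("dose on k%d (1 - rho)",
                                   surface@targets[1L]),
                    ylab = sprintf("dose on k%d (1 - rho)",
                                   surface@targets[2L]))
  invisible(NULL)
}
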