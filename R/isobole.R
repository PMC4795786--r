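## Isobole extraction and curvature classification.
##
## An isobole is a contour of constant effect in the dose plane. Doses are
## fractional inhibitions d = 1 - rho, so the origin is "no inhibition".
## Under dose additivity (Loewe) the isobole joining its axis intercepts is a
## straight line; bowing toward the origin indicates synergy, away from it
## antagonism. Classification is by a normalized signed-area curvature index:
## the area enclosed between the contour polyline and the straight chord
## joining its endpoints, divided by the area of the triangle formed by the
## chord and the origin; positive index = bowed toward the origin.

## signed area of polygon (shoelace); vertices as two-column matrix
.polyArea <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  n <- nrow(xy)
  0.5 * sum(x * y[c(2:n, 1L)] - x[c(2:n, 1L)] * y)
}

## curvature index of one contour polyline in the (d1, d2) plane
.curvatureIndex <- function(d1, d2) {
  n <- length(d1)
  if (n < 2L) return(NA_real_)
  a <- c(d1[1L], d2[1L]); b <- c(d1[n], d2[n])
  chord <- sqrt(sum((b - a)^2))
  if (chord == 0) return(NA_real_)
  ## area between the polyline and the chord (close polygon with the chord)
  area <- .polyArea(cbind(d1, d2))
  ## triangle formed by the chord and the origin
  tri <- abs(.polyArea(rbind(a, b, c(0, 0))))
  if (tri == 0) return(NA_real_)
  ## orient: positive when the polyline bows toward the origin relative to
  ## the chord. The origin's side of the chord is given by the cross product
  ## of (b - a) with (origin - a); a polyline bulging to that same side
  ## traverses the closed polygon with opposite orientation, hence the flip.
  sgn <- sign((b[1L] - a[1L]) * (0 - a[2L]) - (b[2L] - a[2L]) * (0 - a[1L]))
  -sgn * area / tri
}

## classify one 2-D effect matrix (rows = axis1, cols = axis2).
## Requested levels are fractions of the largest effect attainable by BOTH
## single agents (the smaller of the two axis maxima), so each iso-effect
## contour is guaranteed to have axis intercepts when the axis responses are
## monotone -- the classical isobologram requirement.
.classifySlice <- function(eff, d1, d2, levels, threshold) {
  axisCap <- min(max(eff[, 1L]), max(eff[1L, ]))
  out <- lapply(levels, function(lv) {
    lvAbs <- lv * axisCap
    if (axisCap <= 0)
      return(data.frame(level = lv, index = NA_real_,
                        classification = "not-reached"))
    cl <- grDevices::contourLines(d1, d2, eff, levels = lvAbs)
    if (!length(cl))
      return(data.frame(level = lv, index = NA_real_,
                        classification = "not-reached"))
    ## take the longest contour piece
    len <- vapply(cl, function(p) length(p$x), 1L)
    p <- cl[[which.max(len)]]
    ## require the contour to reach both axis-adjacent edges: its endpoints
    ## must lie near d1 = 0 / d2 = 0 edges or the outer edges; we demand axis
    ## intercepts (one endpoint with d2 ~ min, the other with d1 ~ min)
    tol1 <- (max(d1) - min(d1)) * 1e-6
    tol2 <- (max(d2) - min(d2)) * 1e-6
    e1 <- c(p$x[1L], p$y[1L]); e2 <- c(p$x[length(p$x)], p$y[length(p$y)])
    onAxis <- function(e) e[2L] <= min(d2) + tol2 || e[1L] <= min(d1) + tol1
    if (!(onAxis(e1) && onAxis(e2)))
      return(data.frame(level = lv, index = NA_real_,
                        classification = "no-axis-intercepts"))
    idx <- .curvatureIndex(p$x, p$y)
    cls <- if (!is.finite(idx)) "degenerate"
    else if (abs(idx) <= threshold) "additive"
    else if (idx > threshold) "synergistic"
    else "antagonistic"
    data.frame(level = lv, index = idx, classification = cls)
  })
  do.call(rbind, out)
}

#' Classify iso-effect contours of a combination surface
#'
#' Converts the surface to an effect scale (0 at the unperturbed reference
#' corner), extracts iso-effect contours in the dose plane d = 1 - rho at
#' the requested fractions of the largest effect attainable by each single
#' agent alone (the smaller of the two axis maxima, so every contour has
#' axis intercepts), and classifies each contour by its curvature index:
#' \code{additive} when |index| <= \code{threshold} (default 0.05),
#' \code{synergistic} when the isobole bows toward the origin beyond the
#' threshold, \code{antagonistic} when it bows away. Levels whose contour
#' does not intercept both dose axes are reported but flagged, with a
#' warning.
#'
#' Three-axis surfaces are classified slice-wise: the three axis-aligned 2-D
#' faces through rho = 1 of the third axis, plus the main diagonal plane
#' (equal doses on the first two axes against the third).
#'
#' @param surface A [CombinationSurface-class], or (for testing synthetic
#'   response models) a list with elements \code{doses} (list of ratio
#'   vectors) and \code{values} (array) and \code{reference}.
#' @param levels Effect levels as fractions of the maximum achieved effect
#'   (default 0.25, 0.5, 0.75).
#' @param threshold Curvature-index threshold for the additive band
#'   (default 0.05).
#' @return data.frame with columns \code{slice}, \code{level}, \code{index},
#'   \code{classification}.
#' @examples
#' surf <- syntheticSurface("additive")
#' classifyIsoboles(surf)
#' @export
classifyIsoboles <- function(surface, levels = c(0.25, 0.5, 0.75),
                             threshold = 0.05) {
  if (is(surface, "CombinationSurface")) {
    doses <- surface@doses; vals <- surface@values; ref <- surface@reference
  } else {
    doses <- surface$doses; vals <- surface$values; ref <- surface$reference
  }
  if (any(levels <= 0) || any(levels >= 1))
    stop("levels must be fractions in (0, 1)")
  ## normalized effect: 0 at the all-rho-1 corner, 1 at the maximum
  corner <- do.call(`[`, c(list(vals), as.list(rep(1L, length(dim(vals))))))
  span <- max(vals) - corner
  if (span <= 0) stop("surface shows no effect above the reference corner")
  eff <- (vals - corner) / span
  nax <- length(doses)
  ## dose coordinates, ascending for contourLines
  ds <- lapply(doses, function(r) 1 - r)  # descending rho -> ascending d
  slices <- list()
  if (nax == 2L) {
    slices[["d1-d2"]] <- list(eff = eff, d1 = ds[[1L]], d2 = ds[[2L]])
  } else {
    slices[["face-12"]] <- list(eff = eff[, , 1L], d1 = ds[[1L]], d2 = ds[[2L]])
    slices[["face-13"]] <- list(eff = eff[, 1L, ], d1 = ds[[1L]], d2 = ds[[3L]])
    slices[["face-23"]] <- list(eff = eff[1L, , ], d1 = ds[[2L]], d2 = ds[[3L]])
    ## main diagonal plane: equal dose on axes 1 and 2 vs axis 3
    n <- dim(eff)[1L]
    diagEff <- sapply(seq_len(dim(eff)[3L]), function(j)
      vapply(seq_len(n), function(i) eff[i, i, j], 1.0))
    slices[["diagonal-12_3"]] <- list(eff = diagEff, d1 = ds[[1L]],
                                      d2 = ds[[3L]])
  }
  out <- do.call(rbind, lapply(names(slices), function(nm) {
    s <- slices[[nm]]
    if (max(s$eff) <= 0)
      return(data.frame(slice = nm, level = levels, index = NA_real_,
                        classification = "not-reached"))
    r <- .classifySlice(s$eff, s$d1, s$d2, levels, threshold)
    cbind(slice = nm, r)
  }))
  skipped <- out$classification %in% c("not-reached", "no-axis-intercepts")
  if (any(skipped))
    warning(sum(skipped), " contour level(s) skipped: ",
            paste(unique(out$classification[skipped]), collapse = ", "))
  rownames(out) <- NULL
  out
}
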