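#' @rdname WaveField-class
#' @param object,x a package object.
#' @export
setGeneric("zeta", function(object) standardGeneric("zeta"))
#' @rdname WaveField-class
#' @export
setGeneric("fieldPitch", function(object) standardGeneric("fieldPitch"))
#' @rdname NodalSet-class
#' @export
setGeneric("nodalRadii", function(object) standardGeneric("nodalRadii"))
#' @rdname NodalSet-class
#' @export
setGeneric("nodalCurves", function(object) standardGeneric("nodalCurves"))
#' @rdname SyntheticImage-class
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))
#' @rdname SyntheticImage-class
#' @export
setGeneric("imageTruth", function(object) standardGeneric("imageTruth"))
#' @rdname SyntheticImage-class
#' @export
setGeneric("pixelPitch", function(object) standardGeneric("pixelPitch"))
#' @rdname ThicknessMap-class
#' @export
setGeneric("thicknessValues", function(object) standardGeneric("thicknessValues"))

#' Sample a profile along a line in physical coordinates
#'
#' Bilinear interpolation of a wave field or image at `samples` equispaced
#' points between two physical endpoints; the returned arc-length coordinate
#' starts at 0 at `from`. Endpoints must lie inside the grid.
#'
#' @param x a [WaveField] (mm coordinates; centre origin for round fields,
#'   corner origin for square fields) or [SyntheticImage] (um, corner origin).
#' @param from,to numeric length-2 endpoints, physical units of `x`.
#' @param samples number of equispaced sample points.
#' @param ... unused.
#' @return data.frame with columns `s` (arc length) and `value`.
#' @export
setGeneric("symmetryLineProfile",
           function(x, from, to, samples = 512L, ...)
             standardGeneric("symmetryLineProfile"))

#' @rdname WaveField-class
#' @export
setMethod("zeta", "WaveField", function(object) object@zeta)
#' @rdname WaveField-class
#' @export
setMethod("fieldPitch", "WaveField", function(object) object@pitch)
#' @rdname NodalSet-class
#' @export
setMethod("nodalRadii", "NodalSet", function(object) object@radii)
#' @rdname NodalSet-class
#' @export
setMethod("nodalCurves", "NodalSet", function(object) object@curves)
#' @rdname SyntheticImage-class
#' @export
setMethod("intensity", "SyntheticImage", function(object) object@intensity)
#' @rdname SyntheticImage-class
#' @export
setMethod("imageTruth", "SyntheticImage", function(object) object@truth)
#' @rdname SyntheticImage-class
#' @export
setMethod("pixelPitch", "SyntheticImage", function(object) object@pixelPitch)
#' @rdname ThicknessMap-class
#' @export
setMethod("thicknessValues", "ThicknessMap", function(object) object@values)

setMethod("show", "ModeSpec", function(object) {
  cat(sprintf("ModeSpec: %s chamber, m=%d n=%d, dim=%g mm, grid %d^2\n",
              object@shape, object@m, object@n, object@chamberDim,
              object@gridResolution))
})

setMethod("show", "WaveField", function(object) {
  z <- object@zeta
  cat(sprintf("WaveField (%s, m=%d n=%d): %dx%d grid, pitch %.4g mm, %s frame\n",
              object@spec@shape, object@spec@m, object@spec@n,
              nrow(z), ncol(z), object@pitch, object@frame))
  cat(sprintf("  zeta range [%.3f, %.3f]\n",
              min(z, na.rm = TRUE), max(z, na.rm = TRUE)))
})

setMethod("show", "NodalSet", function(object) {
  cat(sprintf("NodalSet: %d curve(s), tol %.3g\n",
              length(object@curves), object@tol))
  if (length(object@radii))
    cat("  nodal circle radii (mm):",
        paste(sprintf("%.3f", object@radii), collapse = ", "), "\n")
})

setMethod("show", "SyntheticImage", function(object) {
  d <- dim(object@intensity)
  cat(sprintf("SyntheticImage: %dx%d px, %.3g um/px (%.2f mm field)\n",
              d[1], d[2], object@pixelPitch, d[1] * object@pixelPitch / 1000))
  tr <- object@truth
  if (!is.null(tr$realizedOnFraction))
    cat(sprintf("  realized GFP+ fraction on/off pattern: %.4f / %.4f\n",
                tr$realizedOnFraction, tr$realizedOffFraction))
  else if (!is.null(tr$realizedFraction))
    cat(sprintf("  realized GFP+ fraction: %.4f\n", tr$realizedFraction))
})

setMethod("show", "RadialProfile", function(object) {
  cat(sprintf("RadialProfile: %d annuli, dr = %.3g um, centre (%.1f, %.1f) um\n",
              length(object@radii), object@dr, object@center[1],
              object@center[2]))
})

setMethod("show", "PeakSet", function(object) {
  cat(sprintf("PeakSet: %d peak(s), %d valley(s)\n",
              nrow(object@peaks), nrow(object@valleys)))
  if (nrow(object@peaks))
    cat("  peak positions (um):",
        paste(sprintf("%.1f", object@peaks$position), collapse = ", "), "\n")
})

setMethod("show", "ThicknessMap", function(object) {
  fg <- object@values[object@values > 0]
  cat(sprintf("ThicknessMap: %dx%d px, %.3g um/px, %d foreground px\n",
              nrow(object@values), ncol(object@values), object@pixelPitch,
              length(fg)))
  if (length(fg))
    cat(sprintf("  thickness mean %.2f um, max %.2f um\n", mean(fg), max(fg)))
})

setMethod("show", "OrientationHist", function(object) {
  cat(sprintf("OrientationHist: %d bins over [-90, 90) deg\n",
              length(object@angles)))
  if (sum(object@weights) > 0)
    cat(sprintf("  modal angle %.1f deg\n",
                object@angles[which.max(object@weights)]))
  else cat("  empty histogram (no pixel above the energy threshold)\n")
})

setMethod("show", "PCAScores", function(object) {
  cat(sprintf("PCAScores: %d samples x %d components\n",
              nrow(object@scores), ncol(object@scores)))
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * object@explained), collapse = ", "), "\n")
})
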