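# Accessor generics and show methods.

#' Physical pixel size in micrometres
#' @param object an object carrying a pixel size.
#' @return numeric scalar, micrometres per pixel.
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "SyntheticImage", function(object) object@pixelSize)
#' @rdname pixelSize
#' @export
setMethod("pixelSize", "ImageStack", function(object) object@pixelSize)
#' @rdname pixelSize
#' @export
setMethod("pixelSize", "ImagingSpec", function(object) object@pixelSize)

#' Ground truth of a synthetic image
#' @param object a \code{SyntheticImage}.
#' @return list of \code{MyofibrilSpec}.
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname groundTruth
#' @export
setMethod("groundTruth", "SyntheticImage", function(object) object@groundTruth)

#' Channel access
#'
#' \code{phalloidinChannel} and \code{zdiscChannel} return the F-actin and
#' Z-disc marker channels of an image container.
#'
#' @param object a \code{SyntheticImage} or \code{ImageStack}.
#' @return numeric matrix (or array for a 3D stack).
#' @export
setGeneric("phalloidinChannel", function(object) standardGeneric("phalloidinChannel"))
#' @rdname phalloidinChannel
#' @export
setGeneric("zdiscChannel", function(object) standardGeneric("zdiscChannel"))
#' @rdname phalloidinChannel
#' @export
setMethod("phalloidinChannel", "SyntheticImage", function(object) object@phalloidin)
#' @rdname phalloidinChannel
#' @export
setMethod("zdiscChannel", "SyntheticImage", function(object) object@zdisc)
#' @rdname phalloidinChannel
#' @export
setMethod("phalloidinChannel", "ImageStack", function(object) {
  x <- object@phalloidin
  if (length(dim(x)) == 3L && dim(x)[3L] == 1L) x <- x[, , 1L]
  x
})
#' @rdname phalloidinChannel
#' @export
setMethod("zdiscChannel", "ImageStack", function(object) {
  x <- object@zdisc
  if (length(dim(x)) == 3L && dim(x)[3L] == 1L) x <- x[, , 1L]
  x
})

#' Cumulative arclength of a centerline
#' @param object a \code{Centerline}.
#' @return numeric vector, micrometres.
#' @export
setGeneric("arclength", function(object) standardGeneric("arclength"))
#' @rdname arclength
#' @export
setMethod("arclength", "Centerline", function(object) object@arclength)

#' Profile coordinates and values
#' @param object an \code{IntensityProfile}.
#' @return numeric vector.
#' @export
setGeneric("positions", function(object) standardGeneric("positions"))
#' @rdname positions
#' @export
setMethod("positions", "IntensityProfile", function(object) object@positions)
#' @rdname positions
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @rdname positions
#' @export
setMethod("intensities", "IntensityProfile", function(object) object@values)

#' Fitted peak centers
#' @param object a \code{GaussianPeakSet}.
#' @return numeric vector of centers in micrometres.
#' @export
setGeneric("peakCenters", function(object) standardGeneric("peakCenters"))
#' @rdname peakCenters
#' @export
setMethod("peakCenters", "GaussianPeakSet", function(object) object@centers)

#' Fitted myofibril diameter
#' @param object a \code{DiscFit}.
#' @return numeric, diameter 2R in micrometres.
#' @export
setGeneric("fitDiameter", function(object) standardGeneric("fitDiameter"))
#' @rdname fitDiameter
#' @export
setMethod("fitDiameter", "DiscFit", function(object) 2 * object@radius)

#' Convergence flag of a model fit
#' @param object a fit object.
#' @return logical.
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))
#' @rdname converged
#' @export
setMethod("converged", "GaussianPeakSet", function(object) object@converged)
#' @rdname converged
#' @export
setMethod("converged", "DiscFit", function(object) object@converged)

#' Quality-control flags of a segmented region
#' @param object a \code{MyofibrilMask}.
#' @return named logical vector.
#' @export
setGeneric("qcFlags", function(object) standardGeneric("qcFlags"))
#' @rdname qcFlags
#' @export
setMethod("qcFlags", "MyofibrilMask", function(object) object@qcFlags)

#' Filament positions of a lattice model
#' @param object a \code{LatticeModel}.
#' @return two-column matrix of positions in nanometres.
#' @export
setGeneric("thickPositions", function(object) standardGeneric("thickPositions"))
#' @rdname thickPositions
#' @export
setGeneric("thinPositions", function(object) standardGeneric("thinPositions"))
#' @rdname thickPositions
#' @export
setMethod("thickPositions", "LatticeModel", function(object) object@thick)
#' @rdname thickPositions
#' @export
setMethod("thinPositions", "LatticeModel", function(object) object@thin)

#' Filament spans of a 3D sarcomere model
#' @param object a \code{Sarcomere3DModel}.
#' @return data.frame with columns type, x, y, zStart, zEnd.
#' @export
setGeneric("filamentSpans", function(object) standardGeneric("filamentSpans"))
#' @rdname filamentSpans
#' @export
setMethod("filamentSpans", "Sarcomere3DModel", function(object) object@filaments)

setMethod("show", "MyofibrilSpec", function(object) {
  cat(sprintf(
    "MyofibrilSpec: %d sarcomeres x %.3g um, D = %.3g um, Z %.3g / H %.3g um, %s%.0f deg\n",
    object@nSarcomeres, object@sarcomereLength, object@diameter,
    object@zdiscWidth, object@hzoneWidth,
    if (object@curvature != 0) sprintf("kappa %.3g/um, ", object@curvature) else "",
    object@orientation))
})

setMethod("show", "SyntheticImage", function(object) {
  d <- dim(object@phalloidin)
  cat(sprintf("SyntheticImage: %d x %d px (%.3g um/px), %d myofibril spec(s)\n",
              d[1], d[2], object@pixelSize, length(object@groundTruth)))
})

setMethod("show", "Centerline", function(object) {
  cat(sprintf("Centerline: %d samples, arclength %.3g um\n",
              nrow(object@points), max(object@arclength)))
})

setMethod("show", "IntensityProfile", function(object) {
  cat(sprintf("IntensityProfile (%s, %s): %d samples over [%.3g, %.3g] um\n",
              object@axisTag, object@channelTag, length(object@positions),
              min(object@positions), max(object@positions)))
})

setMethod("show", "GaussianPeakSet", function(object) {
  cat(sprintf("GaussianPeakSet: %d peaks, residual RMS %.3g, %s\n",
              length(object@centers), object@residualRMS,
              if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "DiscFit", function(object) {
  cat(sprintf(
    "DiscFit: diameter %.4g um (R %.4g, psf sigma %.3g), residual RMS %.3g, %s\n",
    2 * object@radius, object@radius, object@psfSigma, object@residualRMS,
    if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "SarcomereLengthSet", function(object) {
  cat(sprintf("SarcomereLengthSet: %d lengths, mean %.4g um, sd %.3g um\n",
              length(object@distances), object@mean, object@sd))
})

setMethod("show", "StageMorphometrics", function(object) {
  cat(sprintf("StageMorphometrics '%s':\n", object@stage))
  cat(sprintf("  L_sarcomere %.3g um | W_I %.3g | W_H %.3g | W_Z %.3g um\n",
              object@lSarcomere, object@wIBand, object@wHZone, object@wZDisc))
  cat(sprintf("  L_thick %.4g um | L_thin %.4g um | %d thick filaments | d = %.3g nm\n",
              object@lThick, object@lThin, object@nThick, object@spacing))
})

setMethod("show", "LatticeModel", function(object) {
  cat(sprintf("LatticeModel: %d thick (%d interior), %d thin, d = %.3g nm\n",
              nrow(object@thick), sum(object@interior), nrow(object@thin),
              object@spacing))
})

setMethod("show", "Sarcomere3DModel", function(object) {
  tb <- table(object@filaments$type)
  cat(sprintf("Sarcomere3DModel: %d thick + %d thin filaments, L = %.3g um\n",
              tb[["thick"]], tb[["thin"]], object@lSarcomere))
})

setMethod("show", "MeasurementTable", function(object) {
  cat(sprintf("MeasurementTable: n = %s\n", object@nLabel))
  for (v in names(object@grandMean))
    cat(sprintf("  %s: %.4g +/- %.3g (mean of experiment means +/- sd)\n",
                v, object@grandMean[[v]], object@grandSD[[v]]))
})
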