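#' @import methods
NULL

.condition <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "fibrilMorphError")))
}

#' Ground-truth geometry of one simulated myofibril
#'
#' A \code{MyofibrilSpec} describes a single myofibril as a uniformly
#' labelled cylinder laid out in the image plane: \code{nSarcomeres}
#' sarcomeres of length \code{sarcomereLength}, bounded by
#' \code{nSarcomeres + 1} Z-discs.  The phalloidin (F-actin) channel renders
#' the cylinder with axial intensity 1 in thin-filament regions, 2 inside
#' the Z-disc overlap band (thin filaments of adjacent sarcomeres overlap
#' there) and 0 inside the central H-zone gap; the Z-disc channel renders
#' only the Z-disc bands.
#'
#' @slot nSarcomeres integer, number of sarcomeres (>= 0).
#' @slot sarcomereLength numeric, sarcomere length in micrometres.
#' @slot diameter numeric, cylinder diameter in micrometres.
#' @slot zdiscWidth numeric, Z-disc overlap band width in micrometres.
#' @slot hzoneWidth numeric, H-zone gap width in micrometres.
#' @slot orientation numeric, in-plane orientation in degrees.
#' @slot curvature numeric, constant curvature in 1/micrometre (0 = straight;
#'   the axis is a circular arc).
#' @slot origin numeric length 2, (x, y) position of the first Z-line in
#'   micrometres, image frame.
#'
#' @export
setClass("MyofibrilSpec",
  representation(
    nSarcomeres = "integer",
    sarcomereLength = "numeric",
    diameter = "numeric",
    zdiscWidth = "numeric",
    hzoneWidth = "numeric",
    orientation = "numeric",
    curvature = "numeric",
    origin = "numeric"
  ),
  validity = function(object) {
    msg <- character(0)
    if (object@nSarcomeres < 0L) msg <- c(msg, "nSarcomeres must be >= 0")
    if (object@sarcomereLength <= 0) msg <- c(msg, "sarcomereLength must be > 0")
    if (object@diameter <= 0) msg <- c(msg, "diameter must be > 0")
    if (object@zdiscWidth < 0 || object@zdiscWidth >= object@sarcomereLength)
      msg <- c(msg, "zdiscWidth must lie in [0, sarcomereLength)")
    if (object@hzoneWidth < 0 || object@hzoneWidth >= object@sarcomereLength)
      msg <- c(msg, "hzoneWidth must lie in [0, sarcomereLength)")
    if (object@zdiscWidth + object@hzoneWidth >= object@sarcomereLength)
      msg <- c(msg, "zdiscWidth + hzoneWidth must be < sarcomereLength")
    if (length(object@origin) != 2L) msg <- c(msg, "origin must have length 2")
    if (length(msg)) msg else TRUE
  }
)

#' @param nSarcomeres,sarcomereLength,diameter,zdiscWidth,hzoneWidth,orientation,curvature,origin
#'   see slots.
#' @return \code{MyofibrilSpec()} returns a validated \code{MyofibrilSpec}.
#' @rdname MyofibrilSpec-class
#' @examples
#' MyofibrilSpec(nSarcomeres = 6, sarcomereLength = 3.2, diameter = 1.5)
#' @export
MyofibrilSpec <- function(nSarcomeres, sarcomereLength = 3.2, diameter = 1.5,
                          zdiscWidth = 0.25, hzoneWidth = 0.3,
                          orientation = 0, curvature = 0,
                          origin = c(0, 0)) {
  obj <- try(new("MyofibrilSpec",
    nSarcomeres = as.integer(nSarcomeres),
    sarcomereLength = as.numeric(sarcomereLength),
    diameter = as.numeric(diameter),
    zdiscWidth = as.numeric(zdiscWidth),
    hzoneWidth = as.numeric(hzoneWidth),
    orientation = as.numeric(orientation),
    curvature = as.numeric(curvature),
    origin = as.numeric(origin)
  ), silent = TRUE)
  if (inherits(obj, "try-error"))
    .condition(attr(obj, "condition")$message, "InvalidSpec")
  obj
}

#' Optical and noise parameters of the simulated microscope
#'
#' Image formation follows the order: render ground truth (normalised to a
#' per-channel peak of 100 grey levels), add zero-mean Gaussian
#' uneven-labelling noise (\code{labelNoiseSigma}, clipped at zero),
#' convolve with the in-plane Airy pattern of a diffraction-limited
#' objective, scale by \code{photonScale} and draw Poisson photon counts.
#'
#' @slot pixelSize numeric, micrometres per pixel.
#' @slot numericalAperture numeric, objective NA.
#' @slot emissionWavelength numeric, emission wavelength in nanometres.
#' @slot labelNoiseSigma numeric, sd of the uneven-labelling noise in grey
#'   levels of the peak-100 ground truth.
#' @slot photonScale numeric, expected photons per grey level.
#' @slot rngSeed integer, seed making a simulated image reproducible.
#' @export
setClass("ImagingSpec",
  representation(
    pixelSize = "numeric",
    numericalAperture = "numeric",
    emissionWavelength = "numeric",
    labelNoiseSigma = "numeric",
    photonScale = "numeric",
    rngSeed = "integer"
  ),
  validity = function(object) {
    msg <- character(0)
    if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
    if (object@numericalAperture <= 0 || object@numericalAperture > 1.7)
      msg <- c(msg, "numericalAperture must lie in (0, 1.7]")
    if (object@emissionWavelength <= 0)
      msg <- c(msg, "emissionWavelength must be > 0")
    if (object@labelNoiseSigma < 0) msg <- c(msg, "labelNoiseSigma must be >= 0")
    if (object@photonScale <= 0) msg <- c(msg, "photonScale must be > 0")
    if (length(msg)) msg else TRUE
  }
)

#' @param pixelSize,numericalAperture,emissionWavelength,labelNoiseSigma,photonScale,rngSeed
#'   see slots.  Defaults reproduce a widefield/confocal-like setup:
#'   NA 1.4, emission 525 nm, 50 nm pixels, labelling noise sd 2 grey levels.
#' @return \code{ImagingSpec()} returns a validated \code{ImagingSpec}.
#' @rdname ImagingSpec-class
#' @examples
#' ImagingSpec(rngSeed = 7)
#' @export
ImagingSpec <- function(pixelSize = 0.05, numericalAperture = 1.4,
                        emissionWavelength = 525, labelNoiseSigma = 2,
                        photonScale = 5, rngSeed = 1L) {
  new("ImagingSpec",
    pixelSize = as.numeric(pixelSize),
    numericalAperture = as.numeric(numericalAperture),
    emissionWavelength = as.numeric(emissionWavelength),
    labelNoiseSigma = as.numeric(labelNoiseSigma),
    photonScale = as.numeric(photonScale),
    rngSeed = as.integer(rngSeed)
  )
}

#' Two-channel synthetic micrograph with known ground truth
#'
#' @slot phalloidin matrix, F-actin channel intensities (>= 0).
#' @slot zdisc matrix, Z-disc marker channel, same shape.
#' @slot pixelSize numeric, micrometres per pixel.
#' @slot groundTruth list of \code{MyofibrilSpec} used to render the scene.
#' @slot imaging the \code{ImagingSpec} used (may be absent for pure
#'   ground-truth renders).
#' @export
setClass("SyntheticImage",
  representation(
    phalloidin = "matrix",
    zdisc = "matrix",
    pixelSize = "numeric",
    groundTruth = "list",
    imaging = "ANY"
  ),
  validity = function(object) {
    msg <- character(0)
    if (!identical(dim(object@phalloidin), dim(object@zdisc)))
      msg <- c(msg, "channels must share shape")
    if (any(object@phalloidin < 0) || any(object@zdisc < 0))
      msg <- c(msg, "intensities must be >= 0")
    if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
    if (length(msg)) msg else TRUE
  }
)

#' Two-channel image stack under analysis
#'
#' Carrier for a phalloidin (F-actin) channel and a Z-disc marker channel,
#' either a single plane (2D) or a z-stack (3D, planes in the third
#' dimension), with the physical pixel size.
#'
#' @slot phalloidin 2D or 3D numeric array.
#' @slot zdisc array of the same shape.
#' @slot pixelSize numeric, micrometres per pixel.
#' @export
setClass("ImageStack",
  representation(phalloidin = "array", zdisc = "array", pixelSize = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (!identical(dim(object@phalloidin), dim(object@zdisc)))
      msg <- c(msg, "channels must share shape")
    if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
    if (length(msg)) msg else TRUE
  }
)

#' @param phalloidin,zdisc,pixelSize see slots.
#' @return \code{ImageStack()} returns a validated \code{ImageStack}.
#' @rdname ImageStack-class
#' @export
ImageStack <- function(phalloidin, zdisc, pixelSize) {
  if (is.matrix(phalloidin)) phalloidin <- array(phalloidin, dim(phalloidin))
  if (is.matrix(zdisc)) zdisc <- array(zdisc, dim(zdisc))
  new("ImageStack", phalloidin = phalloidin, zdisc = zdisc,
      pixelSize = as.numeric(pixelSize))
}

#' Segmented myofibril candidate region
#'
#' One connected component of the thresholded phalloidin channel together
#' with deterministic quality-control flags.  Flagged components
#' (\code{touches_border}, \code{branched_skeleton},
#' \code{overlaps_neighbour}) are excluded from automatic downstream
#' analysis but still reported.
#'
#' @slot mask logical matrix covering the full image frame.
#' @slot label integer component label.
#' @slot area integer, component area in pixels.
#' @slot bbox integer length 4: row min/max, col min/max (1-based).
#' @slot qcFlags named logical vector with elements \code{touches_border},
#'   \code{branched_skeleton}, \code{overlaps_neighbour}.
#' @export
setClass("MyofibrilMask",
  representation(mask = "matrix", label = "integer", area = "integer",
                 bbox = "integer", qcFlags = "logical"))

#' Arclength-parameterised myofibril centerline
#'
#' @slot points n x 2 matrix of (x, y) positions in micrometres.
#' @slot arclength numeric, cumulative arclength in micrometres (strictly
#'   increasing, starts at 0).
#' @slot tangent n x 2 matrix of unit tangents.
#' @slot normal n x 2 matrix of unit normals (tangent rotated +90 degrees).
#' @export
setClass("Centerline",
  representation(points = "matrix", arclength = "numeric",
                 tangent = "matrix", normal = "matrix"),
  validity = function(object) {
    msg <- character(0)
    n <- nrow(object@points)
    if (length(object@arclength) != n) msg <- c(msg, "arclength length mismatch")
    if (n > 1 && any(diff(object@arclength) <= 0))
      msg <- c(msg, "arclength must be strictly increasing")
    tn <- sqrt(rowSums(object@tangent^2))
    nn <- sqrt(rowSums(object@normal^2))
    if (any(abs(tn - 1) > 1e-6) || any(abs(nn - 1) > 1e-6))
      msg <- c(msg, "tangent and normal must be unit vectors")
    dot <- rowSums(object@tangent * object@normal)
    if (any(abs(dot) > 1e-6)) msg <- c(msg, "tangent must be orthogonal to normal")
    if (length(msg)) msg else TRUE
  }
)

#' Sampled 1D intensity profile
#'
#' Uniformly sampled intensity versus physical position, either along the
#' myofibril axis (\code{axisTag = "longitudinal"}, positions are
#' arclength) or across it (\code{axisTag = "transverse"}, positions are
#' signed distance from the centerline).
#'
#' @slot positions numeric, micrometres, uniform strictly increasing grid.
#' @slot values numeric, intensities (>= 0), same length.
#' @slot axisTag character, "longitudinal" or "transverse".
#' @slot channelTag character, source channel label.
#' @export
setClass("IntensityProfile",
  representation(positions = "numeric", values = "numeric",
                 axisTag = "character", channelTag = "character"),
  validity = function(object) {
    msg <- character(0)
    n <- length(object@positions)
    if (n != length(object@values)) msg <- c(msg, "positions/values length mismatch")
    if (n < 8) msg <- c(msg, "profile needs >= 8 samples")
    if (n >= 2) {
      d <- diff(object@positions)
      if (any(d <= 0)) msg <- c(msg, "positions must be strictly increasing")
      if (diff(range(d)) > 1e-9) msg <- c(msg, "positions must be uniform within 1e-9")
    }
    if (!object@axisTag %in% c("longitudinal", "transverse"))
      msg <- c(msg, "axisTag must be 'longitudinal' or 'transverse'")
    if (length(msg)) msg else TRUE
  }
)

#' @param positions,values,axisTag,channelTag see slots.
#' @return \code{IntensityProfile()} returns a validated profile.
#' @rdname IntensityProfile-class
#' @export
IntensityProfile <- function(positions, values, axisTag = "longitudinal",
                             channelTag = "phalloidin") {
  new("IntensityProfile", positions = as.numeric(positions),
      values = as.numeric(values), axisTag = axisTag, channelTag = channelTag)
}

#' Multi-Gaussian fit of Z-disc peaks
#'
#' Result of fitting \code{baseline + sum_i A_i exp(-(s - mu_i)^2 / (2
#' sigma_i^2))} to a longitudinal Z-disc profile.  Successive center
#' differences are the sarcomere lengths.
#'
#' @slot centers numeric, peak centers mu_i in micrometres, strictly increasing.
#' @slot sigmas numeric, peak widths in micrometres (> 0).
#' @slot amplitudes numeric, peak amplitudes (> 0).
#' @slot baseline numeric scalar.
#' @slot residualRMS numeric, root-mean-square fit residual.
#' @slot converged logical, optimiser convergence flag.
#' @export
setClass("GaussianPeakSet",
  representation(centers = "numeric", sigmas = "numeric",
                 amplitudes = "numeric", baseline = "numeric",
                 residualRMS = "numeric", converged = "logical"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@centers) > 1 && any(diff(object@centers) <= 0))
      msg <- c(msg, "centers must be strictly increasing")
    if (any(object@sigmas <= 0)) msg <- c(msg, "sigmas must be > 0")
    if (any(object@amplitudes <= 0)) msg <- c(msg, "amplitudes must be > 0")
    if (length(msg)) msg else TRUE
  }
)

#' Disc-model fit of a transverse profile
#'
#' Result of fitting the projected chord of a uniform cylinder convolved
#' with a Gaussian point-spread function; \code{2 * radius} is the
#' myofibril diameter.
#'
#' @slot center numeric, cylinder axis position in micrometres.
#' @slot radius numeric, cylinder radius R in micrometres (> 0).
#' @slot psfSigma numeric, Gaussian PSF sigma in micrometres (>= 0).
#' @slot amplitude numeric, peak amplitude above baseline.
#' @slot baseline numeric.
#' @slot residualRMS numeric.
#' @slot converged logical.
#' @export
setClass("DiscFit",
  representation(center = "numeric", radius = "numeric", psfSigma = "numeric",
                 amplitude = "numeric", baseline = "numeric",
                 residualRMS = "numeric", converged = "logical"),
  validity = function(object) {
    msg <- character(0)
    if (object@radius <= 0) msg <- c(msg, "radius must be > 0")
    if (object@psfSigma < 0) msg <- c(msg, "psfSigma must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' Ordered peak-to-peak sarcomere lengths
#'
#' @slot distances numeric, successive Z-disc peak-to-peak distances in
#'   micrometres (all > 0).
#' @slot mean,sd numeric summaries of \code{distances}.
#' @export
setClass("SarcomereLengthSet",
  representation(distances = "numeric", mean = "numeric", sd = "numeric"),
  validity = function(object) {
    if (length(object@distances) && any(object@distances <= 0))
      "distances must be > 0" else TRUE
  }
)

#' Average sarcomere geometry of one developmental stage
#'
#' Houses the morphometric parameters of one stage of flight-muscle
#' myofibrillogenesis.  The filament lengths are tied to the band widths by
#' the two identities
#' \deqn{L_{thick} = L_{sarcomere} - W_{I\mbox{-}band}}
#' \deqn{L_{thin} = (L_{sarcomere} - W_{H\mbox{-}zone} + W_{Z\mbox{-}disc}) / 2}
#' and the validity method enforces them exactly.
#'
#' @slot stage character label, e.g. "36h APF".
#' @slot lSarcomere,wIBand,wHZone,wZDisc numeric, micrometres.
#' @slot lThick,lThin numeric, filament lengths in micrometres (derived).
#' @slot nThick integer, thick filaments per myofibril cross-section.
#' @slot spacing numeric, thick-filament lattice spacing in nanometres.
#' @export
setClass("StageMorphometrics",
  representation(stage = "character", lSarcomere = "numeric",
                 wIBand = "numeric", wHZone = "numeric", wZDisc = "numeric",
                 lThick = "numeric", lThin = "numeric",
                 nThick = "integer", spacing = "numeric"),
  validity = function(object) {
    msg <- character(0)
    w <- c(object@wIBand, object@wHZone, object@wZDisc)
    if (any(w < 0)) msg <- c(msg, "band widths must be >= 0")
    if (object@wIBand >= object@lSarcomere) msg <- c(msg, "wIBand must be < lSarcomere")
    if (object@wHZone >= object@lSarcomere) msg <- c(msg, "wHZone must be < lSarcomere")
    if (abs(object@lThick - (object@lSarcomere - object@wIBand)) > 1e-9)
      msg <- c(msg, "lThick must equal lSarcomere - wIBand")
    if (abs(object@lThin -
            (object@lSarcomere - object@wHZone + object@wZDisc) / 2) > 1e-9)
      msg <- c(msg, "lThin must equal (lSarcomere - wHZone + wZDisc)/2")
    if (object@nThick < 0L) msg <- c(msg, "nThick must be >= 0")
    if (object@spacing <= 0) msg <- c(msg, "spacing must be > 0")
    if (length(msg)) msg else TRUE
  }
)

#' Hexagonal myofilament lattice cross-section
#'
#' Thick filaments on a triangular (hexagonally packed) lattice built in
#' concentric rings; thin filaments at the midpoint of every
#' nearest-neighbour thick pair (the MyAc-layer arrangement).
#'
#' @slot thick n x 2 matrix, thick-filament (x, y) positions in nanometres.
#' @slot thin m x 2 matrix, thin-filament positions in nanometres.
#' @slot spacing numeric, nearest-neighbour thick spacing d in nanometres.
#' @slot interior logical, per thick site: TRUE if it has 6 thick neighbours.
#' @export
setClass("LatticeModel",
  representation(thick = "matrix", thin = "matrix", spacing = "numeric",
                 interior = "logical"))

#' Scaled three-dimensional sarcomere model
#'
#' Filament spans along the sarcomere axis z, with Z-lines at z = 0 and
#' z = lSarcomere and the M-line at z = lSarcomere / 2.  Thick filaments
#' are centred on the M-line; thin filaments are anchored at a Z-line,
#' overhang it by half the Z-disc overlap, and point toward the M-line,
#' mirror-symmetrically in the two half-sarcomeres.
#'
#' @slot filaments data.frame with columns type ("thick"/"thin"), x, y
#'   (nanometres, lattice cross-section), zStart, zEnd (micrometres).
#' @slot lSarcomere numeric, sarcomere length in micrometres.
#' @slot stage the generating \code{StageMorphometrics}.
#' @slot lattice the generating \code{LatticeModel}.
#' @export
setClass("Sarcomere3DModel",
  representation(filaments = "data.frame", lSarcomere = "numeric",
                 stage = "ANY", lattice = "ANY"))

#' Superplot-style hierarchical measurement summary
#'
#' Raw per-sarcomere/per-position measurements with hierarchical means:
#' per myofibril, per experiment (mean of its myofibril means) and grand
#' (mean of experiment means -- the superplot convention, deliberately not
#' the pooled mean).
#'
#' @slot rows data.frame of raw measurements.
#' @slot myofibrilMeans data.frame, one row per (experiment, myofibril).
#' @slot experimentMeans data.frame, one row per experiment.
#' @slot grandMean,grandSD named numeric, per measured variable.
#' @slot nLabel character, "experiments/individual measurements".
#' @slot singleExperiment logical, TRUE when the sd is degenerate (one
#'   experiment) and reported as 0.
#' @export
setClass("MeasurementTable",
  representation(rows = "data.frame", myofibrilMeans = "data.frame",
                 experimentMeans = "data.frame", grandMean = "numeric",
                 grandSD = "numeric", nLabel = "character",
                 singleExperiment = "logical"))

#' Analysis configuration
#'
#' All tunable parameters of the automatic pipeline in one validated
#' object, serialisable to YAML/JSON.  Unknown keys are rejected.
#'
#' @slot values named list of parameters, see \code{\link{analysisConfig}}.
#' @export
setClass("AnalysisConfig", representation(values = "list"))
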