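# File interchange: OME-TIFF stacks, ground-truth manifests, configuration.

# The installed TIFF writer does not emit an ImageDescription tag, so the
# OME-XML block is injected afterwards: the first image file directory (IFD)
# is relocated to the end of the file with an added tag 270 entry.  Classic
# little-endian TIFF only, which is what tiff::writeTIFF produces.
.tiffSetDescription <- function(path, description) {
  raw <- readBin(path, "raw", file.size(path))
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.integer(raw[off + 1:4]) * 256^(0:3))
  if (rawToChar(raw[1:2]) != "II" || u16(2) != 42L)
    stop("not a little-endian classic TIFF")
  ifd <- u32(4)
  n <- u16(ifd)
  entries <- raw[(ifd + 2 + 1):(ifd + 2 + 12 * n)]
  nextIFD <- raw[(ifd + 2 + 12 * n + 1):(ifd + 2 + 12 * n + 4)]
  desc <- c(charToRaw(description), as.raw(0))
  if (length(desc) %% 2) desc <- c(desc, as.raw(0))
  descOff <- length(raw)
  pack32 <- function(x) as.raw(x %/% 256^(0:3) %% 256)
  pack16 <- function(x) as.raw(x %/% c(1, 256) %% 256)
  entry <- c(pack16(270L), pack16(2L), pack32(length(desc)), pack32(descOff))
  # keep entries sorted by tag id
  tags <- vapply(seq_len(n), function(i) {
    e <- entries[((i - 1) * 12 + 1):((i - 1) * 12 + 2)]
    sum(as.integer(e) * c(1, 256))
  }, numeric(1))
  pos <- sum(tags < 270L)
  newEntries <- c(entries[seq_len(pos * 12)], entry,
                  if (pos < n) entries[(pos * 12 + 1):(n * 12)])
  newIFDOff <- descOff + length(desc)
  block <- c(desc, pack16(n + 1L), newEntries, nextIFD)
  raw <- c(raw, block)
  raw[5:8] <- pack32(newIFDOff)
  writeBin(raw, path)
  invisible(path)
}

.omeDescription <- function(pixelSize, channelMax) {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
    '<Image ID="Image:0"><Pixels ID="Pixels:0" DimensionOrder="XYCZT" ',
    sprintf('PhysicalSizeX="%.9g" PhysicalSizeXUnit="µm" ', pixelSize),
    sprintf('PhysicalSizeY="%.9g" PhysicalSizeYUnit="µm" ', pixelSize),
    'SizeC="2" SizeZ="1" SizeT="1" Type="float">',
    sprintf('<Channel ID="Channel:0:0" Name="phalloidin" />'),
    sprintf('<Channel ID="Channel:0:1" Name="zdisc" />'),
    '</Pixels>',
    '<StructuredAnnotations><XMLAnnotation ID="Annotation:0"><Value>',
    sprintf('<ChannelMax c0="%.9g" c1="%.9g"/>', channelMax[1], channelMax[2]),
    '</Value></XMLAnnotation></StructuredAnnotations>',
    '</Image></OME>')
}

#' Write a two-channel image as OME-TIFF
#'
#' Channels are stored as two 32-bit pages scaled to [0, 1]; the OME-XML
#' ImageDescription carries the physical pixel size and the per-channel
#' intensity maxima so that \code{\link{loadStack}} restores the original
#' intensity scale.
#'
#' @param img a \code{\link{SyntheticImage}} or \code{\link{ImageStack}}
#'   with 2D channels.
#' @param path output TIFF path.
#' @param manifestPath optional path for a JSON ground-truth manifest
#'   (\code{SyntheticImage} only).
#' @return the TIFF path, invisibly.
#' @export
writeSyntheticImage <- function(img, path, manifestPath = NULL) {
  ch1 <- if (is(img, "SyntheticImage")) img@phalloidin else phalloidinChannel(img)
  ch2 <- if (is(img, "SyntheticImage")) img@zdisc else zdiscChannel(img)
  px <- pixelSize(img)
  mx <- c(max(ch1, 1e-12), max(ch2, 1e-12))
  p1 <- ch1 / mx[1]
  p2 <- ch2 / mx[2]
  tiff::writeTIFF(list(p1, p2), path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  .tiffSetDescription(path, .omeDescription(px, mx))
  if (!is.null(manifestPath) && is(img, "SyntheticImage"))
    writeGroundTruthManifest(img, manifestPath)
  invisible(path)
}

#' Write / read a ground-truth manifest
#'
#' The manifest is JSON holding every generating \code{MyofibrilSpec}, the
#' \code{ImagingSpec} (including the RNG seed) and the pixel size, at full
#' double precision so that ground truth round-trips losslessly.
#'
#' @param img a \code{\link{SyntheticImage}}.
#' @param path JSON path.
#' @return \code{writeGroundTruthManifest}: the path, invisibly;
#'   \code{readGroundTruthManifest}: a list with elements \code{specs}
#'   (list of \code{MyofibrilSpec}), \code{imaging} (\code{ImagingSpec} or
#'   NULL) and \code{pixelSize}.
#' @export
writeGroundTruthManifest <- function(img, path) {
  specs <- lapply(img@groundTruth, function(sp) list(
    n_sarcomeres = sp@nSarcomeres, sarcomere_length = sp@sarcomereLength,
    diameter = sp@diameter, zdisc_width = sp@zdiscWidth,
    hzone_width = sp@hzoneWidth, orientation = sp@orientation,
    curvature = sp@curvature, origin = sp@origin))
  imaging <- NULL
  if (is(img@imaging, "ImagingSpec")) {
    im <- img@imaging
    imaging <- list(pixel_size = im@pixelSize,
                    numerical_aperture = im@numericalAperture,
                    emission_wavelength = im@emissionWavelength,
                    label_noise_sigma = im@labelNoiseSigma,
                    photon_scale = im@photonScale, rng_seed = im@rngSeed)
  }
  jsonlite::write_json(list(pixel_size = img@pixelSize, specs = specs,
                            imaging = imaging),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeGroundTruthManifest
#' @export
readGroundTruthManifest <- function(path) {
  j <- jsonlite::read_json(path)
  specs <- lapply(j$specs, function(s) MyofibrilSpec(
    nSarcomeres = s$n_sarcomeres, sarcomereLength = s$sarcomere_length,
    diameter = s$diameter, zdiscWidth = s$zdisc_width,
    hzoneWidth = s$hzone_width, orientation = s$orientation,
    curvature = s$curvature, origin = unlist(s$origin)))
  imaging <- NULL
  if (!is.null(j$imaging)) {
    im <- j$imaging
    imaging <- ImagingSpec(pixelSize = im$pixel_size,
                           numericalAperture = im$numerical_aperture,
                           emissionWavelength = im$emission_wavelength,
                           labelNoiseSigma = im$label_noise_sigma,
                           photonScale = im$photon_scale,
                           rngSeed = im$rng_seed)
  }
  list(specs = specs, imaging = imaging, pixelSize = j$pixel_size)
}

#' Load a two-channel OME-TIFF stack
#'
#' Reads a multi-page TIFF (page 1 = phalloidin, page 2 = Z-disc marker by
#' default), restoring the physical pixel size from the OME
#' ImageDescription; when the metadata is absent a
#' \code{pixelSizeOverride} must be supplied.
#'
#' @param path TIFF path.
#' @param pixelSizeOverride micrometres per pixel, used when the file has
#'   no OME pixel-size metadata.
#' @return an \code{\link{ImageStack}}.
#' @export
loadStack <- function(path, pixelSizeOverride = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (length(pages) < 2)
    .condition("expected a two-channel (two-page) TIFF", "ChannelCountError")
  desc <- attr(pages[[1]], "description")
  px <- pixelSizeOverride
  mx <- c(1, 1)
  if (!is.null(desc) && grepl("PhysicalSizeX", desc)) {
    px <- as.numeric(sub('.*PhysicalSizeX="([0-9.eE+-]+)".*', "\\1", desc))
    if (grepl("ChannelMax", desc)) {
      mx <- c(as.numeric(sub('.*ChannelMax c0="([0-9.eE+-]+)".*', "\\1", desc)),
              as.numeric(sub('.*ChannelMax[^/]*c1="([0-9.eE+-]+)".*', "\\1",
                             desc)))
    }
  }
  if (is.null(px) || is.na(px))
    .condition("no pixel-size metadata and no override given",
               "MissingPixelSize")
  drop1 <- function(m) if (length(dim(m)) == 3L) m[, , 1] else m
  ImageStack(drop1(pages[[1]]) * mx[1], drop1(pages[[2]]) * mx[2], px)
}

.configDefaults <- function() list(
  mode = "auto",
  threshold_method = "otsu",
  threshold = NULL,
  min_length_um = 4,
  longitudinal_half_width_um = 0.3,
  transverse_half_length_um = 2.5,
  prominence_frac = 0.2,
  psf_sigma_init_um = 0.21 * 0.525 / 1.4,
  exclude_terminal = TRUE,
  n_transverse = 9,
  centerline_step_um = 0.05
)

#' Build a validated analysis configuration
#'
#' All pipeline parameters with their defaults; unknown keys are rejected.
#' \code{mode} is \code{"auto"} (segmentation) or \code{"manual"}
#' (polyline sidecars).
#'
#' @param ... named overrides of the defaults, see
#'   \code{.configDefaults} in the source or the vignette for the full
#'   list (threshold method, minimum length, ROI sizes, prominence
#'   fraction, PSF sigma init, terminal exclusion, transverse fit count,
#'   centerline step).
#' @return an \code{\link{AnalysisConfig}}.
#' @examples
#' analysisConfig(exclude_terminal = FALSE)
#' @export
analysisConfig <- function(...) {
  defaults <- .configDefaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  if (!defaults$mode %in% c("auto", "manual"))
    stop("mode must be 'auto' or 'manual'")
  new("AnalysisConfig", values = defaults)
}

#' Read an analysis configuration from YAML or JSON
#'
#' @param path file path; format chosen by extension (.yaml/.yml/.json).
#' @return an \code{\link{AnalysisConfig}}.
#' @export
readAnalysisConfig <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysisConfig, vals)
}

#' Write an analysis configuration
#'
#' @param config an \code{\link{AnalysisConfig}}.
#' @param path output path (.yaml/.yml or .json).
#' @return the path, invisibly.
#' @export
writeAnalysisConfig <- function(config, path) {
  vals <- config@values
  vals <- vals[!vapply(vals, is.null, logical(1))]
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(vals, path)
  else jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
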