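# Longitudinal and transverse intensity profiles along a centerline.

# Bilinear interpolation at physical coordinates (um).  Pixel centres sit at
# 0-based index times pixelSize; matrix rows index y, columns index x.
.bilinear <- function(image, x, y, pixelSize) {
  cx <- x / pixelSize   # 0-based fractional column
  ry <- y / pixelSize   # 0-based fractional row
  nr <- nrow(image)
  nc <- ncol(image)
  if (any(cx < 0 | cx > nc - 1 | ry < 0 | ry > nr - 1))
    .condition("sampling position outside the image", "OutOfBounds")
  c0 <- pmin(floor(cx), nc - 2)
  r0 <- pmin(floor(ry), nr - 2)
  fx <- cx - c0
  fy <- ry - r0
  i00 <- (c0) * nr + r0 + 1            # column-major linear index, 1-based
  v00 <- image[i00]
  v10 <- image[i00 + 1]                # next row (y)
  v01 <- image[i00 + nr]               # next column (x)
  v11 <- image[i00 + nr + 1]
  v00 * (1 - fx) * (1 - fy) + v10 * (1 - fx) * fy +
    v01 * fx * (1 - fy) + v11 * fx * fy
}

# Interpolate centerline position and normal at arbitrary arclengths.
.centerlineAt <- function(cl, s) {
  al <- cl@arclength
  if (any(s < al[1] - 1e-9 | s > al[length(al)] + 1e-9))
    .condition("arclength outside the centerline span", "OutOfBounds")
  s <- pmin(pmax(s, al[1]), al[length(al)])
  px <- stats::approx(al, cl@points[, 1], xout = s)$y
  py <- stats::approx(al, cl@points[, 2], xout = s)$y
  nx <- stats::approx(al, cl@normal[, 1], xout = s)$y
  ny <- stats::approx(al, cl@normal[, 2], xout = s)$y
  nn <- sqrt(nx^2 + ny^2)
  cbind(x = px, y = py, nx = nx / nn, ny = ny / nn)
}

#' Longitudinal intensity profile along a myofibril
#'
#' At every arclength sample the intensity is averaged over a segment of
#' \code{[-halfWidth, +halfWidth]} along the local normal (bilinear
#' interpolation), giving intensity versus arclength -- the input for
#' multi-Gaussian sarcomere-length fitting on the Z-disc channel.
#'
#' @param image 2D numeric matrix.
#' @param cl a \code{\link{Centerline}}.
#' @param pixelSize micrometres per pixel.
#' @param halfWidth half-width of the averaging ROI in micrometres.
#' @param step arclength sampling step in micrometres; default half a pixel.
#' @param channelTag label stored on the profile.
#' @return an \code{\link{IntensityProfile}} with \code{axisTag
#'   "longitudinal"}.
#' @export
longitudinalProfile <- function(image, cl, pixelSize, halfWidth = 0.3,
                                step = pixelSize / 2, channelTag = "zdisc") {
  stopifnot(halfWidth > 0, step > 0)
  total <- max(cl@arclength)
  s <- seq(0, total, by = step)
  at <- .centerlineAt(cl, s)
  offs <- seq(-halfWidth, halfWidth, by = pixelSize / 2)
  vals <- rowMeans(vapply(offs, function(o) {
    .bilinear(image, at[, "x"] + o * at[, "nx"], at[, "y"] + o * at[, "ny"],
              pixelSize)
  }, numeric(length(s))))
  IntensityProfile(s, pmax(vals, 0), "longitudinal", channelTag)
}

#' Transverse intensity profile across a myofibril
#'
#' Samples the image along the local normal at one arclength position;
#' profile positions are signed distances from the centerline.  The input
#' for disc-model diameter fitting on the phalloidin channel.
#'
#' @inheritParams longitudinalProfile
#' @param atArclength arclength position in micrometres.
#' @param halfLength half-extent of the profile in micrometres (should cover
#'   the fibril radius plus the PSF tails).
#' @return an \code{\link{IntensityProfile}} with \code{axisTag
#'   "transverse"}.
#' @export
transverseProfile <- function(image, cl, atArclength, pixelSize,
                              halfLength = 2.5, step = pixelSize / 2,
                              channelTag = "phalloidin") {
  stopifnot(halfLength > 0, step > 0)
  at <- .centerlineAt(cl, atArclength)
  pos <- seq(-halfLength, halfLength, by = step)
  vals <- .bilinear(image, at[1, "x"] + pos * at[1, "nx"],
                    at[1, "y"] + pos * at[1, "ny"], pixelSize)
  IntensityProfile(pos, pmax(vals, 0), "transverse", channelTag)
}

#' Export a profile as a two-column CSV
#'
#' @param p an \code{\link{IntensityProfile}}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeProfileCSV <- function(p, path) {
  utils::write.csv(data.frame(position_um = p@positions, intensity = p@values),
                   path, row.names = FALSE)
  invisible(path)
}
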