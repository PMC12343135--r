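# Fixture builders shared across the suite.  All synthetic images are
# generated in code at test time; no binary fixtures are stored.

# Default optics: NA 1.4, 525 nm emission, 50 nm pixels, label noise sd 2.
fixImaging <- function(seed = 1L, ...) ImagingSpec(rngSeed = seed, ...)

# A straight mature-like myofibril that fits a (140, 480) canvas with room
# for 2.5 um transverse profiles on either side.
fixSpec <- function(nSarcomeres = 6, sarcomereLength = 3.2, diameter = 1.5,
                    orientation = 0, origin = c(2, 3), ...) {
  MyofibrilSpec(nSarcomeres, sarcomereLength, diameter,
                orientation = orientation, origin = origin, ...)
}

fixCanvas <- c(140L, 480L)

# Render + full noise pipeline in one call.
fixImage <- function(seed = 1L, specs = list(fixSpec()), canvas = fixCanvas,
                     noise = TRUE, ...) {
  simulateImage(specs, fixImaging(seed, ...), canvas, noise = noise)
}

asStack <- function(img) {
  ImageStack(phalloidinChannel(img), zdiscChannel(img), pixelSize(img))
}

# Straight-axis centerline through a spec laid out at orientation 0.
fixAxisCenterline <- function(spec, from = 0, to = NULL) {
  if (is.null(to)) to <- spec@nSarcomeres * spec@sarcomereLength
  centerlineFromPolyline(rbind(
    c(spec@origin[1] + from, spec@origin[2]),
    c(spec@origin[1] + to, spec@origin[2])))
}
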