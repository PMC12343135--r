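# Multi-Gaussian Z-disc fitting and disc-model diameter fitting.

gaussProfile <- function(mus, A = 100, sigma = 0.2, B = 0,
                         span = c(0, 22), step = 0.05) {
  x <- seq(span[1], span[2], by = step)
  v <- rep(B, length(x))
  for (m in mus) v <- v + A * exp(-(x - m)^2 / (2 * sigma^2))
  IntensityProfile(x, v)
}

test_that("peak detection handles flat, clean and noisy profiles", {
  flat <- IntensityProfile(seq(0, 1, by = 0.05), rep(2, 21))
  expect_error(detectPeaks(flat), class = "NoPeaks")
  two <- gaussProfile(c(5, 8), span = c(0, 13))
  pk <- detectPeaks(two)
  expect_equal(pk$position, c(5, 8), tolerance = 1e-9)
  sp <- fixSpec(6)
  img <- fixImage(21, specs = list(sp))
  cl <- fixAxisCenterline(sp, from = -0.4, to = 19.6)
  lp <- longitudinalProfile(zdiscChannel(img), cl, pixelSize(img))
  expect_equal(nrow(detectPeaks(lp)), 7)
})

test_that("a single noiseless Gaussian is recovered to sub-5-nm accuracy", {
  g <- fitGaussianPeaks(gaussProfile(5, span = c(0, 10)))
  expect_equal(peakCenters(g), 5, tolerance = 0.005)
  expect_equal(g@sigmas, 0.2, tolerance = 0.01)
  expect_true(converged(g))
})

test_that("six noiseless peaks give five spacings of 3.2 um", {
  g <- fitGaussianPeaks(gaussProfile((0:5) * 3.2 + 1.5))
  d <- diff(peakCenters(g))
  expect_length(d, 5)
  expect_true(all(abs(d - 3.2) < 0.01))
})

test_that("center precision under Poisson noise beats 20 nm", {
  centers <- vapply(1:100, function(s) {
    set.seed(s)
    x <- seq(0, 10, by = 0.05)
    v <- rpois(length(x), 100 * exp(-(x - 5)^2 / (2 * 0.2^2)) + 5)
    peakCenters(fitGaussianPeaks(IntensityProfile(x, v)))[1]
  }, numeric(1))
  expect_lt(sd(centers), 0.02)
})

test_that("sarcomere lengths are successive differences with optional trimming", {
  g <- new("GaussianPeakSet", centers = c(0, 3.2, 6.4), sigmas = rep(0.2, 3),
           amplitudes = rep(1, 3), baseline = 0, residualRMS = 0,
           converged = TRUE)
  expect_equal(sarcomereLengths(g)@distances, c(3.2, 3.2))
  g5 <- new("GaussianPeakSet", centers = c(0, 3.2, 6.4, 9.6, 12.8),
            sigmas = rep(0.2, 5), amplitudes = rep(1, 5), baseline = 0,
            residualRMS = 0, converged = TRUE)
  sl <- sarcomereLengths(g5, excludeTerminal = TRUE)
  expect_equal(sl@distances, c(3.2, 3.2))
  expect_equal(sl@mean, mean(sl@distances))
  expect_error(sarcomereLengths(g, excludeTerminal = TRUE),
               class = "TooFewPeaks")
})

test_that("disc model obeys its closed-form limits", {
  x <- seq(-2, 2, by = 0.005)
  y0 <- discModel(x, 0, 0.75, 0, 100, 10)
  expect_equal(y0[x == 0], 110)
  expect_equal(y0[abs(abs(x) - 0.75) < 1e-9], c(10, 10))
  expect_equal(y0, rev(y0))
  # FWHM of the unblurred projection is sqrt(3) R
  p <- IntensityProfile(x, y0, "transverse")
  expect_equal(profileFWHM(p), sqrt(3) * 0.75, tolerance = 1e-3)
  # blurred version remains even
  y1 <- discModel(x, 0, 0.75, 0.1, 100, 10)
  expect_equal(y1, rev(y1), tolerance = 1e-9)
})

test_that("disc fit recovers its own model and shift/scale equivariance holds", {
  x <- seq(-2.5, 2.5, by = 0.025)
  p <- IntensityProfile(x, discModel(x, 0.1, 0.75, 0.10, 100, 10), "transverse")
  f <- fitDisc(p, 0.08)
  expect_true(converged(f))
  expect_equal(fitDiameter(f), 1.5, tolerance = 0.01)
  expect_equal(f@center, 0.1, tolerance = 0.01)
  # scale: positions/widths unchanged, amplitude/baseline scale
  p2 <- IntensityProfile(x, 3 * intensities(p), "transverse")
  f2 <- fitDisc(p2, 0.08)
  expect_equal(fitDiameter(f2), fitDiameter(f), tolerance = 1e-3)
  expect_equal(f2@amplitude / f@amplitude, 3, tolerance = 0.01)
  # translation: centers shift exactly with the coordinate
  p3 <- IntensityProfile(x + 0.7, intensities(p), "transverse")
  f3 <- fitDisc(p3, 0.08)
  expect_equal(f3@center - f@center, 0.7, tolerance = 1e-3)
  expect_equal(fitDiameter(f3), fitDiameter(f), tolerance = 1e-3)
})

test_that("Gaussian fit is scale and translation equivariant", {
  p <- gaussProfile(c(4, 7.2), span = c(0, 11))
  g <- fitGaussianPeaks(p)
  p2 <- IntensityProfile(positions(p) + 2, 5 * intensities(p))
  g2 <- fitGaussianPeaks(p2)
  expect_equal(peakCenters(g2), peakCenters(g) + 2, tolerance = 1e-6)
  expect_equal(g2@sigmas, g@sigmas, tolerance = 1e-6)
  expect_equal(g2@amplitudes / g@amplitudes, c(5, 5), tolerance = 1e-6)
})

test_that("degenerate transverse profiles are rejected", {
  x <- seq(-2, 2, by = 0.05)
  expect_error(fitDisc(IntensityProfile(x, rep(5, length(x)), "transverse")),
               class = "DegenerateProfile")
})

test_that("disc fit absorbs the Airy blur of a simulated fibril within 3%", {
  sp <- fixSpec()
  img <- fixImage(22, specs = list(sp), noise = FALSE)
  cl <- fixAxisCenterline(sp, from = 0.5, to = 18.7)
  tp <- transverseProfile(phalloidinChannel(img), cl, 4.0, pixelSize(img))
  f <- fitDisc(tp)
  expect_true(converged(f))
  expect_lt(abs(fitDiameter(f) - 1.5) / 1.5, 0.03)
})

test_that("naive FWHM underestimates the diameter but the disc fit does not", {
  x <- seq(-2.5, 2.5, by = 0.025)
  p <- IntensityProfile(x, discModel(x, 0, 0.75, 1e-6, 100, 0), "transverse")
  fw <- profileFWHM(p)
  expect_lt(fw / 1.5, 0.9)
  expect_gt(fw / 1.5, 0.82)              # ~ sqrt(3)/2 = 0.866
  f <- fitDisc(p, 0.05)
  expect_lt(abs(fitDiameter(f) - 1.5) / 1.5, 0.01)
})

test_that("median diameter over positions matches a constant-diameter fixture", {
  sp <- fixSpec()
  # noiseless: every converged per-position fit agrees with the median
  clean <- fixImage(23, specs = list(sp), noise = FALSE)
  cl <- fixAxisCenterline(sp, from = 0.5, to = 18.7)
  dmc <- measureDiameter(phalloidinChannel(clean), cl, pixelSize(clean),
                         nPositions = 7)
  okc <- !is.na(dmc$diameters)
  expect_true(all(abs(dmc$diameters[okc] - dmc$diameter) < 0.02))
  # with full noise the median still lands within 5% of truth
  img <- fixImage(23, specs = list(sp))
  dm <- measureDiameter(phalloidinChannel(img), cl, pixelSize(img),
                        nPositions = 7)
  expect_lt(abs(dm$diameter - 1.5) / 1.5, 0.05)
  one <- measureDiameter(phalloidinChannel(img), cl, pixelSize(img),
                         nPositions = 1)
  expect_length(one$positions, 1)
})
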