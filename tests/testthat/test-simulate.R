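# Ground-truth rendering, Airy PSF and the noise pipeline.

test_that("spec invariants are enforced at construction", {
  expect_s4_class(fixSpec(), "MyofibrilSpec")
  expect_error(MyofibrilSpec(3, sarcomereLength = 3.2, zdiscWidth = 3.3),
               class = "InvalidSpec")
  expect_error(MyofibrilSpec(3, diameter = -1), class = "InvalidSpec")
  expect_error(MyofibrilSpec(3, zdiscWidth = 1.7, hzoneWidth = 1.6),
               class = "InvalidSpec")
})

test_that("empty scene renders all-zero channels", {
  gt <- renderGroundTruth(list(), fixImaging(), c(32, 32))
  expect_equal(sum(phalloidinChannel(gt)), 0)
  expect_equal(sum(zdiscChannel(gt)), 0)
})

test_that("a spec that does not fit the canvas is rejected", {
  expect_error(renderGroundTruth(list(fixSpec()), fixImaging(), c(30, 30)),
               class = "SpecOutOfCanvas")
})

test_that("n sarcomeres produce n+1 disjoint Z-disc bands", {
  for (n in c(2L, 6L)) {
    gt <- renderGroundTruth(list(fixSpec(n)), fixImaging(), c(140, 480))
    occupied <- colSums(zdiscChannel(gt)) > 0
    expect_equal(sum(diff(c(0, occupied)) == 1), n + 1)
  }
})

test_that("transverse extent of the rendered cylinder matches the diameter", {
  # with the axis offset half a pixel from the pixel-centre grid, the
  # D = 1.5 um cylinder at 50 nm pixels covers exactly 30 rows
  sp <- fixSpec(origin = c(2, 3.025))
  gt <- renderGroundTruth(list(sp), fixImaging(), c(140, 480))
  col <- round((2 + 0.8) / 0.05) + 1      # mid thin-filament region
  expect_equal(sum(phalloidinChannel(gt)[, col] > 1e-9), 30)
})

test_that("Z-disc overlap doubles the axial intensity", {
  gt <- renderGroundTruth(list(fixSpec()), fixImaging(), c(140, 480))
  ph <- phalloidinChannel(gt)
  row <- round(3 / 0.05) + 1
  zCol <- round((2 + 3.2) / 0.05) + 1      # on the second Z-line
  iCol <- round((2 + 0.8) / 0.05) + 1      # thin-filament region
  hCol <- round((2 + 1.6) / 0.05) + 1      # H-zone centre
  expect_equal(ph[row, zCol] / ph[row, iCol], 2, tolerance = 1e-6)
  expect_equal(ph[row, hCol], 0)
})

test_that("total Z-disc channel intensity scales with the Z-disc count", {
  tot <- vapply(c(2L, 5L, 9L), function(n) {
    sum(zdiscChannel(renderGroundTruth(list(fixSpec(n)), fixImaging(),
                                       c(140, 700))))
  }, numeric(1))
  perDisc <- tot / (c(2, 5, 9) + 1)
  expect_lt(diff(range(perDisc)) / mean(perDisc), 1e-6)
})

test_that("Airy kernel is normalised, symmetric, with the correct first zero", {
  k <- airyPSF(fixImaging(), 25)
  expect_equal(sum(k), 1, tolerance = 1e-9)
  expect_equal(k, k[rev(seq_len(nrow(k))), rev(seq_len(ncol(k)))])
  # radial profile on a fine grid: first zero at 3.8317 lambda / (2 pi NA)
  fine <- ImagingSpec(pixelSize = 1e-3)    # 1 nm grid
  kf <- airyPSF(fine, 300)
  centre <- 301
  prof <- kf[centre, centre:ncol(kf)]
  firstZero <- (which(diff(prof) > 0)[1] - 1) * 1e-3   # um
  expect_equal(firstZero, 3.8317 * 0.525 / (2 * pi * 1.4), tolerance = 2e-3)
  expect_error(airyPSF(fixImaging(), 2), "kernelRadius")
})

test_that("identical seeds reproduce the image bit for bit", {
  a <- fixImage(seed = 11)
  b <- fixImage(seed = 11)
  expect_identical(phalloidinChannel(a), phalloidinChannel(b))
  expect_identical(zdiscChannel(a), zdiscChannel(b))
  c <- fixImage(seed = 12)
  expect_false(identical(phalloidinChannel(a), phalloidinChannel(c)))
})

test_that("noiseless limit equals the blurred normalised ground truth", {
  im <- fixImaging(3)
  gt <- renderGroundTruth(list(fixSpec()), im, fixCanvas)
  ref <- fibrilMorph:::.convolveReflect(
    phalloidinChannel(gt) * (100 / max(phalloidinChannel(gt))),
    airyPSF(im, 25))
  out <- simulateImage(list(fixSpec()), im, fixCanvas, noise = FALSE)
  expect_equal(phalloidinChannel(out), ref, tolerance = 1e-12)
})

test_that("blur conserves total intensity away from the border", {
  gt <- renderGroundTruth(list(fixSpec()), fixImaging(), fixCanvas)
  ph <- phalloidinChannel(gt)
  blurred <- fibrilMorph:::.convolveReflect(ph, airyPSF(fixImaging(), 25))
  expect_lt(abs(sum(blurred) - sum(ph)) / sum(ph), 1e-3)
})

test_that("shot noise is mean-preserving over many realisations", {
  # pure Poisson configuration (no label noise): the mean of many noisy
  # draws converges to the blurred ground truth
  mk <- function(seed, sigma) ImagingSpec(pixelSize = 0.1, rngSeed = seed,
                                          labelNoiseSigma = sigma)
  sp <- MyofibrilSpec(2, 3.2, 1.2, origin = c(1.2, 2))
  canvas <- c(40, 90)
  noiseless <- simulateImage(list(sp), mk(1, 0), canvas, noise = FALSE,
                             kernelRadius = 12)
  expected <- phalloidinChannel(noiseless) * 5   # photonScale default
  acc <- matrix(0, canvas[1], canvas[2])
  nrep <- 1000
  for (s in seq_len(nrep))
    acc <- acc + phalloidinChannel(
      simulateImage(list(sp), mk(s, 0), canvas, kernelRadius = 12))
  mn <- acc / nrep
  sel <- expected > 10
  expect_lt(mean(abs(mn[sel] - expected[sel]) / expected[sel]), 0.01)
})

test_that("full noise pipeline stays mean-faithful on bright pixels", {
  # with clipped label noise a small positive bias appears at dim pixels;
  # bright pixels remain within 1%
  mk <- function(seed) ImagingSpec(pixelSize = 0.1, rngSeed = seed)
  sp <- MyofibrilSpec(2, 3.2, 1.2, origin = c(1.2, 2))
  canvas <- c(40, 90)
  noiseless <- simulateImage(list(sp), mk(1), canvas, noise = FALSE,
                             kernelRadius = 12)
  expected <- phalloidinChannel(noiseless) * 5
  acc <- matrix(0, canvas[1], canvas[2])
  for (s in seq_len(400))
    acc <- acc + phalloidinChannel(simulateImage(list(sp), mk(s), canvas,
                                                 kernelRadius = 12))
  mn <- acc / 400
  sel <- expected > 100
  expect_lt(mean(abs(mn[sel] - expected[sel]) / expected[sel]), 0.01)
})

test_that("rotating the spec by 90 degrees rotates the rendered canvas", {
  im <- fixImaging(5)
  N <- 200
  X <- (N - 1) * 0.05
  spA <- MyofibrilSpec(2, 3.2, 1.2, origin = c(1.5, 4), orientation = 10)
  spB <- MyofibrilSpec(2, 3.2, 1.2, origin = c(X - 4, 1.5), orientation = 100)
  A <- phalloidinChannel(renderGroundTruth(list(spA), im, c(N, N)))
  B <- phalloidinChannel(renderGroundTruth(list(spB), im, c(N, N)))
  expect_lt(max(abs(B - t(A[N:1, ]))) / max(A), 0.01)
})
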