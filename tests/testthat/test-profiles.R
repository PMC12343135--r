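# Longitudinal and transverse intensity profiles.

test_that("a constant image yields a constant profile", {
  img <- matrix(7, 120, 300)
  cl <- centerlineFromPolyline(rbind(c(3, 3), c(10, 3)))
  lp <- longitudinalProfile(img, cl, 0.05)
  expect_equal(diff(range(intensities(lp))), 0)
  expect_equal(intensities(lp)[1], 7)
})

test_that("the Z-disc profile of a 6-sarcomere fibril has 7 maxima", {
  sp <- fixSpec(6)
  img <- fixImage(1, specs = list(sp), noise = FALSE)
  cl <- fixAxisCenterline(sp, from = -0.4, to = 19.6)
  lp <- longitudinalProfile(zdiscChannel(img), cl, pixelSize(img))
  pk <- detectPeaks(lp, minProminenceFrac = 0.5)
  expect_equal(nrow(pk), 7)
})

test_that("widening the ROI on a transversely uniform ribbon changes nothing", {
  img <- matrix(0, 120, 300)
  img[40:80, ] <- 5
  cl <- centerlineFromPolyline(rbind(c(2, 3), c(12, 3)))
  a <- longitudinalProfile(img, cl, 0.05, halfWidth = 0.3)
  b <- longitudinalProfile(img, cl, 0.05, halfWidth = 0.6)
  expect_equal(intensities(a), intensities(b), tolerance = 1e-3)
})

test_that("transverse profile of a centred fibril is even and peaks at zero", {
  sp <- fixSpec()
  img <- fixImage(2, specs = list(sp), noise = FALSE)
  cl <- fixAxisCenterline(sp, from = 0.5, to = 18.7)
  tp <- transverseProfile(phalloidinChannel(img), cl, 4, pixelSize(img))
  v <- intensities(tp)
  x <- positions(tp)
  expect_lt(max(abs(v - rev(v))), 0.02 * max(v))
  expect_lt(abs(x[which.max(v)]), pixelSize(img))
})

test_that("background-only positions return background", {
  img <- matrix(3, 200, 200)
  cl <- centerlineFromPolyline(rbind(c(3, 5), c(7, 5)))
  tp <- transverseProfile(img, cl, 2, 0.05)
  expect_equal(range(intensities(tp)), c(3, 3))
})

test_that("profiles are translation invariant for integer-pixel shifts", {
  sp <- fixSpec()
  img <- fixImage(3, specs = list(sp), noise = FALSE)
  ph <- phalloidinChannel(img)
  shift <- 8L                           # pixels
  ph2 <- matrix(0, nrow(ph), ncol(ph))
  ph2[, (shift + 1):ncol(ph)] <- ph[, 1:(ncol(ph) - shift)]
  cl1 <- fixAxisCenterline(sp, from = 1, to = 18)
  sp2 <- sp
  sp2@origin <- sp@origin + c(shift * 0.05, 0)
  cl2 <- fixAxisCenterline(sp2, from = 1, to = 18)
  a <- longitudinalProfile(ph, cl1, 0.05)
  b <- longitudinalProfile(ph2, cl2, 0.05)
  expect_lt(max(abs(intensities(a) - intensities(b))) /
              diff(range(intensities(a))), 0.01)
})

test_that("sampling outside the image raises OutOfBounds", {
  img <- matrix(1, 50, 50)
  cl <- centerlineFromPolyline(rbind(c(0.5, 1), c(2, 1)))
  expect_error(transverseProfile(img, cl, 1, 0.05, halfLength = 2),
               class = "OutOfBounds")
})

test_that("profiles round-trip through CSV export", {
  p <- IntensityProfile(seq(0, 2, by = 0.05), sin(seq(0, 4, length.out = 41)) + 2)
  f <- tempfile(fileext = ".csv")
  writeProfileCSV(p, f)
  d <- read.csv(f)
  expect_equal(d$position_um, positions(p))
  expect_equal(d$intensity, intensities(p))
  unlink(f)
})
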