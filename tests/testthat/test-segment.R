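# Segmentation, QC flags and centerline extraction.

test_that("projection keeps a 2D stack and collapses a 3D one", {
  img <- fixImage(1, noise = FALSE)
  st <- asStack(img)
  expect_equal(phalloidinChannel(projectStack(st)), phalloidinChannel(st))
  ph <- phalloidinChannel(img)
  zd <- zdiscChannel(img)
  cube <- array(0, c(dim(ph), 3))
  cube[, , 2] <- ph
  st3 <- ImageStack(cube, array(rep(zd, 3), c(dim(zd), 3)), pixelSize(img))
  expect_equal(phalloidinChannel(projectStack(st3)), ph)
  # defocused copies never exceed the in-focus peak
  blur <- fibrilMorph:::.convolveReflect(ph, airyPSF(fixImaging(), 10))
  cube[, , 1] <- blur
  cube[, , 3] <- blur
  st3b <- ImageStack(cube, array(rep(zd, 3), c(dim(zd), 3)), pixelSize(img))
  expect_equal(max(phalloidinChannel(projectStack(st3b))), max(ph))
})

test_that("one clean fibril gives exactly one unflagged mask", {
  img <- fixImage(2)
  masks <- segmentMyofibrils(phalloidinChannel(img), pixelSize(img))
  expect_length(masks, 1)
  expect_false(any(qcFlags(masks[[1]])))
})

test_that("two well-separated parallel fibrils give two unflagged masks", {
  specs <- list(fixSpec(origin = c(2, 2)), fixSpec(origin = c(2, 5)))
  img <- fixImage(3, specs = specs)
  masks <- segmentMyofibrils(phalloidinChannel(img), pixelSize(img))
  expect_length(masks, 2)
  expect_false(any(vapply(masks, function(m) any(qcFlags(m)), logical(1))))
})

test_that("crossing fibrils are flagged as branched", {
  specs <- list(fixSpec(origin = c(2, 3.5)),
                MyofibrilSpec(6, 3.2, 1.5, origin = c(3, 1),
                              orientation = 25))
  img <- fixImage(4, specs = specs, canvas = c(240, 480))
  masks <- segmentMyofibrils(phalloidinChannel(img), pixelSize(img))
  expect_true(any(vapply(masks, function(m)
    qcFlags(m)[["branched_skeleton"]], logical(1))))
})

test_that("segmentation is idempotent on an isolated fibril", {
  img <- fixImage(5)
  masks <- segmentMyofibrils(phalloidinChannel(img), pixelSize(img))
  cut <- phalloidinChannel(img)
  cut[!masks[[1]]@mask] <- 0
  again <- segmentMyofibrils(cut, pixelSize(img))
  expect_length(again, 1)
  ov <- sum(again[[1]]@mask & masks[[1]]@mask) / sum(masks[[1]]@mask)
  expect_gt(ov, 0.95)
})

test_that("nothing segmentable raises NothingSegmented", {
  flat <- matrix(10, 60, 60)
  flat[30, 30] <- 11
  expect_error(segmentMyofibrils(flat, 0.05), class = "NothingSegmented")
})

test_that("centerline of a straight fibril lies on the true axis", {
  img <- fixImage(6, noise = FALSE)
  masks <- segmentMyofibrils(phalloidinChannel(img), pixelSize(img))
  cl <- fitCenterline(masks[[1]], pixelSize(img))
  expect_lt(max(abs(cl@points[, 2] - 3)), 0.5 * pixelSize(img))
  # unit, orthogonal frame
  expect_equal(sqrt(rowSums(cl@tangent^2)), rep(1, nrow(cl@tangent)))
  expect_equal(rowSums(cl@tangent * cl@normal), rep(0, nrow(cl@tangent)),
               tolerance = 1e-9)
})

test_that("arclength of a quarter-circle arc is recovered within 1%", {
  Ltrue <- pi * 20 / 2
  sp <- MyofibrilSpec(10, Ltrue / 10, 1.5, origin = c(2, 3),
                      curvature = 1 / 20)
  im <- ImagingSpec(pixelSize = 0.1, rngSeed = 1)
  gt <- renderGroundTruth(list(sp), im, c(250, 250))
  masks <- segmentMyofibrils(phalloidinChannel(gt), 0.1)
  cl <- fitCenterline(masks[[1]], 0.1, trimUm = 0)
  expect_equal(max(arclength(cl)), Ltrue, tolerance = 0.01)
})

test_that("rotating the image by 90 degrees preserves arclength", {
  img <- fixImage(7, canvas = c(480, 480))
  ph <- phalloidinChannel(img)
  N <- nrow(ph)
  rot <- t(ph[N:1, ])
  len <- function(m) {
    masks <- segmentMyofibrils(m, pixelSize(img))
    max(arclength(fitCenterline(masks[[1]], pixelSize(img))))
  }
  expect_equal(len(ph), len(rot), tolerance = 0.005)
})

test_that("centerline arclength dominates the endpoint chord", {
  Ltrue <- pi * 20 / 2
  sp <- MyofibrilSpec(10, Ltrue / 10, 1.5, origin = c(2, 3),
                      curvature = 1 / 20)
  im <- ImagingSpec(pixelSize = 0.1, rngSeed = 1)
  gt <- renderGroundTruth(list(sp), im, c(250, 250))
  masks <- segmentMyofibrils(phalloidinChannel(gt), 0.1)
  cl <- fitCenterline(masks[[1]], 0.1)
  chord <- sqrt(sum((cl@points[nrow(cl@points), ] - cl@points[1, ])^2))
  expect_gte(max(arclength(cl)), chord)
})

test_that("flagged masks are rejected unless overridden", {
  img <- fixImage(8)
  masks <- segmentMyofibrils(phalloidinChannel(img), pixelSize(img))
  m <- masks[[1]]
  m@qcFlags["branched_skeleton"] <- TRUE
  expect_error(fitCenterline(m, pixelSize(img)), class = "BranchedSkeleton")
})

test_that("manual polylines become valid centerlines", {
  cl <- centerlineFromPolyline(rbind(c(0, 0), c(5, 0), c(10, 2)))
  expect_s4_class(cl, "Centerline")
  expect_gt(max(arclength(cl)), sqrt(10^2 + 2^2) - 0.2)
  expect_true(all(diff(arclength(cl)) > 0))
})
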