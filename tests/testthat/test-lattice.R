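# Hexagonal lattice geometry, derived quantities and 3D sarcomere models.

test_that("degenerate and minimal lattices behave", {
  expect_error(buildHexLattice(0), class = "InvalidCount")
  one <- buildHexLattice(1, 47)
  expect_equal(nrow(thickPositions(one)), 1)
  expect_equal(nrow(thinPositions(one)), 0)
  expect_error(interiorThinPerThick(buildHexLattice(2, 47)),
               class = "NoInteriorSites")
})

test_that("the 7-site lattice has 12 thin sites and a 3.0 interior ratio", {
  lat <- buildHexLattice(7, 47)
  expect_equal(nrow(thickPositions(lat)), 7)
  expect_equal(nrow(thinPositions(lat)), 12)    # 6 spokes + 6 ring edges
  expect_equal(sum(lat@interior), 1)
  expect_equal(interiorThinPerThick(lat), 3)
  expect_equal(thinNeighbours(lat, which(lat@interior)), 6)
  expect_error(thinNeighbours(lat, which(!lat@interior)[1]),
               class = "NotInterior")
})

test_that("minimum thick-thick distance equals the spacing exactly", {
  for (n in c(7, 32, 134)) {
    lat <- buildHexLattice(n, 46.5)
    d <- stats::dist(thickPositions(lat))
    expect_equal(min(d), 46.5, tolerance = 1e-9)
    # no duplicate positions anywhere
    all <- rbind(thickPositions(lat), thinPositions(lat))
    expect_equal(nrow(unique(round(all, 6))), nrow(all))
  }
})

test_that("every interior site of a large lattice sees 6 thin neighbours", {
  lat <- buildHexLattice(169, 48)
  ints <- which(lat@interior)
  expect_gt(length(ints), 50)
  expect_true(all(vapply(ints, function(i) thinNeighbours(lat, i),
                         numeric(1)) == 6))
  expect_equal(interiorThinPerThick(lat), 3)
})

test_that("bulk thin/thick ratio approaches 3 from below", {
  ns <- c(19, 37, 169, 469)
  ratios <- vapply(ns, function(n) {
    lat <- buildHexLattice(n, 47)
    nrow(thinPositions(lat)) / nrow(thickPositions(lat))
  }, numeric(1))
  expect_true(all(ratios < 3))
  expect_true(all(diff(ratios) > 0))
  expect_gt(ratios[length(ratios)], 2.8)
})

test_that("equivalent diameter matches the hexagonal-cell formula", {
  expect_equal(equivalentDiameter(846, 48), 1.47, tolerance = 0.005)
  expect_equal(equivalentDiameter(0, 48), 0)
  expect_equal(equivalentDiameter(100, 96) / equivalentDiameter(100, 48), 2)
  # strictly increasing in both arguments
  expect_gt(equivalentDiameter(101, 48), equivalentDiameter(100, 48))
  expect_gt(equivalentDiameter(100, 49), equivalentDiameter(100, 48))
})

test_that("incorporation times follow the count increments", {
  expect_equal(incorporationTime(32, 134, 24), 60 * 24 / 102)
  expect_equal(incorporationTime(23, 32, 12), 80)
  expect_error(incorporationTime(32, 32, 24), class = "NonPositiveGrowth")
})

test_that("the mature 3D model reproduces its generating band widths", {
  st <- getStage("24h AE")
  m <- build3dSarcomere(st)
  w <- remeasureBandWidths(m)
  expect_equal(unname(w["wIBand"]), st@wIBand)
  expect_equal(unname(w["wHZone"]), st@wHZone)
  expect_equal(unname(w["wZDisc"]), st@wZDisc)
  # derived landmarks: thin pointed end at L/2 - W_H/2, thick tip gap W_I/2
  f <- filamentSpans(m)
  thin <- f[f$type == "thin" & f$zStart < st@lSarcomere / 2, ]
  expect_equal(max(thin$zEnd), st@lSarcomere / 2 - st@wHZone / 2)
  thick <- f[f$type == "thick", ]
  expect_equal(min(thick$zStart), st@wIBand / 2)
})

test_that("every stage model is mirror-symmetric about the M-line", {
  for (s in stageTable()$stage) {
    st <- getStage(s)
    m <- build3dSarcomere(st)
    f <- filamentSpans(m)
    mirrored <- data.frame(type = f$type, x = f$x, y = f$y,
                           zStart = m@lSarcomere - f$zEnd,
                           zEnd = m@lSarcomere - f$zStart)
    key <- function(d) sort(sprintf("%s|%.6f|%.6f|%.6f|%.6f",
                                    d$type, d$x, d$y, d$zStart, d$zEnd))
    expect_equal(key(mirrored), key(f))
    w <- remeasureBandWidths(m)
    expect_equal(unname(w), c(st@wIBand, st@wHZone, st@wZDisc))
  }
})

test_that("3D models export to spans CSV and OBJ", {
  m <- build3dSarcomere(getStage("48h APF"))
  csv <- tempfile(fileext = ".csv")
  obj <- tempfile(fileext = ".obj")
  exportSpans(m, csv)
  back <- read.csv(csv)
  expect_equal(nrow(back), nrow(filamentSpans(m)))
  exportOBJ(m, obj)
  lines <- readLines(obj)
  expect_equal(sum(grepl("^v ", lines)), 12 * nrow(filamentSpans(m)))
  unlink(c(csv, obj))
})
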