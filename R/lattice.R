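# Hexagonal myofilament lattice and scaled 3D sarcomere models.

#' Build a hexagonal thick-filament lattice with midpoint thin filaments
#'
#' Thick filaments occupy a triangular lattice filled in concentric
#' hexagonal rings from the centre; a partially filled outer ring is filled
#' in angular order (counter-clockwise from angle 0).  Thin filaments sit
#' at the midpoint of every nearest-neighbour thick pair -- the MyAc-layer
#' arrangement -- so the 1:3 thick-to-thin bulk ratio emerges from the
#' geometry instead of being imposed.
#'
#' @param nThick number of thick filaments (>= 1).
#' @param spacing nearest-neighbour centre-to-centre distance d in
#'   nanometres.
#' @return a \code{\link{LatticeModel}}.
#' @examples
#' buildHexLattice(7, 47)   # 7 thick, 12 thin
#' @export
buildHexLattice <- function(nThick, spacing = 47) {
  nThick <- as.integer(nThick)
  if (nThick < 1L) .condition("nThick must be >= 1", "InvalidCount")
  stopifnot(spacing > 0)
  # enough rings: ring k holds 6k sites, total 1 + 3k(k+1)
  kmax <- 0L
  while (1 + 3 * kmax * (kmax + 1) < nThick) kmax <- kmax + 1L
  # axial coordinates (i, j) -> cartesian; hex ring index (|i|+|j|+|i+j|)/2
  ij <- expand.grid(i = -kmax:kmax, j = -kmax:kmax)
  ring <- (abs(ij$i) + abs(ij$j) + abs(ij$i + ij$j)) / 2
  ij <- ij[ring <= kmax, ]
  ring <- ring[ring <= kmax]
  x <- spacing * (ij$i + ij$j / 2)
  y <- spacing * (ij$j * sqrt(3) / 2)
  ang <- atan2(y, x) %% (2 * pi)
  ord <- order(ring, ang, ij$i)
  sel <- ord[seq_len(nThick)]
  thick <- cbind(x = x[sel], y = y[sel])
  # nearest-neighbour pairs (distance d) and their midpoints
  dm <- as.matrix(stats::dist(thick))
  nb <- dm < spacing * (1 + 1e-9) & dm > 0
  thin <- NULL
  if (nThick >= 2) {
    pairs <- which(nb & upper.tri(nb), arr.ind = TRUE)
    if (nrow(pairs) > 0)
      thin <- (thick[pairs[, 1], , drop = FALSE] +
               thick[pairs[, 2], , drop = FALSE]) / 2
  }
  if (is.null(thin)) thin <- matrix(numeric(0), 0, 2,
                                    dimnames = list(NULL, c("x", "y")))
  interior <- rowSums(nb) == 6
  new("LatticeModel", thick = thick, thin = thin, spacing = spacing,
      interior = interior)
}

#' Interior thin-to-thick filament ratio
#'
#' For every interior thick filament (6 thick neighbours) the 6 adjacent
#' thin sites are counted with weight 1/2 each, since each thin filament is
#' shared by exactly two thick filaments in the MyAc layer.  The mean over
#' interior sites is 3 for any lattice with at least one interior site --
#' the 1:3 thick-to-thin ratio of the flight-muscle lattice.
#'
#' @param lat a \code{\link{LatticeModel}}.
#' @return numeric, thin filaments per thick filament.
#' @examples
#' interiorThinPerThick(buildHexLattice(7))
#' @export
interiorThinPerThick <- function(lat) {
  sites <- which(lat@interior)
  if (length(sites) == 0)
    .condition("lattice has no interior thick site", "NoInteriorSites")
  mean(vapply(sites, function(i) thinNeighbours(lat, i) / 2, numeric(1)))
}

#' Number of thin filaments adjacent to an interior thick filament
#'
#' Counts thin sites at distance d/2 from the given thick site; 6 for
#' every interior site of the hexagonal MyAc lattice (the unit of lateral
#' growth: one thick filament comes with six thin filaments).
#'
#' @param lat a \code{\link{LatticeModel}}.
#' @param site index of a thick site.
#' @return integer count.
#' @export
thinNeighbours <- function(lat, site) {
  stopifnot(site >= 1, site <= nrow(lat@thick))
  if (!lat@interior[site])
    .condition("site is not interior (fewer than 6 thick neighbours)",
               "NotInterior")
  p <- lat@thick[site, ]
  d <- sqrt((lat@thin[, 1] - p[1])^2 + (lat@thin[, 2] - p[2])^2)
  sum(abs(d - lat@spacing / 2) < lat@spacing * 1e-9)
}

#' Area-equivalent myofibril diameter of a hexagonally packed lattice
#'
#' Each thick filament occupies a hexagonal unit cell of area
#' \eqn{(\sqrt 3/2) d^2}; the diameter of the circle of equal total area is
#' \deqn{D_{eq} = 2 \sqrt{n_{thick} (\sqrt 3 / 2) d^2 / \pi}.}
#'
#' @param nThick thick-filament count (>= 0).
#' @param spacing lattice spacing d in nanometres.
#' @return equivalent diameter in micrometres.
#' @examples
#' equivalentDiameter(846, 48)  # ~1.47
#' @export
equivalentDiameter <- function(nThick, spacing) {
  stopifnot(nThick >= 0, spacing > 0)
  2 * sqrt(nThick * (sqrt(3) / 2) * spacing^2 / pi) / 1000
}

#' Mean filament incorporation time between two stages
#'
#' Given mean thick-filament counts n1 < n2 at stages separated by
#' \code{deltaTHours}, returns the average time to incorporate one thick
#' filament (equivalently, six thin filaments) in minutes.
#'
#' @param n1,n2 thick-filament counts at the earlier/later stage.
#' @param deltaTHours time between the stages in hours.
#' @return minutes per thick filament.
#' @examples
#' incorporationTime(32, 134, 24)  # ~14.1 min between 48 h and 72 h APF
#' @export
incorporationTime <- function(n1, n2, deltaTHours) {
  if (n2 <= n1 || deltaTHours <= 0)
    .condition("counts must grow over a positive interval",
               "NonPositiveGrowth")
  60 * deltaTHours / (n2 - n1)
}

#' Scaled 3D sarcomere model from stage morphometrics
#'
#' Places the hexagonal lattice of \code{nThick} thick filaments with thin
#' filaments at bond midpoints, and assigns axial spans: thick filaments of
#' length \code{lThick} centred on the M-line; at every thin site two thin
#' filaments, one anchored at each Z-line, overhanging it by half the
#' Z-disc overlap and pointing toward the M-line (mirror-symmetric in the
#' two half-sarcomeres).  By construction, the re-measured I-band, H-zone
#' and Z-disc widths reproduce the inputs exactly.
#'
#' @param stage a \code{\link{StageMorphometrics}}.
#' @param spacing lattice spacing in nanometres; defaults to the stage's.
#' @return a \code{\link{Sarcomere3DModel}}.
#' @examples
#' build3dSarcomere(getStage("24h AE"))
#' @export
build3dSarcomere <- function(stage, spacing = NULL) {
  validObject(stage)
  if (is.null(spacing)) spacing <- stage@spacing
  Ls <- stage@lSarcomere
  if (stage@lThin > Ls / 2 + stage@wZDisc / 2)
    .condition("thin filaments longer than half-sarcomere plus overlap",
               "GeometryError")
  lat <- buildHexLattice(stage@nThick, spacing)
  m <- Ls / 2
  thickSpan <- c(m - stage@lThick / 2, m + stage@lThick / 2)
  if (thickSpan[1] >= thickSpan[2] || thickSpan[1] < 0)
    .condition("thick filament span inverted or outside sarcomere",
               "GeometryError")
  thinA <- c(-stage@wZDisc / 2, stage@lThin - stage@wZDisc / 2)   # from Z at 0
  thinB <- c(Ls - stage@lThin + stage@wZDisc / 2, Ls + stage@wZDisc / 2)
  if (thinA[1] >= thinA[2]) .condition("thin filament span inverted",
                                       "GeometryError")
  nthick <- nrow(lat@thick)
  nthin <- nrow(lat@thin)
  filaments <- rbind(
    data.frame(type = "thick", x = lat@thick[, 1], y = lat@thick[, 2],
               zStart = thickSpan[1], zEnd = thickSpan[2]),
    if (nthin > 0) data.frame(type = "thin", x = lat@thin[, 1],
                              y = lat@thin[, 2],
                              zStart = thinA[1], zEnd = thinA[2]),
    if (nthin > 0) data.frame(type = "thin", x = lat@thin[, 1],
                              y = lat@thin[, 2],
                              zStart = thinB[1], zEnd = thinB[2]))
  new("Sarcomere3DModel", filaments = filaments, lSarcomere = Ls,
      stage = stage, lattice = lat)
}

#' Re-measure band widths from a 3D sarcomere model
#'
#' Inverts the model geometry: the I-band width is twice the gap between
#' thick-filament tips and the nearest Z-line, the H-zone width twice the
#' minimum distance of thin pointed ends to the M-line, and the Z-disc
#' width twice the thin-filament overhang beyond the Z-line.
#'
#' @param model a \code{\link{Sarcomere3DModel}}.
#' @return named numeric: \code{wIBand}, \code{wHZone}, \code{wZDisc}
#'   (micrometres).
#' @export
remeasureBandWidths <- function(model) {
  f <- model@filaments
  Ls <- model@lSarcomere
  m <- Ls / 2
  thick <- f[f$type == "thick", ]
  thin <- f[f$type == "thin", ]
  wI <- 2 * min(thick$zStart - 0)
  # pointed ends: the span end closest to the M-line for each anchored set
  pointedA <- thin$zEnd[thin$zStart < m]     # anchored at Z = 0
  pointedB <- thin$zStart[thin$zEnd > m]     # anchored at Z = Ls
  wH <- 2 * min(abs(c(pointedA, pointedB) - m))
  wZ <- 2 * max(0 - min(thin$zStart), max(thin$zEnd) - Ls)
  c(wIBand = wI, wHZone = wH, wZDisc = wZ)
}

#' Export a 3D sarcomere model
#'
#' \code{exportSpans} writes the exact filament spans as CSV;
#' \code{exportOBJ} writes a display-only Wavefront OBJ with filaments as
#' cylinders (thick radius 8 nm, thin radius 4 nm, hexagonal cross-section
#' for compactness).
#'
#' @param model a \code{\link{Sarcomere3DModel}}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
exportSpans <- function(model, path) {
  utils::write.csv(model@filaments, path, row.names = FALSE)
  invisible(path)
}

#' @rdname exportSpans
#' @export
exportOBJ <- function(model, path) {
  f <- model@filaments
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# scaled sarcomere model: filament cylinders (nm / um axis)", con)
  vcount <- 0L
  nsides <- 6L
  ang <- seq(0, 2 * pi, length.out = nsides + 1)[-(nsides + 1)]
  for (i in seq_len(nrow(f))) {
    r <- if (f$type[i] == "thick") 8 else 4
    # axis z in nm for a uniform coordinate system
    z0 <- f$zStart[i] * 1000
    z1 <- f$zEnd[i] * 1000
    vx <- f$x[i] + r * cos(ang)
    vy <- f$y[i] + r * sin(ang)
    for (z in c(z0, z1))
      for (k in seq_len(nsides))
        writeLines(sprintf("v %.3f %.3f %.3f", vx[k], vy[k], z), con)
    for (k in seq_len(nsides)) {
      k2 <- k %% nsides + 1L
      writeLines(sprintf("f %d %d %d %d", vcount + k, vcount + k2,
                         vcount + nsides + k2, vcount + nsides + k), con)
    }
    vcount <- vcount + 2L * nsides
  }
  invisible(path)
}
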