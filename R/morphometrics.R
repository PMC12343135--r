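# Filament lengths from band widths, stage parameter tables, and
# superplot-style hierarchical summaries.

#' Thick filament length from sarcomere length and I-band width
#'
#' Thick filaments span the A-band; the I-band (thin filaments only)
#' contributes half its width on each side of the sarcomere, so
#' \deqn{L_{thick} = L_{sarcomere} - 2\,(W_{I\mbox{-}band}/2) =
#'   L_{sarcomere} - W_{I\mbox{-}band}.}
#'
#' @param lSarcomere sarcomere length, micrometres.
#' @param wIBand I-band width, micrometres.
#' @return thick filament length in micrometres.
#' @examples
#' thickLength(3.40, 0.16)  # 3.24
#' @export
thickLength <- function(lSarcomere, wIBand) {
  stopifnot(wIBand >= 0)
  if (any(wIBand >= lSarcomere))
    .condition("I-band width must be smaller than sarcomere length",
               "NegativeLength")
  lSarcomere - wIBand
}

#' Thin filament length from sarcomere length, H-zone and Z-disc widths
#'
#' A thin filament runs from its barbed end inside the Z-disc overlap
#' (half the overlap beyond the Z-line) to its pointed end at the H-zone
#' boundary:
#' \deqn{L_{thin} = L_{sarcomere}/2 - W_{H\mbox{-}zone}/2 +
#'   W_{Z\mbox{-}disc}/2.}
#'
#' @param lSarcomere sarcomere length, micrometres.
#' @param wHZone H-zone width, micrometres.
#' @param wZDisc Z-disc overlap width, micrometres.
#' @return thin filament length in micrometres.
#' @examples
#' thinLength(3.40, 0.134, 0.094)  # 1.68
#' @export
thinLength <- function(lSarcomere, wHZone, wZDisc) {
  stopifnot(wHZone >= 0, wZDisc >= 0)
  if (any(wHZone >= lSarcomere))
    .condition("H-zone width must be smaller than sarcomere length",
               "NegativeLength")
  out <- (lSarcomere - wHZone + wZDisc) / 2
  if (any(out <= 0)) .condition("thin filament length is not positive",
                                "NegativeLength")
  out
}

#' Construct per-stage morphometrics
#'
#' Filament lengths are derived from the band widths via
#' \code{\link{thickLength}} and \code{\link{thinLength}}, so the object
#' always satisfies both identities exactly.
#'
#' @param stage character stage label.
#' @param lSarcomere,wIBand,wHZone,wZDisc band geometry in micrometres.
#' @param nThick thick filaments per cross-section.
#' @param spacing thick-filament lattice spacing in nanometres.
#' @return a \code{\link{StageMorphometrics}}.
#' @export
stageMorphometrics <- function(stage, lSarcomere, wIBand, wHZone, wZDisc,
                               nThick, spacing) {
  new("StageMorphometrics", stage = as.character(stage),
      lSarcomere = lSarcomere, wIBand = wIBand, wHZone = wHZone,
      wZDisc = wZDisc,
      lThick = thickLength(lSarcomere, wIBand),
      lThin = thinLength(lSarcomere, wHZone, wZDisc),
      nThick = as.integer(nThick), spacing = spacing)
}

#' Developmental stage parameter table
#'
#' Reads the packaged CSV of flight-muscle stage parameters (36 h APF to
#' 24 h after eclosion): measured thick-filament counts, lattice spacings
#' and Z-disc overlaps, band widths consistent with the measured filament
#' lengths, and representative sarcomere lengths.  See the package vignette
#' for the provenance of each column.
#'
#' @param path optional path to an alternative CSV with the same columns
#'   (\code{stage, L_sarcomere_um, W_I_band_um, W_H_zone_um, W_Z_disc_um,
#'   n_thick, spacing_nm}).
#' @return data.frame, one row per stage.
#' @examples
#' stageTable()
#' @export
stageTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "stage_morphometrics.csv",
                        package = "fibrilMorph", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Look up one stage as a StageMorphometrics object
#'
#' @param stage stage label, e.g. \code{"24h AE"}.
#' @param table optional table from \code{\link{stageTable}}.
#' @return a \code{\link{StageMorphometrics}}.
#' @examples
#' getStage("24h AE")
#' @export
getStage <- function(stage, table = stageTable()) {
  row <- table[table$stage == stage, , drop = FALSE]
  if (nrow(row) != 1)
    stop(sprintf("unknown stage '%s'; available: %s", stage,
                 paste(table$stage, collapse = ", ")))
  stageMorphometrics(row$stage, row$L_sarcomere_um, row$W_I_band_um,
                     row$W_H_zone_um, row$W_Z_disc_um, row$n_thick,
                     row$spacing_nm)
}

#' Superplot-style hierarchical summary
#'
#' Aggregates raw measurements hierarchically: per-myofibril means, then
#' per-experiment means of the myofibril means, then the grand mean across
#' experiments.  The grand mean is the mean of experiment means -- not the
#' pooled mean -- so unbalanced experiments do not dominate.  With a single
#' experiment the between-experiment sd is undefined and reported as 0 with
#' \code{singleExperiment = TRUE}.
#'
#' @param rows data.frame with columns \code{experiment}, \code{myofibril}
#'   and one or more numeric measurement columns (e.g.
#'   \code{sarcomere_length_um}, \code{diameter_um}).
#' @return a \code{\link{MeasurementTable}}.
#' @examples
#' rows <- data.frame(experiment = c(1, 1, 2, 2), myofibril = c(1, 2, 1, 2),
#'                    sarcomere_length_um = c(3.0, 3.0, 3.4, 3.4))
#' summarizeMeasurements(rows)
#' @export
summarizeMeasurements <- function(rows) {
  if (!is.data.frame(rows) || nrow(rows) < 1)
    .condition("no measurement rows", "EmptyInput")
  stopifnot(all(c("experiment", "myofibril") %in% names(rows)))
  vars <- setdiff(names(rows), c("experiment", "myofibril"))
  vars <- vars[vapply(rows[vars], is.numeric, logical(1))]
  if (length(vars) == 0) .condition("no numeric measurement columns", "EmptyInput")
  agg <- function(d, by) stats::aggregate(d[vars], by = by, FUN = mean,
                                          na.rm = TRUE)
  myo <- agg(rows, list(experiment = rows$experiment,
                        myofibril = rows$myofibril))
  expm <- agg(myo, list(experiment = myo$experiment))
  gm <- vapply(vars, function(v) mean(expm[[v]]), numeric(1))
  single <- nrow(expm) < 2
  gs <- vapply(vars, function(v) if (single) 0 else stats::sd(expm[[v]]),
               numeric(1))
  new("MeasurementTable", rows = rows, myofibrilMeans = myo,
      experimentMeans = expm, grandMean = gm, grandSD = gs,
      nLabel = sprintf("%d/%d", nrow(expm), nrow(rows)),
      singleExperiment = single)
}
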