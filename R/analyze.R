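# End-to-end automatic analysis: project -> segment -> centerline ->
# profiles -> model fits -> superplot summary.

#' Analyse one two-channel stack
#'
#' Runs the full automatic pipeline on an \code{\link{ImageStack}}:
#' maximum-intensity projection, myofibril segmentation with QC, spline
#' centerlines, multi-Gaussian sarcomere-length fitting on the Z-disc
#' channel and disc-model diameter fitting on the phalloidin channel.
#' QC-flagged or failing myofibrils are skipped and logged with a reason
#' code.  The result is deterministic given the inputs and configuration.
#'
#' In manual mode, supply \code{polylines}: a list of n x 2 matrices of
#' (x, y) vertices in micrometres, one per myofibril; segmentation is
#' skipped.
#'
#' @param stack an \code{\link{ImageStack}}.
#' @param config an \code{\link{AnalysisConfig}}.
#' @param experiment,image identifiers copied into the output rows.
#' @param polylines manual-mode centerline polylines.
#' @return list with elements \code{measurements} (data.frame, one row per
#'   sarcomere and per diameter position), \code{fibrils} (per-fibril
#'   summary), \code{log} (data.frame of QC events).
#' @export
analyzeStack <- function(stack, config = analysisConfig(),
                         experiment = "exp1", image = "img1",
                         polylines = NULL) {
  cfg <- config@values
  proj <- projectStack(stack)
  phal <- phalloidinChannel(proj)
  zd <- zdiscChannel(proj)
  px <- pixelSize(stack)
  logs <- list()
  note <- function(fibril, stage, reason)
    logs[[length(logs) + 1L]] <<- data.frame(
      image = image, fibril = fibril, stage = stage, reason = reason)
  centerlines <- list()
  if (identical(cfg$mode, "manual")) {
    if (is.null(polylines)) stop("manual mode requires polylines")
    for (i in seq_along(polylines))
      centerlines[[as.character(i)]] <-
        centerlineFromPolyline(polylines[[i]], step = cfg$centerline_step_um)
  } else {
    masks <- segmentMyofibrils(phal, px, minLengthUm = cfg$min_length_um,
                               thresholdMethod = cfg$threshold_method,
                               threshold = cfg$threshold)
    for (m in masks) {
      id <- as.character(m@label)
      if (any(m@qcFlags)) {
        note(id, "segment", paste(names(which(m@qcFlags)), collapse = "+"))
        next
      }
      cl <- tryCatch(
        fitCenterline(m, px, step = cfg$centerline_step_um,
                      minLengthUm = cfg$min_length_um),
        fibrilMorphError = function(e) {
          note(id, "centerline", conditionMessage(e)); NULL
        })
      if (!is.null(cl)) centerlines[[id]] <- cl
    }
  }
  rows <- list()
  fib <- list()
  for (id in names(centerlines)) {
    cl <- centerlines[[id]]
    res <- tryCatch({
      lp <- longitudinalProfile(zd, cl, px,
                                halfWidth = cfg$longitudinal_half_width_um)
      g <- fitGaussianPeaks(lp, minProminenceFrac = cfg$prominence_frac)
      sl <- sarcomereLengths(g, excludeTerminal = cfg$exclude_terminal)
      dm <- measureDiameter(phal, cl, px, nPositions = cfg$n_transverse,
                            halfLength = cfg$transverse_half_length_um,
                            psfSigmaInit = cfg$psf_sigma_init_um)
      list(sl = sl, dm = dm, g = g)
    }, fibrilMorphError = function(e) {
      note(id, "fit", conditionMessage(e)); NULL
    })
    if (is.null(res)) next
    rows[[id]] <- data.frame(
      experiment = experiment, image = image, myofibril = id,
      sarcomere = seq_along(res$sl@distances),
      sarcomere_length_um = res$sl@distances,
      diameter_um = res$dm$diameter)
    fib[[id]] <- data.frame(
      experiment = experiment, image = image, myofibril = id,
      n_sarcomeres = length(res$sl@distances),
      mean_sarcomere_length_um = res$sl@mean,
      sd_sarcomere_length_um = res$sl@sd,
      diameter_um = res$dm$diameter,
      gaussian_rms = res$g@residualRMS)
  }
  if (length(rows) == 0)
    .condition("no analysable myofibril in the stack", "NothingSegmented")
  list(measurements = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       fibrils = do.call(rbind, c(fib, list(make.row.names = FALSE))),
       log = if (length(logs)) do.call(rbind, logs) else
         data.frame(image = character(0), fibril = character(0),
                    stage = character(0), reason = character(0)))
}

#' Analyse a batch of OME-TIFF files
#'
#' Thin wrapper over \code{\link{loadStack}} and \code{\link{analyzeStack}}
#' producing pooled measurement rows, a superplot summary and the combined
#' QC log.  Used by the command-line interface.
#'
#' @param paths character vector of TIFF paths.
#' @param config an \code{\link{AnalysisConfig}}.
#' @param experiment experiment identifier for all files.
#' @param pixelSizeOverride forwarded to \code{\link{loadStack}}.
#' @return list with \code{measurements}, \code{fibrils}, \code{summary}
#'   (a \code{\link{MeasurementTable}}) and \code{log}.
#' @export
analyzeFiles <- function(paths, config = analysisConfig(),
                         experiment = "exp1", pixelSizeOverride = NULL) {
  out <- lapply(paths, function(p) {
    stack <- loadStack(p, pixelSizeOverride)
    analyzeStack(stack, config, experiment = experiment,
                 image = basename(p))
  })
  meas <- do.call(rbind, lapply(out, `[[`, "measurements"))
  fib <- do.call(rbind, lapply(out, `[[`, "fibrils"))
  logd <- do.call(rbind, lapply(out, `[[`, "log"))
  meas$myofibril <- paste(meas$image, meas$myofibril, sep = ":")
  list(measurements = meas, fibrils = fib,
       summary = summarizeMeasurements(
         meas[, c("experiment", "myofibril", "sarcomere_length_um",
                  "diameter_um")]),
       log = logd)
}
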