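# Myofibril detection and centerline extraction (automatic mode).

#' Maximum-intensity projection of a two-channel stack
#'
#' Collapses a z-stack to a single analysis plane per channel; a 2D input
#' is returned unchanged.
#'
#' @param stack an \code{\link{ImageStack}}.
#' @return an \code{ImageStack} whose channels are 2D.
#' @export
projectStack <- function(stack) {
  proj <- function(x) {
    d <- dim(x)
    if (length(d) == 2L) return(x)
    if (length(d) != 3L || d[3L] < 1L)
      .condition("stack has no z-planes", "EmptyStack")
    apply(x, c(1, 2), max)
  }
  ImageStack(proj(stack@phalloidin), proj(stack@zdisc), stack@pixelSize)
}

# --- binary skeletonization (Zhang-Suen thinning) -------------------------
# No installed package exposes 2D skeletonization, so the classic two-pass
# thinning is implemented here on logical matrices, vectorised via shifts.

.shift <- function(m, dr, dc) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

.thinMask <- function(mask) {
  m <- mask
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      # neighbours clockwise from north (rows grow downward, so north = -1 row)
      p2 <- .shift(m, -1, 0); p3 <- .shift(m, -1, 1); p4 <- .shift(m, 0, 1)
      p5 <- .shift(m, 1, 1);  p6 <- .shift(m, 1, 0);  p7 <- .shift(m, 1, -1)
      p8 <- .shift(m, 0, -1); p9 <- .shift(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (pass == 1) {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

.neighbourCount <- function(m) {
  .shift(m, -1, 0) + .shift(m, -1, 1) + .shift(m, 0, 1) + .shift(m, 1, 1) +
    .shift(m, 1, 0) + .shift(m, 1, -1) + .shift(m, 0, -1) + .shift(m, -1, -1)
}

# Remove terminal spurs of up to `maxLen` pixels (thinning artefacts at the
# rounded fibril caps), without touching genuine branches.
.pruneSpurs <- function(skel, maxLen = 5L) {
  for (i in seq_len(maxLen)) {
    nb <- .neighbourCount(skel)
    ends <- skel & nb == 1
    branch <- skel & nb >= 3
    if (sum(branch) == 0) break        # simple path: keep its endpoints
    # remove endpoints that sit within one step of a branch point chain
    drop <- ends
    if (!any(drop)) break
    skel[drop] <- FALSE
  }
  skel
}

.skeletonEndpoints <- function(skel) {
  nb <- .neighbourCount(skel)
  which(skel & nb == 1, arr.ind = TRUE)
}

# Order the pixels of a simple-path skeleton from one endpoint to the other.
.orderSkeleton <- function(skel) {
  pts <- which(skel, arr.ind = TRUE)
  n <- nrow(pts)
  if (n < 2) .condition("skeleton too short to order", "TooShort")
  ends <- .skeletonEndpoints(skel)
  if (nrow(ends) == 0) .condition("skeleton has no endpoints (loop)", "BranchedSkeleton")
  key <- function(r, c) paste(r, c)
  idx <- new.env(hash = TRUE)
  for (i in seq_len(n)) assign(key(pts[i, 1], pts[i, 2]), i, envir = idx)
  visited <- logical(n)
  path <- integer(n)
  cur <- get(key(ends[1, 1], ends[1, 2]), envir = idx)
  off <- expand.grid(dr = -1:1, dc = -1:1)
  off <- off[!(off$dr == 0 & off$dc == 0), ]
  # orthogonal steps first so staircases are traversed without skips
  off <- off[order(abs(off$dr) + abs(off$dc)), ]
  for (i in seq_len(n)) {
    path[i] <- cur
    visited[cur] <- TRUE
    r <- pts[cur, 1]; c <- pts[cur, 2]
    nxt <- 0L
    for (j in seq_len(nrow(off))) {
      k <- key(r + off$dr[j], c + off$dc[j])
      if (exists(k, envir = idx, inherits = FALSE)) {
        cand <- get(k, envir = idx)
        if (!visited[cand]) { nxt <- cand; break }
      }
    }
    if (nxt == 0L) {
      if (i < n * 0.9)
        .condition("skeleton is not a simple path", "BranchedSkeleton")
      path <- path[seq_len(i)]
      break
    }
    cur <- nxt
  }
  pts[path, , drop = FALSE]
}

# Principal-axis extent of a pixel coordinate set, in pixels.
.majorAxisExtent <- function(coords) {
  if (nrow(coords) < 2) return(0)
  cc <- scale(coords, scale = FALSE)
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)$vectors[, 1]
  proj <- cc %*% ev
  diff(range(proj))
}

#' Segment myofibrils in a 2D phalloidin image
#'
#' Thresholds the (median-filtered) phalloidin channel, labels connected
#' components, drops components shorter than \code{minLengthUm} along their
#' principal axis, and attaches deterministic QC flags:
#' \code{touches_border}, \code{branched_skeleton} (skeleton with more than
#' two endpoints, e.g. crossing fibrils) and \code{overlaps_neighbour}
#' (within 2 px of another component).  Flagged components are excluded from
#' automatic downstream analysis but still returned.
#'
#' @param image 2D numeric matrix (phalloidin channel), nonnegative.
#' @param pixelSize micrometres per pixel.
#' @param minLengthUm minimum principal-axis length in micrometres.
#' @param thresholdMethod \code{"otsu"} (default) or \code{"fixed"}.
#' @param threshold numeric in (0, 1) on the normalised image when
#'   \code{thresholdMethod = "fixed"}.
#' @param closingUm diameter of the morphological closing element in
#'   micrometres; bridges the dim H-zone gaps so one myofibril stays one
#'   component.  Must stay well below the fibril separation of interest.
#' @return list of \code{\link{MyofibrilMask}}.
#' @export
segmentMyofibrils <- function(image, pixelSize, minLengthUm = 4,
                              thresholdMethod = c("otsu", "fixed"),
                              threshold = NULL, closingUm = 0.6) {
  thresholdMethod <- match.arg(thresholdMethod)
  stopifnot(is.matrix(image), pixelSize > 0)
  if (any(image < 0)) stop("image must be nonnegative")
  rng <- range(image)
  imgn <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
  med <- EBImage::medianFilter(imgn, size = 1)
  th <- if (thresholdMethod == "otsu") EBImage::otsu(EBImage::Image(med)) else threshold
  bw <- med > th
  closePx <- 2L * as.integer(round(closingUm / (2 * pixelSize))) + 1L
  if (closePx >= 3L)
    bw <- EBImage::closing(bw, EBImage::makeBrush(closePx, "disc")) > 0
  lab <- EBImage::bwlabel(bw)
  nlab <- max(lab)
  if (nlab == 0) .condition("no components above threshold", "NothingSegmented")
  keep <- list()
  comps <- lapply(seq_len(nlab), function(l) which(lab == l, arr.ind = TRUE))
  lens <- vapply(comps, .majorAxisExtent, numeric(1)) * pixelSize
  sel <- which(lens >= minLengthUm)
  if (length(sel) == 0) .condition("no component passes minLengthUm", "NothingSegmented")
  # pairwise proximity: dilate each kept component by 2 px
  brush <- EBImage::makeBrush(5, shape = "disc")
  dil <- lapply(sel, function(l) {
    m <- lab == l
    EBImage::dilate(m, brush) > 0
  })
  out <- vector("list", length(sel))
  for (i in seq_along(sel)) {
    l <- sel[i]
    m <- lab == l
    co <- comps[[l]]
    touches <- any(co[, 1] %in% c(1L, nrow(image))) ||
      any(co[, 2] %in% c(1L, ncol(image)))
    skel <- .pruneSpurs(.thinMask(m))
    branched <- nrow(.skeletonEndpoints(skel)) > 2
    overlaps <- FALSE
    for (j in seq_along(sel)) {
      if (j == i) next
      if (any(dil[[i]] & (lab == sel[j]))) { overlaps <- TRUE; break }
    }
    out[[i]] <- new("MyofibrilMask", mask = m, label = as.integer(l),
      area = as.integer(nrow(co)),
      bbox = as.integer(c(range(co[, 1]), range(co[, 2]))),
      qcFlags = c(touches_border = touches, branched_skeleton = branched,
                  overlaps_neighbour = overlaps))
  }
  out
}

#' Fit a smoothing-spline centerline to a segmented myofibril
#'
#' Skeletonizes the mask, orders the skeleton pixels endpoint to endpoint,
#' fits smoothing splines to x and y versus chord length, and resamples the
#' curve at uniform arclength steps.  Endpoints are trimmed by one estimated
#' diameter to avoid cap artefacts.
#'
#' @param mask a \code{\link{MyofibrilMask}}.
#' @param pixelSize micrometres per pixel.
#' @param step arclength resampling step in micrometres.
#' @param df spline degrees of freedom; default scales with fibril length
#'   (about one basis function per 3 micrometres) so straight fixtures are
#'   recovered with sub-pixel residuals while gentle arcs are followed.
#' @param trimUm end trim in micrometres; default one estimated diameter.
#' @param minLengthUm minimum centerline length after trimming.
#' @param override ignore QC flags on the mask.
#' @return a \code{\link{Centerline}}.
#' @export
fitCenterline <- function(mask, pixelSize, step = 0.05, df = NULL,
                          trimUm = NULL, minLengthUm = 4, override = FALSE) {
  if (!override && any(mask@qcFlags))
    .condition(paste("mask is QC-flagged:",
                     paste(names(which(mask@qcFlags)), collapse = ", ")),
               "BranchedSkeleton")
  skel <- .pruneSpurs(.thinMask(mask@mask))
  if (nrow(.skeletonEndpoints(skel)) > 2)
    .condition("skeleton has more than two endpoints", "BranchedSkeleton")
  ord <- .orderSkeleton(skel)
  # pixel (row, col) -> physical (x, y); 0-based indices at pixel centres
  x <- (ord[, 2] - 1) * pixelSize
  y <- (ord[, 1] - 1) * pixelSize
  t <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  total <- t[length(t)]
  if (is.null(trimUm)) trimUm <- mask@area * pixelSize^2 / max(total, pixelSize)
  if (total - 2 * trimUm < minLengthUm)
    .condition("centerline shorter than minLengthUm after trimming", "TooShort")
  if (is.null(df)) df <- max(4, round(total / 3) + 3)
  df <- min(df, length(unique(t)) - 1)
  sx <- stats::smooth.spline(t, x, df = df)
  sy <- stats::smooth.spline(t, y, df = df)
  tt <- seq(0, total, length.out = max(400L, 4L * length(t)))
  xx <- stats::predict(sx, tt)$y
  yy <- stats::predict(sy, tt)$y
  # thinning insets the skeleton from the fibril caps by about one radius;
  # extend both ends along the local tangent while still inside the mask
  ext <- function(xx, yy, head) {
    if (head) { xx <- rev(xx); yy <- rev(yy) }
    n <- length(xx)
    dx <- xx[n] - xx[n - 5]; dy <- yy[n] - yy[n - 5]
    nm <- sqrt(dx^2 + dy^2)
    if (nm > 0) {
      stp <- pixelSize / 2
      for (i in seq_len(200)) {
        nx <- xx[length(xx)] + stp * dx / nm
        ny <- yy[length(yy)] + stp * dy / nm
        r <- round(ny / pixelSize) + 1
        c <- round(nx / pixelSize) + 1
        if (r < 1 || c < 1 || r > nrow(mask@mask) || c > ncol(mask@mask) ||
            !mask@mask[r, c]) break
        xx <- c(xx, nx); yy <- c(yy, ny)
      }
    }
    if (head) list(x = rev(xx), y = rev(yy)) else list(x = xx, y = yy)
  }
  e <- ext(xx, yy, head = FALSE); xx <- e$x; yy <- e$y
  e <- ext(xx, yy, head = TRUE); xx <- e$x; yy <- e$y
  alen <- c(0, cumsum(sqrt(diff(xx)^2 + diff(yy)^2)))
  lo <- trimUm
  hi <- alen[length(alen)] - trimUm
  s <- seq(lo, hi, by = step)
  px <- stats::approx(alen, xx, xout = s)$y
  py <- stats::approx(alen, yy, xout = s)$y
  .centerlineFromSamples(px, py)
}

# Build a Centerline (arclength, unit tangents/normals) from ordered samples.
.centerlineFromSamples <- function(px, py) {
  n <- length(px)
  stopifnot(n >= 3)
  alen <- c(0, cumsum(sqrt(diff(px)^2 + diff(py)^2)))
  tx <- numeric(n); ty <- numeric(n)
  tx[2:(n - 1)] <- px[3:n] - px[1:(n - 2)]
  ty[2:(n - 1)] <- py[3:n] - py[1:(n - 2)]
  tx[1] <- px[2] - px[1]; ty[1] <- py[2] - py[1]
  tx[n] <- px[n] - px[n - 1]; ty[n] <- py[n] - py[n - 1]
  nrm <- sqrt(tx^2 + ty^2)
  tx <- tx / nrm; ty <- ty / nrm
  new("Centerline", points = cbind(px, py), arclength = alen,
      tangent = cbind(tx, ty), normal = cbind(-ty, tx))
}

#' Build a centerline from a manually drawn polyline
#'
#' Manual-mode counterpart of \code{\link{fitCenterline}}: interpolates a
#' user-supplied polyline (cubic spline through the vertices) and resamples
#' it at uniform arclength steps.  Used for microdissected or sectioned
#' muscle where automatic segmentation is not applicable.
#'
#' @param points n x 2 matrix of (x, y) polyline vertices in micrometres.
#' @param step arclength step in micrometres.
#' @return a \code{\link{Centerline}}.
#' @export
centerlineFromPolyline <- function(points, step = 0.05) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) >= 2)
  t <- c(0, cumsum(sqrt(diff(points[, 1])^2 + diff(points[, 2])^2)))
  tt <- seq(0, t[length(t)], length.out = max(200L, 20L * nrow(points)))
  if (nrow(points) > 2) {
    xx <- stats::spline(t, points[, 1], xout = tt)$y
    yy <- stats::spline(t, points[, 2], xout = tt)$y
  } else {
    xx <- stats::approx(t, points[, 1], xout = tt)$y
    yy <- stats::approx(t, points[, 2], xout = tt)$y
  }
  alen <- c(0, cumsum(sqrt(diff(xx)^2 + diff(yy)^2)))
  s <- seq(0, alen[length(alen)], by = step)
  px <- stats::approx(alen, xx, xout = s)$y
  py <- stats::approx(alen, yy, xout = s)$y
  .centerlineFromSamples(px, py)
}
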