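## Geometry of the peripapillary analysis: magnification correction,
## disc shape indices, PPA morphometry, feature ROIs and ETDRS grids.
## All mm quantities are pixel measurements times the per-case Littmann
## scale; areas scale with its square.

#' Littmann/Bennett magnification model for a case
#'
#' Bennett's axial-length-only adjustment of Littmann's formula gives the
#' ocular magnification factor q = 0.01306 (AL - 1.82). The millimetre
#' extent of one pixel is the camera constant times q, so retinal lengths
#' are pixel lengths times `scale` and areas scale with `scale^2`.
#'
#' @param al axial length in mm; must lie in (15, 40).
#' @param cameraConstant camera factor in mm per pixel per unit q. The
#'   default reproduces a 0.0075 mm/px scale at the cohort-mean axial
#'   length of 25.51 mm on a 1024 px image.
#' @return A [MagnificationModel-class] object.
#' @examples
#' littmannScale(23.82)@q  # 0.28732
#' @export
littmannScale <- function(al, cameraConstant = 0.0075 / (0.01306 * (25.51 - 1.82))) {
  if (!is.finite(al) || al <= 15 || al >= 40)
    stop("axial length out of the supported range (15, 40) mm: ", al)
  if (!is.finite(cameraConstant) || cameraConstant <= 0)
    stop("cameraConstant must be positive")
  q <- 0.01306 * (al - 1.82)
  new("MagnificationModel", al = al, cameraConstant = cameraConstant,
      q = q, scale = cameraConstant * q)
}

## Signed area, centroid and central second moments of a closed polygon
## (shoelace / Green's theorem). Input: n x 2 matrix, implicitly closed.
.polygonMoments <- function(p) {
  n <- nrow(p)
  if (n >= 2 && all(p[1, ] == p[n, ])) { p <- p[-n, , drop = FALSE]; n <- n - 1 }
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  A <- sum(cr) / 2
  if (abs(A) < .Machine$double.eps * 100)
    stop("degenerate contour: zero area")
  cx <- sum((x + x2) * cr) / (6 * A)
  cy <- sum((y + y2) * cr) / (6 * A)
  sxx <- sum((x^2 + x * x2 + x2^2) * cr) / 12
  syy <- sum((y^2 + y * y2 + y2^2) * cr) / 12
  sxy <- sum((x * y2 + 2 * x * y + 2 * x2 * y2 + x2 * y) * cr) / 24
  ## uniform-density covariance about the centroid
  cov <- matrix(c(sxx / A - cx^2, sxy / A - cx * cy,
                  sxy / A - cx * cy, syy / A - cy^2), 2, 2)
  list(area = abs(A), centroid = c(cx, cy), cov = cov,
       vertices = cbind(x, y))
}

.polygonPerimeter <- function(p) {
  n <- nrow(p)
  if (n >= 2 && all(p[1, ] == p[n, ])) p <- p[-n, , drop = FALSE]
  q <- p[c(2:nrow(p), 1), , drop = FALSE]
  sum(sqrt(rowSums((q - p)^2)))
}

## Unit vectors of the case's anatomical frame: temporal (towards the
## fovea), nasal, and superior (image-up side of the perpendicular).
.caseFrame <- function(center, foveaXY) {
  t <- foveaXY - center
  len <- sqrt(sum(t^2))
  if (len < 1e-9) stop("fovea coincides with disc center: temporal direction undefined")
  t <- t / len
  p <- c(-t[2], t[1])          # one perpendicular
  if (p[2] > 0 || (p[2] == 0 && p[1] < 0)) p <- -p  # superior = image-up (y down)
  list(temporal = t, nasal = -t, superior = p, dfdPx = len)
}

#' Disc shape metrics: diameters, ovality index and torsion angle
#'
#' The disc contour's second-moment principal axes define the long and
#' short axis; the longest diameter (LD) and shortest diameter (SD) are the
#' contour extents along them, in mm. The ovality index is SD/LD. The
#' torsion angle is the signed angle between the long axis and the line
#' perpendicular to the disc-centre--fovea line: positive when the superior
#' end of the long axis tilts towards the nasal side (superonasal torsion),
#' negative towards the temporal side (inferotemporal), with superior
#' meaning image-up. Nearly circular discs (ovality above 0.995) report a
#' torsion of 0 by convention.
#'
#' @param annotation a [FundusAnnotation-class].
#' @param mag a [MagnificationModel-class] from [littmannScale()].
#' @return A list with elements `LD`, `SD` (mm), `ovalityIndex`,
#'   `torsionAngle` (degrees), `center` (pixel), `longAxis` (unit vector).
#' @export
discShapeMetrics <- function(annotation, mag) {
  stopifnot(is(annotation, "FundusAnnotation"), is(mag, "MagnificationModel"))
  m <- .polygonMoments(annotation@discContour)
  e <- eigen(m$cov, symmetric = TRUE)
  u <- e$vectors[, 1]                      # long axis (largest variance)
  v <- e$vectors[, 2]
  pts <- sweep(m$vertices, 2, m$centroid)
  ld <- diff(range(pts %*% u)) * mag@scale
  sd_ <- diff(range(pts %*% v)) * mag@scale
  if (sd_ > ld) { tmp <- ld; ld <- sd_; sd_ <- tmp; tmp <- u; u <- v; v <- tmp }
  ovality <- sd_ / ld
  fr <- .caseFrame(m$centroid, annotation@fovea)
  if (ovality > 0.995) {
    torsion <- 0
    u <- fr$superior
  } else {
    if (sum(u * fr$superior) < 0) u <- -u   # orient towards the superior end
    torsion <- atan2(sum(u * fr$nasal), sum(u * fr$superior)) * 180 / pi
    if (torsion <= -90) torsion <- torsion + 180
    if (torsion > 90) torsion <- torsion - 180
  }
  list(LD = ld, SD = sd_, ovalityIndex = ovality, torsionAngle = torsion,
       center = m$centroid, longAxis = u)
}

#' PPA morphometry: area, perimeter, width and disc-fovea distance
#'
#' Area is that of the PPA region with any overlap with the disc region
#' removed, in mm^2; perimeter is the PPA contour length in mm; width is
#' the extent of the PPA region measured along the ray from the disc centre
#' through the fovea, in mm; the disc-fovea distance is measured from the
#' disc centroid. An empty PPA contour yields zero area, perimeter and
#' width. Region membership is evaluated on a fine subpixel grid.
#'
#' @inheritParams discShapeMetrics
#' @return list with `area` (mm^2), `perimeter` (mm), `width` (mm),
#'   `discFoveaDistance` (mm).
#' @export
ppaMetrics <- function(annotation, mag) {
  stopifnot(is(annotation, "FundusAnnotation"), is(mag, "MagnificationModel"))
  dm <- .polygonMoments(annotation@discContour)
  fr <- .caseFrame(dm$centroid, annotation@fovea)
  dfd <- fr$dfdPx * mag@scale
  pc <- annotation@ppaContour
  if (nrow(pc) == 0)
    return(list(area = 0, perimeter = 0, width = 0, discFoveaDistance = dfd))
  ## fine-grid area of PPA minus disc
  xr <- range(pc[, 1]); yr <- range(pc[, 2])
  step <- max(diff(xr), diff(yr)) / 240
  gx <- seq(xr[1], xr[2], by = step)
  gy <- seq(yr[1], yr[2], by = step)
  g <- expand.grid(x = gx, y = gy)
  inPpa <- pointsInPolygon(g$x, g$y, pc)
  inDisc <- rep(FALSE, nrow(g))
  inDisc[inPpa] <- pointsInPolygon(g$x[inPpa], g$y[inPpa],
                                   annotation@discContour)
  nIn <- sum(inPpa & !inDisc)
  if (nIn == 0)
    stop("PPA contour lies entirely inside the disc: non-positive area")
  area <- nIn * step^2 * mag@scale^2
  perim <- .polygonPerimeter(pc) * mag@scale
  ## width along the disc-centre -> fovea ray
  smax <- max((sweep(pc, 2, dm$centroid) %*% fr$temporal)) + 2 * step
  if (smax <= 0) {
    width <- 0
  } else {
    ss <- seq(0, smax, length.out = 2048)
    px <- dm$centroid[1] + ss * fr$temporal[1]
    py <- dm$centroid[2] + ss * fr$temporal[2]
    on <- pointsInPolygon(px, py, pc)
    on[on] <- !pointsInPolygon(px[on], py[on], annotation@discContour)
    width <- sum(on) * (ss[2] - ss[1]) * mag@scale
  }
  list(area = area, perimeter = perim, width = width, discFoveaDistance = dfd)
}

#' Test points against a closed polygon
#'
#' Vectorised even-odd (crossing-number) point-in-polygon test in the
#' package's pixel coordinate convention.
#'
#' @param x,y numeric vectors of point coordinates.
#' @param poly n x 2 matrix of polygon vertices, implicitly closed.
#' @return logical vector.
#' @export
pointsInPolygon <- function(x, y, poly) {
  n <- nrow(poly)
  if (n >= 2 && all(poly[1, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  cppPointsInPolygon(as.numeric(x), as.numeric(y),
                     as.numeric(poly[, 1]), as.numeric(poly[, 2]))
}

## Rasterise a polygon to a logical vector (column-major, h x w),
## testing only pixels inside its bounding box.
.maskFromPolygon <- function(poly, h, w) {
  out <- rep(FALSE, h * w)
  x0 <- max(0, floor(min(poly[, 1]))); x1 <- min(w - 1, ceiling(max(poly[, 1])))
  y0 <- max(0, floor(min(poly[, 2]))); y1 <- min(h - 1, ceiling(max(poly[, 2])))
  if (x1 < x0 || y1 < y0) return(out)
  bx <- rep(x0:x1, each = y1 - y0 + 1)
  by <- rep(y0:y1, times = x1 - x0 + 1)
  inside <- pointsInPolygon(bx, by, poly)
  out[bx * h + by + 1] <- inside
  out
}

## Sector index relative to the case frame: 1 temporal, 2 superior,
## 3 nasal, 4 inferior. Boundaries at +-45 deg around the temporal axis;
## a point exactly on a boundary joins the sector counter-clockwise of it
## (angles measured from temporal towards superior, right-open intervals).
.quadrantIndex <- function(dx, dy, frame) {
  a <- atan2(dx * frame$superior[1] + dy * frame$superior[2],
             dx * frame$temporal[1] + dy * frame$temporal[2]) * 180 / pi
  idx <- integer(length(a))
  idx[a >= -45 & a < 45] <- 1L
  idx[a >= 45 & a < 135] <- 2L
  idx[a >= 135 | a < -135] <- 3L
  idx[a >= -135 & a < -45] <- 4L
  idx
}

#' Build the four feature-extraction ROI masks
#'
#' ETDRS circles of 3 and 6 mm diameter centred on the disc centroid define
#' the inner ring (between the disc margin and the 3-mm circle, PPA pixels
#' included) and the outer ring (3-6 mm annulus). Quadrants are 90-degree
#' sectors centred on the temporal (towards the fovea), superior
#' (image-up), nasal and inferior directions, so the construction is
#' agnostic to eye laterality. Returned masks: disc interior (D), inner
#' ring (I), temporal quadrant of the inner ring (IT) and temporal quadrant
#' of the outer ring (OT). Vessel pixels are removed from every mask.
#' Pixel membership is decided at pixel centres.
#'
#' @inheritParams discShapeMetrics
#' @param imageShape integer (rows, cols) of the photograph.
#' @param excludeVessels logical; remove vessel-mask pixels (default TRUE).
#' @return A [ROIMaskSet-class].
#' @export
buildRoiMasks <- function(annotation, mag, imageShape = dim(vesselMask(annotation)),
                          excludeVessels = TRUE) {
  stopifnot(is(annotation, "FundusAnnotation"), is(mag, "MagnificationModel"))
  h <- imageShape[1]; w <- imageShape[2]
  if (3 / mag@scale > min(h, w) / 2)
    warning("6-mm ETDRS circle does not fit inside the image at this scale")
  dm <- .polygonMoments(annotation@discContour)
  fr <- .caseFrame(dm$centroid, annotation@fovea)
  xs <- rep(0:(w - 1), each = h)
  ys <- rep(0:(h - 1), times = w)
  dx <- xs - dm$centroid[1]; dy <- ys - dm$centroid[2]
  rmm <- sqrt(dx^2 + dy^2) * mag@scale
  disc <- matrix(.maskFromPolygon(annotation@discContour, h, w), h, w)
  quad <- matrix(.quadrantIndex(dx, dy, fr), h, w)
  innerCircle <- matrix(rmm <= 1.5, h, w)
  outerRing <- matrix(rmm > 1.5 & rmm <= 3, h, w)
  inner <- innerCircle & !disc
  it <- inner & quad == 1L
  ot <- outerRing & quad == 1L
  if (excludeVessels) {
    v <- annotation@vesselMask
    if (!identical(dim(v), c(h, w)))
      stop("vessel mask dimensions do not match imageShape")
    disc <- disc & !v; inner <- inner & !v; it <- it & !v; ot <- ot & !v
  }
  new("ROIMaskSet", disc = disc, inner = inner, innerTemporal = it,
      outerTemporal = ot, vesselExcluded = excludeVessels)
}

#' Eight-region peripapillary partition
#'
#' The full partition the peripapillary analysis is based on: inner and
#' outer ETDRS rings around the disc, each split into temporal, superior,
#' nasal and inferior quadrants (the disc itself is returned separately by
#' [buildRoiMasks()]).
#'
#' @inheritParams buildRoiMasks
#' @return Named list of eight logical masks
#'   (`inner_temporal`, ..., `outer_inferior`).
#' @export
peripapillaryPartition <- function(annotation, mag,
                                   imageShape = dim(vesselMask(annotation))) {
  h <- imageShape[1]; w <- imageShape[2]
  dm <- .polygonMoments(annotation@discContour)
  fr <- .caseFrame(dm$centroid, annotation@fovea)
  xs <- rep(0:(w - 1), each = h)
  ys <- rep(0:(h - 1), times = w)
  dx <- xs - dm$centroid[1]; dy <- ys - dm$centroid[2]
  rmm <- sqrt(dx^2 + dy^2) * mag@scale
  disc <- .maskFromPolygon(annotation@discContour, h, w)
  quad <- .quadrantIndex(dx, dy, fr)
  out <- list()
  qn <- c("temporal", "superior", "nasal", "inferior")
  for (qi in 1:4) {
    out[[paste0("inner_", qn[qi])]] <-
      matrix(rmm <= 1.5 & !disc & quad == qi, h, w)
    out[[paste0("outer_", qn[qi])]] <-
      matrix(rmm > 1.5 & rmm <= 3 & quad == qi, h, w)
  }
  out
}

#' ETDRS sector means of a scalar map
#'
#' Overlays the ETDRS grid (1/3/6-mm diameter circles) on a scalar raster
#' and averages pixel values per sector. Macular mode returns nine values:
#' the central 1-mm circle, and temporal/superior/nasal/inferior quadrants
#' of the 1-3 mm inner ring and the 3-6 mm outer ring. Peripapillary mode
#' returns only the four outer-ring quadrants (no reliable choroidal signal
#' exists in the central sectors there).
#'
#' @param map numeric matrix (rows y, cols x).
#' @param center (x, y) pixel position of the grid centre.
#' @param mag a [MagnificationModel-class].
#' @param mode `"macula"` or `"peripapillary"`.
#' @param temporalDir unit (x, y) vector pointing temporally, used to place
#'   the quadrants.
#' @return Named numeric vector of sector means (9 or 4 values).
#' @export
etdrsSectorMeans <- function(map, center, mag,
                             mode = c("macula", "peripapillary"),
                             temporalDir) {
  mode <- match.arg(mode)
  h <- nrow(map); w <- ncol(map)
  xs <- rep(0:(w - 1), each = h)
  ys <- rep(0:(h - 1), times = w)
  dx <- xs - center[1]; dy <- ys - center[2]
  rmm <- sqrt(dx^2 + dy^2) * mag@scale
  if (max(rmm[c(1, h, (w - 1) * h + 1, w * h)]) < 3)
    stop("6-mm ETDRS grid does not fit inside the raster")
  td <- temporalDir / sqrt(sum(temporalDir^2))
  p <- c(-td[2], td[1])
  if (p[2] > 0 || (p[2] == 0 && p[1] < 0)) p <- -p
  quad <- .quadrantIndex(dx, dy, list(temporal = td, superior = p))
  v <- as.numeric(map)
  qn <- c("temporal", "superior", "nasal", "inferior")
  sectorMean <- function(sel, name) {
    if (!any(sel)) stop("empty ETDRS sector: ", name)
    mean(v[sel])
  }
  out <- numeric()
  if (mode == "macula") {
    out["central"] <- sectorMean(rmm <= 0.5, "central")
    for (qi in 1:4)
      out[paste0("inner_", qn[qi])] <-
        sectorMean(rmm > 0.5 & rmm <= 1.5 & quad == qi, paste0("inner_", qn[qi]))
  }
  for (qi in 1:4)
    out[paste0("outer_", qn[qi])] <-
      sectorMean(rmm > 1.5 & rmm <= 3 & quad == qi, paste0("outer_", qn[qi]))
  out
}
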