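#' @import methods
NULL

## Pixel coordinate convention used throughout the package:
## origin at the top-left pixel centre, x increases rightward (columns),
## y increases downward (rows), both 0-based. Contour points are stored in
## pixel units with sub-pixel precision, one point per row (x, y).
## "Superior" always means image-up (decreasing y).

#' Manual annotation of a disc-centred fundus photograph
#'
#' Holds the hand-drawn (or synthetically rendered) optic-disc contour, the
#' peripapillary-atrophy (PPA) contour, the fovea position and the binary
#' vessel mask for one photograph. Contours are implicitly closed polygons
#' in pixel coordinates (origin top-left, x rightward, y downward).
#'
#' @slot discContour numeric matrix, one (x, y) point per row; at least 8
#'   points, non-self-intersecting.
#' @slot ppaContour numeric matrix as above, possibly with zero rows when no
#'   PPA is present.
#' @slot fovea numeric length-2 (x, y) pixel position of the fovea.
#' @slot vesselMask logical matrix with the image's dimensions; \code{TRUE}
#'   marks vessel pixels, which are excluded from every feature ROI.
#' @slot eye one of \code{"right"}, \code{"left"}, \code{"unknown"}.
#'
#' @seealso [fundusAnnotation()], [loadCase()]
#' @export
setClass("FundusAnnotation",
  representation(
    discContour = "matrix",
    ppaContour  = "matrix",
    fovea       = "numeric",
    vesselMask  = "matrix",
    eye         = "character"
  )
)

.isClosedSimplePolygon <- function(p) {
  ## implicitly closed; drop duplicated closing vertex if present
  n <- nrow(p)
  if (n >= 2 && isTRUE(all(p[1, ] == p[n, ]))) p <- p[-n, , drop = FALSE]
  n <- nrow(p)
  if (n < 8) return("fewer than 8 points")
  ax <- p[, 1]; ay <- p[, 2]
  bx <- ax[c(2:n, 1)]; by <- ay[c(2:n, 1)]
  ux <- bx - ax; uy <- by - ay
  ## proper-crossing test between non-adjacent segments, with a small
  ## tolerance so touching/near-collinear tips do not count as crossings
  eps <- 1e-8 * max(1, max(abs(p)))^2
  for (i in seq_len(n - 2)) {
    j <- (i + 2):n
    if (i == 1) j <- j[j != n]
    d1 <- ux[i] * (ay[j] - ay[i]) - uy[i] * (ax[j] - ax[i])
    d2 <- ux[i] * (by[j] - ay[i]) - uy[i] * (bx[j] - ax[i])
    d3 <- ux[j] * (ay[i] - ay[j]) - uy[j] * (ax[i] - ax[j])
    d4 <- ux[j] * (by[i] - ay[j]) - uy[j] * (bx[i] - ax[j])
    if (any(d1 * d2 < -eps & d3 * d4 < -eps &
            pmin(abs(d1), abs(d2), abs(d3), abs(d4)) > eps))
      return("self-intersecting contour")
  }
  TRUE
}

setValidity("FundusAnnotation", function(object) {
  msg <- character()
  dc <- object@discContour
  if (ncol(dc) != 2) msg <- c(msg, "discContour: must have two columns (x, y)")
  ck <- .isClosedSimplePolygon(dc)
  if (!isTRUE(ck)) msg <- c(msg, paste0("discContour: ", ck))
  pc <- object@ppaContour
  if (nrow(pc) > 0) {
    if (ncol(pc) != 2) msg <- c(msg, "ppaContour: must have two columns (x, y)")
    ck <- .isClosedSimplePolygon(pc)
    if (!isTRUE(ck)) msg <- c(msg, paste0("ppaContour: ", ck))
  }
  if (length(object@fovea) != 2 || any(!is.finite(object@fovea)))
    msg <- c(msg, "fovea: must be a finite (x, y) pair")
  h <- nrow(object@vesselMask); w <- ncol(object@vesselMask)
  if (!is.logical(object@vesselMask))
    msg <- c(msg, "vesselMask: must be a logical matrix")
  if (length(object@fovea) == 2 &&
      (object@fovea[1] < 0 || object@fovea[1] > w - 1 ||
       object@fovea[2] < 0 || object@fovea[2] > h - 1))
    msg <- c(msg, "fovea out of bounds")
  if (!(object@eye %in% c("right", "left", "unknown")))
    msg <- c(msg, "eye: must be 'right', 'left' or 'unknown'")
  if (length(msg)) msg else TRUE
})

#' Construct a FundusAnnotation
#'
#' @param discContour,ppaContour numeric matrices of (x, y) contour points in
#'   pixel coordinates; the PPA contour may have zero rows.
#' @param fovea numeric (x, y) fovea position in pixels.
#' @param vesselMask logical matrix matching the image dimensions.
#' @param eye `"right"`, `"left"` or `"unknown"`.
#' @return A validated [FundusAnnotation-class] object.
#' @export
fundusAnnotation <- function(discContour, ppaContour = matrix(numeric(), 0, 2),
                             fovea, vesselMask, eye = "unknown") {
  new("FundusAnnotation",
      discContour = as.matrix(discContour),
      ppaContour = as.matrix(ppaContour),
      fovea = as.numeric(fovea),
      vesselMask = vesselMask,
      eye = eye)
}

#' @describeIn FundusAnnotation-class optic-disc contour accessor
#' @param object,x a \code{FundusAnnotation}
#' @export
setGeneric("discContour", function(object) standardGeneric("discContour"))
#' @rdname FundusAnnotation-class
#' @export
setMethod("discContour", "FundusAnnotation", function(object) object@discContour)

#' @rdname FundusAnnotation-class
#' @export
setGeneric("ppaContour", function(object) standardGeneric("ppaContour"))
#' @rdname FundusAnnotation-class
#' @export
setMethod("ppaContour", "FundusAnnotation", function(object) object@ppaContour)

#' @rdname FundusAnnotation-class
#' @export
setGeneric("fovea", function(object) standardGeneric("fovea"))
#' @rdname FundusAnnotation-class
#' @export
setMethod("fovea", "FundusAnnotation", function(object) object@fovea)

#' @rdname FundusAnnotation-class
#' @export
setGeneric("vesselMask", function(object) standardGeneric("vesselMask"))
#' @rdname FundusAnnotation-class
#' @export
setMethod("vesselMask", "FundusAnnotation", function(object) object@vesselMask)

#' @rdname FundusAnnotation-class
#' @export
setGeneric("eyeSide", function(object) standardGeneric("eyeSide"))
#' @rdname FundusAnnotation-class
#' @export
setMethod("eyeSide", "FundusAnnotation", function(object) object@eye)

setMethod("show", "FundusAnnotation", function(object) {
  cat("FundusAnnotation (", object@eye, " eye)\n", sep = "")
  cat("  disc contour: ", nrow(object@discContour), " points\n", sep = "")
  cat("  PPA contour:  ", nrow(object@ppaContour), " points\n", sep = "")
  cat("  fovea: (", round(object@fovea[1], 1), ", ",
      round(object@fovea[2], 1), ") px\n", sep = "")
  cat("  vessel mask: ", nrow(object@vesselMask), " x ",
      ncol(object@vesselMask), " (", sum(object@vesselMask),
      " vessel px)\n", sep = "")
})

#' Ocular magnification model (Littmann/Bennett)
#'
#' Converts pixel measurements on a fundus photograph to millimetres on the
#' retina. The ocular factor follows Bennett's axial-length-only adjustment
#' of Littmann's formula, q = 0.01306 (AL - 1.82) mm per degree-equivalent
#' unit; the per-case scale is the camera constant times q.
#'
#' @slot al axial length, mm.
#' @slot cameraConstant camera factor linking q to mm per pixel.
#' @slot q Bennett ocular factor, strictly increasing in AL.
#' @slot scale mm per pixel for this case.
#' @seealso [littmannScale()]
#' @export
setClass("MagnificationModel",
  representation(al = "numeric", cameraConstant = "numeric",
                 q = "numeric", scale = "numeric"))

setValidity("MagnificationModel", function(object) {
  if (object@scale <= 0) "scale must be positive" else TRUE
})

#' @rdname MagnificationModel-class
#' @param object a \code{MagnificationModel}
#' @export
setGeneric("mmPerPixel", function(object) standardGeneric("mmPerPixel"))
#' @rdname MagnificationModel-class
#' @export
setMethod("mmPerPixel", "MagnificationModel", function(object) object@scale)

setMethod("show", "MagnificationModel", function(object) {
  cat("MagnificationModel: AL ", object@al, " mm, q = ",
      signif(object@q, 5), ", scale = ", signif(object@scale, 5),
      " mm/px\n", sep = "")
})

#' Feature-extraction ROI masks for one case
#'
#' Binary rasters for the four regions of interest: optic disc (D), inner
#' ring (I, between disc margin and the 3-mm ETDRS circle), inner temporal
#' region (IT, temporal quadrant of the inner ring) and outer temporal
#' region (OT, temporal quadrant of the 3-6 mm annulus). The inner temporal
#' mask is by construction a subset of the inner ring; disc, inner ring and
#' outer temporal masks are pairwise disjoint. When \code{vesselExcluded} is
#' \code{TRUE}, vessel pixels have been removed from every mask.
#'
#' @slot disc,inner,innerTemporal,outerTemporal logical matrices.
#' @slot vesselExcluded logical flag.
#' @seealso [buildRoiMasks()]
#' @export
setClass("ROIMaskSet",
  representation(disc = "matrix", inner = "matrix",
                 innerTemporal = "matrix", outerTemporal = "matrix",
                 vesselExcluded = "logical"))

setValidity("ROIMaskSet", function(object) {
  d <- dim(object@disc)
  for (s in c("inner", "innerTemporal", "outerTemporal"))
    if (!identical(dim(slot(object, s)), d)) return("mask dimensions differ")
  if (any(object@disc & object@inner)) return("disc and inner ring overlap")
  if (any(object@disc & object@outerTemporal) ||
      any(object@inner & object@outerTemporal))
    return("outer temporal mask overlaps an inner region")
  if (any(object@innerTemporal & !object@inner))
    return("inner temporal mask must lie inside the inner ring")
  TRUE
})

#' @rdname ROIMaskSet-class
#' @param object a \code{ROIMaskSet}
#' @param roi one of \code{"D"}, \code{"I"}, \code{"IT"}, \code{"OT"}
#' @export
setGeneric("roiMask", function(object, roi) standardGeneric("roiMask"))
#' @rdname ROIMaskSet-class
#' @export
setMethod("roiMask", "ROIMaskSet", function(object, roi) {
  switch(match.arg(roi, c("D", "I", "IT", "OT")),
         D = object@disc, I = object@inner,
         IT = object@innerTemporal, OT = object@outerTemporal)
})

setMethod("show", "ROIMaskSet", function(object) {
  cat("ROIMaskSet (", nrow(object@disc), " x ", ncol(object@disc),
      "; vessels ", if (object@vesselExcluded) "excluded" else "retained",
      ")\n", sep = "")
  for (r in c("D", "I", "IT", "OT"))
    cat("  ", format(r, width = 2), ": ", sum(roiMask(object, r)),
        " px\n", sep = "")
})

#' LASSO selection path with adjusted-R-squared trace
#'
#' Features ordered by first entry along a decreasing-lambda LASSO
#' regularisation path, together with the adjusted R-squared of the
#' ordinary-least-squares refit of the first k features, evaluated on the
#' training and the held-out test set for each k.
#'
#' @slot featureOrder character vector, entry order.
#' @slot adjR2Train,adjR2Test numeric per-k traces (filled by
#'   [selectFeatureCount()]; empty until then).
#' @seealso [lassoOrder()], [selectFeatureCount()]
#' @export
setClass("SelectionPath",
  representation(featureOrder = "character",
                 adjR2Train = "numeric", adjR2Test = "numeric"))

setMethod("show", "SelectionPath", function(object) {
  cat("SelectionPath with", length(object@featureOrder), "ordered features\n")
  k <- length(object@adjR2Test)
  if (k) {
    cat("  adjR2 (train):", paste(signif(object@adjR2Train, 3), collapse = " "), "\n")
    cat("  adjR2 (test): ", paste(signif(object@adjR2Test, 3), collapse = " "), "\n")
  }
})

#' Imaging indicator of the optic disc (IOD)
#'
#' A linear model predicting choroidal thickness from a small set of
#' imaging features. Features are standardised with training-set means and
#' standard deviations; the fitted value divided by 10 is the indicator, in
#' units of 10 micrometres.
#'
#' @slot target \code{"mChT"} or \code{"pChT"}.
#' @slot featureNames ordered character vector of predictor names.
#' @slot center,scaleSd named training-set means / sds used to standardise.
#' @slot coefficients named coefficients on standardised features (micrometre
#'   scale).
#' @slot intercept model intercept, micrometres.
#' @slot unit always \code{"10um"}.
#' @seealso [fitIod()], [predictIod()], [saveModel()]
#' @export
setClass("IODModel",
  representation(target = "character", featureNames = "character",
                 center = "numeric", scaleSd = "numeric",
                 coefficients = "numeric", intercept = "numeric",
                 unit = "character"))

setValidity("IODModel", function(object) {
  msg <- character()
  if (!(object@target %in% c("mChT", "pChT")))
    msg <- c(msg, "target must be 'mChT' or 'pChT'")
  k <- length(object@featureNames)
  if (length(object@center) != k || length(object@scaleSd) != k ||
      length(object@coefficients) != k)
    msg <- c(msg, "center, scaleSd and coefficients must match featureNames")
  if (any(object@scaleSd <= 0)) msg <- c(msg, "scaleSd must be positive")
  if (!identical(object@unit, "10um")) msg <- c(msg, "unit must be '10um'")
  if (length(msg)) msg else TRUE
})

#' @rdname IODModel-class
#' @param object an \code{IODModel}
#' @export
setGeneric("featureNames", function(object) standardGeneric("featureNames"))
#' @rdname IODModel-class
#' @export
setMethod("featureNames", "IODModel", function(object) object@featureNames)

#' @rdname IODModel-class
#' @export
setGeneric("modelTarget", function(object) standardGeneric("modelTarget"))
#' @rdname IODModel-class
#' @export
setMethod("modelTarget", "IODModel", function(object) object@target)

setMethod("show", "IODModel", function(object) {
  cat("IODModel for ", object@target, " (unit: 10 um)\n", sep = "")
  cat("  features: ", paste(object@featureNames, collapse = ", "), "\n", sep = "")
  cat("  intercept: ", signif(object@intercept, 6), " um\n", sep = "")
})
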