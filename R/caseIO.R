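## Readers and writers for every artifact format: PNG/TIFF photographs,
## annotation JSON, feature-table CSV (+ units sidecar), and model JSON.
## All writers are deterministic (stable key order, fixed float handling);
## all readers validate type invariants and fail naming the bad field.

.ANNOTATION_SCHEMA <- "fundusIOD-annotation-1"
.MODEL_SCHEMA <- "fundusIOD-iod-model-1"

## deterministic CSV writer (15 significant digits via as.character)
.writeCsv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "NA")
}

#' Write an annotation to JSON
#'
#' The package's annotation dialect: schema tag, eye side, fovea, contours
#' as point lists, and the vessel mask as a run-length encoding of the
#' column-major flattened raster.
#'
#' @param annotation a [FundusAnnotation-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAnnotation <- function(annotation, path) {
  stopifnot(is(annotation, "FundusAnnotation"))
  v <- as.logical(annotation@vesselMask)
  rl <- rle(v)
  obj <- list(
    schema = .ANNOTATION_SCHEMA,
    eye = annotation@eye,
    fovea = as.numeric(annotation@fovea),
    disc_contour = unname(apply(annotation@discContour, 1, as.numeric,
                                simplify = FALSE)),
    ppa_contour = if (nrow(annotation@ppaContour))
      unname(apply(annotation@ppaContour, 1, as.numeric, simplify = FALSE))
      else list(),
    vessel_mask = list(
      dims = dim(annotation@vesselMask),
      first = rl$values[1],
      run_lengths = rl$lengths))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an annotation JSON
#'
#' @param path annotation file written by [writeAnnotation()].
#' @return A validated [FundusAnnotation-class]; invariant violations
#'   raise an error naming the offending field.
#' @export
readAnnotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, .ANNOTATION_SCHEMA))
    stop("unsupported annotation schema: ", obj$schema)
  dims <- as.integer(obj$vessel_mask$dims)
  v <- rep(rep(c(obj$vessel_mask$first, !obj$vessel_mask$first),
               length.out = length(obj$vessel_mask$run_lengths)),
           times = obj$vessel_mask$run_lengths)
  toMat <- function(x) {
    if (length(x) == 0) return(matrix(numeric(), 0, 2))
    if (is.list(x)) x <- do.call(rbind, x)
    matrix(as.numeric(x), ncol = 2)
  }
  fundusAnnotation(
    discContour = toMat(obj$disc_contour),
    ppaContour = toMat(obj$ppa_contour),
    fovea = as.numeric(obj$fovea),
    vesselMask = matrix(v, dims[1], dims[2]),
    eye = obj$eye)
}

#' Load a photograph and its annotation
#'
#' Decodes the image (PNG, or TIFF when the tiff package is installed) to
#' an 8-bit RGB array and validates the annotation against all type
#' invariants.
#'
#' @param imagePath path to a 3-channel PNG or TIFF.
#' @param annotationPath path to the matching annotation JSON.
#' @return List with `image` (H x W x 3 array in [0, 1]) and `annotation`.
#' @export
loadCase <- function(imagePath, annotationPath) {
  if (!file.exists(imagePath)) stop("image file not found: ", imagePath)
  ext <- tolower(tools::file_ext(imagePath))
  img <- switch(ext,
    png = png::readPNG(imagePath),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the tiff package")
      tiff::readTIFF(imagePath)
    },
    stop("unsupported image format: .", ext))
  if (length(dim(img)) != 3 || dim(img)[3] < 3)
    stop("image must have 3 colour channels (got ",
         if (length(dim(img)) == 3) dim(img)[3] else 1, ")")
  img <- img[, , 1:3, drop = FALSE]
  ann <- readAnnotation(annotationPath)
  if (!identical(dim(ann@vesselMask), dim(img)[1:2]))
    stop("vessel_mask dimensions do not match the image")
  list(image = img, annotation = ann)
}

#' Write / read a feature table
#'
#' The feature table holds one row per case with named feature columns and
#' the target columns `mChT`/`pChT` when available. Written as CSV with a
#' JSON sidecar (`<path>.units.json`) recording the unit of every column;
#' read-write round trips are identity up to 15-significant-digit float
#' formatting.
#'
#' @param table data frame, unique column names; optional `units`
#'   attribute (named character).
#' @param path CSV path.
#' @return `path` invisibly for the writer; the data frame (with `units`
#'   attribute) for the reader.
#' @export
writeFeatureTable <- function(table, path) {
  if (anyDuplicated(names(table)))
    stop("duplicate column names: ",
         paste(unique(names(table)[duplicated(names(table))]), collapse = ", "))
  .writeCsv(table, path)
  units <- attr(table, "units")
  if (is.null(units)) units <- stats::setNames(rep("", ncol(table)), names(table))
  jsonlite::write_json(as.list(units), paste0(path, ".units.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @param requireTargets character vector of target columns that must be
#'   present (e.g. `"mChT"`); absence is an error.
#' @export
readFeatureTable <- function(path, requireTargets = NULL) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  tb <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(names(tb)))
    stop("duplicate column names in feature table")
  missing <- setdiff(requireTargets, names(tb))
  if (length(missing))
    stop("required target column(s) absent: ", paste(missing, collapse = ", "))
  up <- paste0(path, ".units.json")
  if (file.exists(up))
    attr(tb, "units") <- unlist(jsonlite::read_json(up, simplifyVector = TRUE))
  tb
}

#' Save / load an IOD model
#'
#' JSON with a schema version, ordered feature names, training-set
#' standardisation parameters, coefficients, intercept and the output
#' unit (10 um). A save-load round trip reproduces predictions
#' bit-identically.
#'
#' @param model an [IODModel-class].
#' @param path JSON path.
#' @return `path` invisibly; the loader returns the validated model.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "IODModel"))
  obj <- list(
    schema = .MODEL_SCHEMA,
    target = model@target,
    feature_names = model@featureNames,
    center = as.numeric(model@center),
    scale_sd = as.numeric(model@scaleSd),
    coefficients = as.numeric(model@coefficients),
    intercept = model@intercept,
    unit = model@unit)
  ## 17 significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, .MODEL_SCHEMA))
    stop("unsupported model schema: ", obj$schema)
  need <- c("target", "feature_names", "center", "scale_sd",
            "coefficients", "intercept", "unit")
  miss <- need[!vapply(need, function(f) !is.null(obj[[f]]), TRUE)]
  if (length(miss))
    stop("model file missing field(s): ", paste(miss, collapse = ", "))
  fn <- as.character(obj$feature_names)
  new("IODModel", target = obj$target, featureNames = fn,
      center = stats::setNames(as.numeric(obj$center), fn),
      scaleSd = stats::setNames(as.numeric(obj$scale_sd), fn),
      coefficients = stats::setNames(as.numeric(obj$coefficients), fn),
      intercept = as.numeric(obj$intercept), unit = obj$unit)
}
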