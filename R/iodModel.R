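## Model construction: 70/30 cohort split, LASSO entry ordering of the
## feature pool, adjusted-R-squared stopping rule on the held-out set, and
## the final ordinary-least-squares indicator models in 10-um units.

#' Adjusted coefficient of determination
#'
#' adjR2 = 1 - (1 - R2)(n - 1)/(n - p - 1).
#'
#' @param r2 coefficient of determination.
#' @param n number of observations.
#' @param p number of predictors (excluding the intercept).
#' @return adjusted R-squared.
#' @export
adjustedR2 <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

#' Split a cohort into training and test sets
#'
#' Simple random split without stratification; the training set holds
#' `floor(trainFraction * n)` rows.
#'
#' @param table data frame (one row per case).
#' @param trainFraction in (0, 1); default 0.7.
#' @param seed RNG seed.
#' @return List with `train` and `test` data frames (disjoint, exhaustive).
#' @export
splitCohort <- function(table, trainFraction = 0.7, seed = 1) {
  n <- nrow(table)
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie strictly between 0 and 1")
  if (n < 10) stop("cohort too small to split (need n >= 10)")
  set.seed(seed)
  nTrain <- floor(trainFraction * n)
  idx <- sample.int(n, nTrain)
  list(train = table[sort(idx), , drop = FALSE],
       test = table[sort(setdiff(seq_len(n), idx)), , drop = FALSE])
}

#' Order features by first entry on the LASSO path
#'
#' Standardises the predictors, fits the LASSO regularisation path
#' (decreasing lambda) and orders features by the lambda index at which
#' they first obtain a non-zero coefficient. Ties are broken by larger
#' absolute correlation with the response, then by name. Zero-variance
#' features are excluded with a warning before fitting; a constant
#' response yields an empty ordering.
#'
#' @param X numeric matrix or data frame of features (training set).
#' @param y numeric response (choroidal thickness, um).
#' @param kMax maximum number of ordered features returned.
#' @return A [SelectionPath-class] with the entry order (adjR2 traces are
#'   filled in by [selectFeatureCount()]).
#' @export
lassoOrder <- function(X, y, kMax = 30) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    warning("excluding zero-variance feature(s): ",
            paste(colnames(X)[sds == 0 | !is.finite(sds)], collapse = ", "))
    X <- X[, sds > 0 & is.finite(sds), drop = FALSE]
  }
  if (ncol(X) == 0 || stats::sd(y) == 0)
    return(new("SelectionPath", featureOrder = character(),
               adjR2Train = numeric(), adjR2Test = numeric()))
  Xs <- scale(X)
  fit <- glmnet::glmnet(Xs, y, family = "gaussian", standardize = FALSE,
                        nlambda = 200, lambda.min.ratio = 1e-4)
  beta <- fit$beta  # features x lambda sparse matrix
  entry <- apply(as.matrix(beta) != 0, 1, function(z)
    if (any(z)) which(z)[1] else Inf)
  absCor <- abs(apply(Xs, 2, function(xx) stats::cor(xx, y)))
  ord <- order(entry, -absCor, colnames(X))
  ord <- ord[is.finite(entry[ord])]
  new("SelectionPath",
      featureOrder = utils::head(colnames(X)[ord], kMax),
      adjR2Train = numeric(), adjR2Test = numeric())
}

.olsAdjR2 <- function(train, test, features, target) {
  Xtr <- as.matrix(train[, features, drop = FALSE])
  Xte <- as.matrix(test[, features, drop = FALSE])
  ytr <- train[[target]]; yte <- test[[target]]
  fit <- stats::lm.fit(cbind(1, Xtr), ytr)
  k <- length(features)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0   # pivoted-out (exactly collinear) columns
  prTr <- cbind(1, Xtr) %*% cf
  prTe <- cbind(1, Xte) %*% cf
  r2tr <- 1 - sum((ytr - prTr)^2) / sum((ytr - mean(ytr))^2)
  r2te <- 1 - sum((yte - prTe)^2) / sum((yte - mean(yte))^2)
  c(adjustedR2(r2tr, length(ytr), k), adjustedR2(r2te, length(yte), k))
}

#' Choose the feature count by the held-out adjusted-R-squared rule
#'
#' For each k the first k path features are refit by ordinary least
#' squares on the training set and adjusted R-squared is evaluated on the
#' training and test sets. The chosen k* is the largest k such that the
#' test adjR2 strictly increased at every step up to k -- i.e. the first
#' local maximum of the held-out trace, where adding features stops
#' helping and redundancy/overfitting sets in.
#'
#' @param path a [SelectionPath-class] from [lassoOrder()].
#' @param train,test data frames containing the path features and target.
#' @param target response column name.
#' @return List with `k`, `features` (the selected set), and the updated
#'   `path` carrying the per-k adjR2 traces.
#' @export
selectFeatureCount <- function(path, train, test, target) {
  stopifnot(is(path, "SelectionPath"))
  feats <- path@featureOrder
  kMax <- length(feats)
  if (kMax < 1) stop("empty selection path")
  tr <- matrix(NA_real_, kMax, 2)
  for (k in seq_len(kMax))
    tr[k, ] <- .olsAdjR2(train, test, feats[seq_len(k)], target)
  kStar <- 1L
  while (kStar < kMax && tr[kStar + 1, 2] > tr[kStar, 2]) kStar <- kStar + 1L
  path@adjR2Train <- tr[, 1]
  path@adjR2Test <- tr[, 2]
  list(k = kStar, features = feats[seq_len(kStar)], path = path)
}

#' Fit an imaging indicator of the optic disc (IOD)
#'
#' Ordinary least squares of choroidal thickness (um) on the selected
#' features standardised with training-set means and standard deviations.
#' The indicator is the fitted value divided by 10, in 10-um units, so on
#' the training set mean(IOD) x 10 equals mean(ChT).
#'
#' @param train training data frame.
#' @param features character vector of selected feature names.
#' @param target `"mChT"` or `"pChT"` (column of `train`).
#' @return An [IODModel-class].
#' @export
fitIod <- function(train, features, target = c("mChT", "pChT")) {
  target <- match.arg(target)
  missing <- setdiff(features, names(train))
  if (length(missing))
    stop("selected feature(s) absent from table: ",
         paste(missing, collapse = ", "))
  X <- as.matrix(train[, features, drop = FALSE])
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  if (any(sdv == 0))
    stop("zero-variance selected feature(s): ",
         paste(features[sdv == 0], collapse = ", "))
  Xs <- scale(X, center = mu, scale = sdv)
  y <- train[[target]]
  qrX <- qr(cbind(1, Xs))
  if (qrX$rank < ncol(Xs) + 1)
    stop("rank-deficient (collinear) selected feature set: ",
         paste(features, collapse = ", "))
  cf <- qr.coef(qrX, y)
  new("IODModel", target = target, featureNames = features,
      center = stats::setNames(as.numeric(mu), features),
      scaleSd = stats::setNames(as.numeric(sdv), features),
      coefficients = stats::setNames(as.numeric(cf[-1]), features),
      intercept = as.numeric(cf[1]), unit = "10um")
}

#' Predict the IOD for new cases
#'
#' Standardises the model features with the stored training parameters,
#' applies the coefficients and divides by 10.
#'
#' @param model an [IODModel-class].
#' @param features named numeric vector, or a data frame with one row per
#'   case, containing every model feature.
#' @return Numeric IOD value(s) in 10-um units.
#' @export
predictIod <- function(model, features) {
  stopifnot(is(model, "IODModel"))
  if (is.numeric(features) && !is.null(names(features)))
    features <- as.data.frame(as.list(features))
  missing <- setdiff(model@featureNames, names(features))
  if (length(missing))
    stop("missing model feature(s): ", paste(missing, collapse = ", "))
  X <- as.matrix(features[, model@featureNames, drop = FALSE])
  Xs <- sweep(sweep(X, 2, model@center), 2, model@scaleSd, "/")
  as.numeric(model@intercept + Xs %*% model@coefficients) / 10
}

#' Published six-feature IOD templates
#'
#' The two six-feature sets selected in the source cohort, shipped as
#' named templates so the same feature sets can be refit on new data (the
#' original cohort's coefficients are not distributed). Feature names
#' follow the package's `<ROI>_<channel>_<operator>` scheme.
#'
#' @return Named list with `IOD_mChT` and `IOD_pChT` character vectors.
#' @export
iodTemplates <- function() {
  list(
    IOD_mChT = c("PPA_width", "disc_fovea_distance", "OT_A_skewness",
                 "IT_L_range", "OT_A_range", "OT_B_range"),
    IOD_pChT = c("PPA_perimeter", "I_B_skewness", "OT_A_skewness",
                 "IT_L_range", "OT_A_range", "OT_B_range"))
}
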