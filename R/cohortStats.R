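## Evaluation statistics: clinical derivations and eligibility, Spearman
## and sex/age-adjusted partial correlations, multivariate regression
## reports with standardised coefficients, train/test comparison, and
## axial-length stratification. Two-sided p-values throughout; no
## multiple-testing correction is applied (none is used in this design).

#' Derive clinical quantities and eligibility
#'
#' Completes mean arterial pressure MAP = (SBP + 2 DBP)/3 and spherical
#' equivalent SER = sphere + cylinder/2, assigns the axial-length stratum
#' (1: AL < 24 mm; 2: 24 <= AL < 26 mm; 3: AL >= 26 mm, high myopia) and
#' flags eligibility: age between 16 and 40 years, SER < 0.5 D and
#' IOP <= 21 mm Hg.
#'
#' @param records data frame with columns `age`, `iop`, `al`, and either
#'   `map` or `sbp`+`dbp`, and either `ser` or `sphere`+`cylinder`.
#' @return The data frame with `map`, `ser`, `alStratum` and `eligible`
#'   columns filled in.
#' @export
deriveClinical <- function(records) {
  need <- c("age", "iop", "al")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing required field(s): ", paste(miss, collapse = ", "))
  if (!("map" %in% names(records))) {
    if (!all(c("sbp", "dbp") %in% names(records)))
      stop("missing required field(s): sbp, dbp (or map)")
    records$map <- (records$sbp + 2 * records$dbp) / 3
  }
  if (!("ser" %in% names(records))) {
    if (!all(c("sphere", "cylinder") %in% names(records)))
      stop("missing required field(s): sphere, cylinder (or ser)")
    records$ser <- records$sphere + records$cylinder / 2
  }
  records$alStratum <- ifelse(records$al < 24, 1L,
                              ifelse(records$al < 26, 2L, 3L))
  records$eligible <- records$age >= 16 & records$age <= 40 &
    records$ser < 0.5 & records$iop <= 21
  records
}

#' Spearman rank correlation with two-sided p-value
#'
#' Average ranks for ties; the p-value is the usual large-sample
#' approximation (two-sided).
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return List with `r` and `p`.
#' @export
spearmanCor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("spearmanCor needs two equal-length vectors with n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Partial correlation given covariates
#'
#' Correlation of the residuals of `x` and `y` after ordinary
#' least-squares adjustment for the covariates (by default sex and age in
#' the enclosing analyses); the two-sided p-value uses
#' n - 2 - #covariates degrees of freedom.
#'
#' @param x,y numeric vectors.
#' @param covariates data frame or matrix of adjustment variables (may
#'   have zero columns, in which case the plain Pearson correlation is
#'   returned).
#' @return List with `r` and `p`.
#' @export
partialCorrelation <- function(x, y, covariates) {
  covariates <- as.data.frame(covariates)
  k <- ncol(covariates)
  n <- length(x)
  if (n <= k + 2) stop("too few observations for partial correlation")
  if (k == 0) {
    rx <- x; ry <- y
  } else {
    Z <- stats::model.matrix(~ ., data = covariates)
    if (qr(Z)$rank < ncol(Z)) stop("collinear covariates")
    rx <- stats::lm.fit(Z, x)$residuals
    ry <- stats::lm.fit(Z, y)$residuals
  }
  ## a variable fully explained by the covariates has (numerically) zero
  ## residual variance: its partial correlation is 0 by convention
  if (stats::sd(rx) < 1e-10 * max(1e-12, stats::sd(x)) ||
      stats::sd(ry) < 1e-10 * max(1e-12, stats::sd(y)))
    return(list(r = 0, p = 1))
  r <- stats::cor(rx, ry)
  df <- n - 2 - k
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df))
}

#' Multivariate regression report with standardised coefficients
#'
#' Ordinary least squares of the response on the predictors (plus
#' covariates), reporting for each predictor the raw coefficient B, the
#' standardised coefficient beta = B sd(x)/sd(y) and the two-sided
#' p-value, together with the model's adjusted R-squared and n. This is
#' the report format used when assessing the independent association of
#' an indicator with choroidal thickness, overall and per AL stratum.
#'
#' @param y numeric response.
#' @param predictors data frame of predictors of interest.
#' @param covariates optional data frame of adjustment covariates
#'   (reported too, e.g. age and sex).
#' @return List with `table` (term, B, beta, p), `adjR2`, `r2`, `n`.
#' @export
olsReport <- function(y, predictors, covariates = NULL) {
  df <- as.data.frame(predictors)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0)
    df <- cbind(as.data.frame(covariates), df)
  num <- as.data.frame(lapply(df, function(col) {
    if (is.numeric(col)) col else as.numeric(factor(col))
  }))
  X <- as.matrix(num)
  n <- length(y)
  p <- ncol(X)
  qrX <- qr(cbind(`(Intercept)` = 1, X))
  if (qrX$rank < p + 1) stop("rank-deficient design matrix")
  fit <- stats::lm(y ~ ., data = num)
  sm <- summary(fit)
  B <- stats::coef(fit)[-1]
  beta <- B * apply(X, 2, stats::sd) / stats::sd(y)
  tab <- data.frame(term = names(B), B = unname(B), beta = unname(beta),
                    p = unname(sm$coefficients[-1, 4]),
                    stringsAsFactors = FALSE)
  r2 <- sm$r.squared
  a2 <- adjustedR2(r2, n, p)
  stopifnot(isTRUE(all.equal(a2, sm$adj.r.squared)))  # closed form agrees
  list(table = tab, adjR2 = a2, r2 = r2, n = n)
}

#' Compare training and test sets variable by variable
#'
#' Continuous variables: mean +/- sd per set and Student's two-sample
#' t-test (equal variances); categorical variables: counts and the
#' chi-squared test without continuity correction; each continuous
#' variable also gets a Kolmogorov-Smirnov normality flag on the pooled
#' standardised values. Layout mirrors a cohort-characteristics table.
#'
#' @param train,test data frames.
#' @param variables character vector of column names to compare.
#' @return Data frame with one row per variable.
#' @export
compareTrainTest <- function(train, test, variables) {
  if (!nrow(train) || !nrow(test)) stop("both sets must be non-empty")
  rows <- lapply(variables, function(v) {
    a <- train[[v]]; b <- test[[v]]
    if (is.numeric(a)) {
      if (stats::sd(c(a, b)) == 0)
        stop("zero-variance continuous variable: ", v)
      tt <- stats::t.test(a, b, var.equal = TRUE)
      ks <- suppressWarnings(stats::ks.test(scale(c(a, b)), "pnorm"))
      data.frame(variable = v, type = "continuous",
                 train = sprintf("%.2f ± %.2f", mean(a), stats::sd(a)),
                 test = sprintf("%.2f ± %.2f", mean(b), stats::sd(b)),
                 p = tt$p.value, ksNormalP = ks$p.value,
                 stringsAsFactors = FALSE)
    } else {
      tab <- rbind(table(factor(a)), table(factor(b, levels = levels(factor(a)))))
      cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      data.frame(variable = v, type = "categorical",
                 train = paste(table(factor(a)), collapse = "/"),
                 test = paste(table(factor(b, levels = levels(factor(a)))),
                              collapse = "/"),
                 p = cs$p.value, ksNormalP = NA_real_,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Evaluate an IOD on the test set
#'
#' Spearman correlation (r, p) between the predicted indicator and each
#' requested clinical/imaging variable in the held-out set, plus the
#' simple linear (Pearson) R-squared between the indicator and its own
#' target.
#'
#' @param model an [IODModel-class].
#' @param test held-out data frame containing the model features, the
#'   target and the evaluation variables.
#' @param variables character vector of columns to correlate against
#'   (default: both ChT targets and the validated disc features present).
#' @return List with `table` (variable, r, p), `r2Target`, and the
#'   predicted `iod` values.
#' @export
evaluateIod <- function(model, test,
                        variables = intersect(c("mChT", "pChT", "al",
                                                "PPA_area", "ovality_index",
                                                "torsion_angle"),
                                              names(test))) {
  iod <- predictIod(model, test)
  miss <- setdiff(variables, names(test))
  if (length(miss)) stop("missing variable(s): ", paste(miss, collapse = ", "))
  tab <- do.call(rbind, lapply(variables, function(v) {
    sc <- spearmanCor(iod, test[[v]])
    data.frame(variable = v, r = sc$r, p = sc$p, stringsAsFactors = FALSE)
  }))
  r2 <- stats::cor(iod, test[[model@target]])^2
  list(table = tab, r2Target = r2, iod = iod)
}
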