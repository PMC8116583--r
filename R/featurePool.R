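## Radiomic feature pool over CIELAB channels of the annotated ROIs.
## Families and definitions follow the public radiomics standard: 19
## first-order statistics, 10 2D shape descriptors, 24 GLCM, 16 GLRLM,
## 16 GLSZM, 5 NGTDM and 14 GLDM texture features. Texture matrices are
## built at distance 1 (Chebyshev neighbourhoods for NGTDM/GLDM), with
## features averaged over the four 2D directions for GLCM/GLRLM.
## Degenerate conventions on constant regions: skewness 0, kurtosis 0,
## GLCM correlation 1.

.texDirections <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))

#' Convert an 8-bit sRGB fundus photograph to CIELAB channels
#'
#' Standard sRGB to CIELAB conversion under the D65 white point. Accepts
#' an H x W x 3 array either in [0, 1] or as 0-255 intensities.
#'
#' @param image numeric H x W x 3 array.
#' @return List of numeric matrices `L` (0-100), `A`, `B`.
#' @export
rgbToLab <- function(image) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3)
    stop("image must be a 3-channel (H x W x 3) RGB array")
  v <- matrix(as.numeric(image), ncol = 3)
  if (max(v) > 1) v <- v / 255
  lab <- grDevices::convertColor(v, from = "sRGB", to = "Lab")
  list(L = matrix(lab[, 1], d[1], d[2]),
       A = matrix(lab[, 2], d[1], d[2]),
       B = matrix(lab[, 3], d[1], d[2]))
}

#' Affinely rescale a channel to the 0-255 range
#'
#' Applied to each LAB channel before fixed-bin-width discretisation so
#' that one bin width serves all channels. A constant channel maps to 0.
#'
#' @param ch numeric matrix.
#' @return numeric matrix in [0, 255].
#' @export
rescaleChannel <- function(ch) {
  rng <- range(ch)
  if (diff(rng) == 0) return(matrix(0, nrow(ch), ncol(ch)))
  (ch - rng[1]) / diff(rng) * 255
}

#' Fixed-bin-width discretisation of masked channel values
#'
#' Level i covers the half-open interval [min + (i-1) w, min + i w) with
#' the minimum taken over the masked pixels; a value exactly at
#' min + k w falls in level k + 1.
#'
#' @param ch numeric matrix of channel values.
#' @param mask logical matrix; pixels outside are set to `NA`.
#' @param binWidth positive bin width (default 25 on 0-255 channels).
#' @return Integer matrix of levels with `NA` outside the mask, with
#'   attribute `nLevels`.
#' @export
discretizeChannel <- function(ch, mask, binWidth = 25) {
  if (binWidth <= 0) stop("binWidth must be positive")
  if (!any(mask)) stop("mask is empty")
  v <- ch[mask]
  lev <- matrix(NA_integer_, nrow(ch), ncol(ch))
  lev[mask] <- as.integer(floor((v - min(v)) / binWidth)) + 1L
  attr(lev, "nLevels") <- max(lev, na.rm = TRUE)
  lev
}

#' First-order (histogram) statistics of an ROI
#'
#' The 19 standard first-order features of the masked intensity values.
#' Moments are population (biased) moments; entropy and uniformity are
#' computed on the fixed-bin-width discretised histogram; `total_energy`
#' weights `energy` by the pixel area. Skewness and kurtosis of a constant
#' region are 0 by convention.
#'
#' @param ch numeric matrix of channel values.
#' @param mask logical matrix with at least 2 `TRUE` pixels.
#' @param binWidth discretisation bin width for entropy/uniformity.
#' @param pixelAreaMm2 area of one pixel in mm^2 (for `total_energy`).
#' @param levels optional pre-computed discretised levels of the masked
#'   pixels (used for entropy/uniformity instead of re-binning `ch`).
#' @return Named numeric vector of 19 features.
#' @export
firstOrderFeatures <- function(ch, mask, binWidth = 25, pixelAreaMm2 = 1,
                               levels = NULL) {
  v <- ch[mask]
  n <- length(v)
  if (n < 2) stop("first-order features need at least 2 masked pixels")
  m <- mean(v)
  m2 <- mean((v - m)^2)
  m3 <- mean((v - m)^3)
  m4 <- mean((v - m)^4)
  qs <- unname(stats::quantile(v, c(0.10, 0.25, 0.75, 0.90), type = 7))
  mid <- v[v >= qs[1] & v <= qs[4]]
  if (is.null(levels)) levels <- floor((v - min(v)) / binWidth)
  p <- tabulate(as.integer(levels) + 1L) / n
  p <- p[p > 0]
  c(energy = sum(v^2),
    total_energy = pixelAreaMm2 * sum(v^2),
    entropy = -sum(p * log2(p)),
    minimum = min(v),
    p10 = qs[1],
    p90 = qs[4],
    maximum = max(v),
    mean = m,
    median = stats::median(v),
    iqr = qs[3] - qs[2],
    range = max(v) - min(v),
    mad = mean(abs(v - m)),
    rmad = if (length(mid)) mean(abs(mid - mean(mid))) else 0,
    rms = sqrt(mean(v^2)),
    sd = sqrt(m2),
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    variance = m2,
    uniformity = sum(p^2))
}

## Marching-squares area of a binary mask on the 0.5 iso-contour through
## pixel-centre midpoints (per-2x2-cell contributions precomputed for the
## 16 binary cases, saddles split into two opposite corner cuts), plus a
## Cauchy-Crofton boundary length over four line directions -- an
## isotropic perimeter estimator, unlike the staircase-biased iso-contour
## length.
.maskAreaPerimeter <- function(mask) {
  m <- mask * 1
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 2 || nc < 2) return(list(area = sum(m), perimeter = 4 * sum(m)))
  tl <- m[-nr, -nc]; tr <- m[-nr, -1]; bl <- m[-1, -nc]; br <- m[-1, -1]
  code <- tl + 2 * tr + 4 * bl + 8 * br + 1
  areaTab <- c(0, 1/8, 1/8, 1/2, 1/8, 1/2, 1/4, 7/8,
               1/8, 1/4, 1/2, 7/8, 1/2, 7/8, 7/8, 1)
  n <- tabulate(code, 16)
  edge <- sum(m[1, ]) + sum(m[nr, ]) + sum(m[, 1]) + sum(m[, nc])
  corner <- m[1, 1] + m[1, nc] + m[nr, 1] + m[nr, nc]
  ## Crofton: transition counts along rows, columns and both diagonals
  th <- sum(abs(m[, -1] - m[, -nc])) + sum(m[, 1]) + sum(m[, nc])
  tv <- sum(abs(m[-1, ] - m[-nr, ])) + sum(m[1, ]) + sum(m[nr, ])
  td1 <- sum(abs(br - tl)) + sum(m[1, ]) + sum(m[nr, ]) +
    sum(m[-1, 1]) + sum(m[-nr, nc])
  td2 <- sum(abs(bl - tr)) + sum(m[1, ]) + sum(m[nr, ]) +
    sum(m[-1, nc]) + sum(m[-nr, 1])
  list(area = sum(n * areaTab) + edge / 2 - corner / 4,
       perimeter = pi / 8 * (th + tv + (td1 + td2) / sqrt(2)))
}

#' 2D shape features of a binary ROI mask
#'
#' The 10 standard 2D shape descriptors in millimetre units. The mesh
#' surface comes from the marching-squares 0.5 iso-contour of the mask;
#' the perimeter uses the Cauchy-Crofton estimate over four line
#' directions (isotropic, unlike the staircase-biased contour length);
#' the maximum diameter is the largest pairwise distance between boundary
#' pixels; axis lengths are 4 sqrt(lambda) from the principal component
#' analysis of pixel-centre coordinates.
#'
#' @param mask logical matrix, non-empty.
#' @param mag a [MagnificationModel-class].
#' @return Named numeric vector of 10 features (lengths mm, areas mm^2).
#' @export
shape2DFeatures <- function(mask, mag) {
  if (!any(mask)) stop("shape features of an empty mask")
  s <- mag@scale
  npx <- sum(mask)
  ms <- .maskAreaPerimeter(mask)
  area <- ms$area * s^2
  per <- ms$perimeter * s
  idx <- which(mask, arr.ind = TRUE)
  xy <- cbind(idx[, 2] - 1, idx[, 1] - 1) * s
  ## boundary pixels only, via convex hull, for the maximum diameter
  hull <- grDevices::chull(xy)
  hxy <- xy[hull, , drop = FALSE]
  maxd <- if (nrow(hxy) > 1) max(stats::dist(hxy)) else 0
  if (npx > 1) {
    ev <- eigen(stats::cov(xy) * (npx - 1) / npx, symmetric = TRUE)$values
    ev[ev < 0] <- 0
  } else ev <- c(0, 0)
  c(mesh_surface = area,
    pixel_surface = npx * s^2,
    perimeter = per,
    perimeter_surface_ratio = per / area,
    sphericity = 2 * sqrt(pi * area) / per,
    spherical_disproportion = per / (2 * sqrt(pi * area)),
    maximum_diameter = maxd,
    major_axis_length = 4 * sqrt(ev[1]),
    minor_axis_length = 4 * sqrt(ev[2]),
    elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1)
}

## ---- GLCM -----------------------------------------------------------

.glcmFromMatrix <- function(P, nLevels) {
  tot <- sum(P)
  if (tot == 0) stop("GLCM has no co-occurring pairs")
  p <- P / tot
  i <- row(p); j <- col(p)
  px <- rowSums(p)
  mu <- sum(i * p)
  sig2 <- sum((i - mu)^2 * p)
  ## difference and sum distributions
  dk <- 0:(nLevels - 1)
  pdiff <- vapply(dk, function(k) sum(p[abs(i - j) == k]), 0)
  sk <- 2:(2 * nLevels)
  psum <- vapply(sk, function(k) sum(p[(i + j) == k]), 0)
  da <- sum(dk * pdiff)
  eps <- .Machine$double.eps
  H <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  hx <- H(px)
  hxy <- H(p)
  pxy <- outer(px, px)
  hxy1 <- -sum(p[pxy > 0] * log2(pxy[pxy > 0]))
  hxy2 <- H(pxy)
  corr <- if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else 1
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2v <- 1 - exp(-2 * (hxy2 - hxy))
  ## MCC: second largest eigenvalue of Q
  if (nLevels > 1 && all(px > 0)) {
    ## Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) px(k))
    Q <- (p / px) %*% t(sweep(p, 2, px, "/"))
    lam <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(max(0, lam[2]))
  } else mcc <- 1
  offd <- abs(i - j) > 0
  c(autocorrelation = sum(i * j * p),
    joint_average = mu,
    cluster_prominence = sum((i + j - 2 * mu)^4 * p),
    cluster_shade = sum((i + j - 2 * mu)^3 * p),
    cluster_tendency = sum((i + j - 2 * mu)^2 * p),
    contrast = sum((i - j)^2 * p),
    correlation = corr,
    difference_average = da,
    difference_entropy = H(pdiff),
    difference_variance = sum((dk - da)^2 * pdiff),
    joint_energy = sum(p^2),
    joint_entropy = hxy,
    imc1 = imc1,
    imc2 = if (imc2v > 0) sqrt(imc2v) else 0,
    idm = sum(p / (1 + (i - j)^2)),
    idmn = sum(p / (1 + ((i - j) / nLevels)^2)),
    id = sum(p / (1 + abs(i - j))),
    idn = sum(p / (1 + abs(i - j) / nLevels)),
    inverse_variance = sum(p[offd] / (i - j)[offd]^2),
    maximum_probability = max(p),
    sum_average = sum(sk * psum),
    sum_entropy = H(psum),
    sum_squares = sig2,
    mcc = mcc)
}

#' Grey-level co-occurrence (GLCM) features
#'
#' Symmetric co-occurrence matrices at distance 1 are built for the four
#' 2D directions, normalised, and the 24 standard GLCM features are
#' averaged over directions. On a constant region correlation is 1 by
#' convention.
#'
#' @param levels integer level matrix from [discretizeChannel()].
#' @param nLevels number of grey levels (defaults to the matrix maximum).
#' @return Named numeric vector of 24 features.
#' @export
glcmFeatures <- function(levels, nLevels = max(levels, na.rm = TRUE)) {
  if (all(is.na(levels))) stop("empty mask")
  per <- lapply(.texDirections, function(d) {
    P <- cppGlcm(levels, nLevels, d[1], d[2])
    if (sum(P) == 0) return(NULL)
    .glcmFromMatrix(P, nLevels)
  })
  per <- per[!vapply(per, is.null, TRUE)]
  if (!length(per)) stop("GLCM undefined: no neighbouring pixel pairs in any direction")
  colMeans(do.call(rbind, per))
}

## ---- GLRLM ----------------------------------------------------------

.glrlmFromMatrix <- function(R, np) {
  nr <- sum(R)
  p <- R / nr
  i <- row(R); j <- col(R)
  ri <- rowSums(R); rj <- colSums(R)
  pe <- p[p > 0]
  gl <- sum(i * p)
  rl <- sum(j * p)
  c(sre = sum(p / j^2),
    lre = sum(p * j^2),
    gln = sum(ri^2) / nr,
    glnn = sum(ri^2) / nr^2,
    rln = sum(rj^2) / nr,
    rlnn = sum(rj^2) / nr^2,
    rp = nr / np,
    glv = sum((i - gl)^2 * p),
    rv = sum((j - rl)^2 * p),
    re = -sum(pe * log2(pe)),
    lglre = sum(p / i^2),
    hglre = sum(p * i^2),
    srlgle = sum(p / (i^2 * j^2)),
    srhgle = sum(p * i^2 / j^2),
    lrlgle = sum(p * j^2 / i^2),
    lrhgle = sum(p * i^2 * j^2))
}

## ---- shared size/dependence-style feature set -----------------------

## Size-zone features from per-zone (level, size) pairs, one row per zone.
.szFromPairs <- function(i, j, np) {
  nz <- length(i)
  ni <- tabulate(i)
  cellId <- (i - 1) * (max(j) + 1) + j
  ncell <- tabulate(match(cellId, unique(cellId)))
  pe <- ncell / nz
  nj <- tabulate(j)
  gl <- mean(i); sz <- mean(j)
  out <- c(mean(1 / j^2), mean(j^2),
           sum(ni^2) / nz, sum(ni^2) / nz^2,
           sum(nj^2) / nz, sum(nj^2) / nz^2,
           nz / np,
           mean((i - gl)^2), mean((j - sz)^2),
           -sum(pe * log2(pe)),
           mean(1 / i^2), mean(i^2),
           mean(1 / (i^2 * j^2)), mean(i^2 / j^2),
           mean(j^2 / i^2), mean(i^2 * j^2))
  names(out) <- c("sae", "lae", "gln", "glnn", "szn", "sznn",
                  "zp", "glv", "zv", "ze", "lglze", "hglze",
                  "salgle", "sahgle", "lalgle", "lahgle")
  out
}

.ngtdmFeatures <- function(acc, nLevels) {
  ni <- acc[, 1]; si <- acc[, 2]
  N <- sum(ni)
  if (N == 0) stop("NGTDM undefined: no pixel has an in-mask neighbour")
  p <- ni / N
  act <- which(p > 0)
  ngp <- length(act)
  ivals <- seq_len(nLevels)
  sps <- sum(p * si)
  coarseness <- if (sps > 0) 1 / sps else 1e6
  if (ngp > 1) {
    pij <- outer(p[act], p[act])
    dij <- outer(ivals[act], ivals[act], "-")
    contrast <- sum(pij * dij^2) / (ngp * (ngp - 1)) * sum(si) / N
    den <- sum(abs(outer(ivals[act] * p[act], ivals[act] * p[act], "-")))
    busyness <- if (den > 0) sps / den else 0
    num <- outer(p[act] * si[act], p[act] * si[act], "+")
    complexity <- sum(abs(dij) * num / outer(p[act], p[act], "+")) / N
    strength <- if (sum(si) > 0)
      sum(outer(p[act], p[act], "+") * dij^2) / sum(si) else 0
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  c(coarseness = coarseness, contrast = contrast, busyness = busyness,
    complexity = complexity, strength = strength)
}

.gldmFromMatrix <- function(P, np) {
  keep <- which(colSums(P) > 0)
  if (!length(keep)) stop("empty GLDM")
  P <- P[, seq_len(max(keep)), drop = FALSE]
  nz <- sum(P)
  p <- P / nz
  i <- row(P); j <- col(P)
  ri <- rowSums(P); cj <- colSums(P)
  pe <- p[p > 0]
  gl <- sum(i * p)
  dep <- sum(j * p)
  c(sde = sum(p / j^2),
    lde = sum(p * j^2),
    gln = sum(ri^2) / nz,
    dn = sum(cj^2) / nz,
    dnn = sum(cj^2) / nz^2,
    glv = sum((i - gl)^2 * p),
    dv = sum((j - dep)^2 * p),
    de = -sum(pe * log2(pe)),
    lgle = sum(p / i^2),
    hgle = sum(p * i^2),
    sdlgle = sum(p / (i^2 * j^2)),
    sdhgle = sum(p * i^2 / j^2),
    ldlgle = sum(p * j^2 / i^2),
    ldhgle = sum(p * i^2 * j^2))
}

#' Texture-matrix features: GLRLM, GLSZM, NGTDM and GLDM families
#'
#' Builds the requested family matrix from a discretised ROI and returns
#' its standard feature set: 16 run-length features (runs along the four
#' 2D directions, features averaged), 16 size-zone features (zones by
#' 8-connectivity), 5 neighbourhood-tone-difference features and 14
#' dependence features (both with Chebyshev-1 neighbourhoods; GLDM
#' dependence counts the centre pixel plus its alpha = 0 dependent
#' neighbours). Masked-out neighbours are ignored everywhere.
#'
#' @inheritParams glcmFeatures
#' @param family one of `"GLRLM"`, `"GLSZM"`, `"NGTDM"`, `"GLDM"`.
#' @return Named numeric vector (16, 16, 5 or 14 features).
#' @export
textureMatrixFeatures <- function(levels, family,
                                  nLevels = max(levels, na.rm = TRUE)) {
  family <- match.arg(family, c("GLRLM", "GLSZM", "NGTDM", "GLDM"))
  np <- sum(!is.na(levels))
  if (np == 0) stop("empty mask")
  switch(family,
    GLRLM = {
      per <- lapply(.texDirections, function(d) {
        R <- cppGlrlm(levels, nLevels, d[1], d[2])
        used <- which(colSums(R) > 0)
        .glrlmFromMatrix(R[, seq_len(max(used)), drop = FALSE], np)
      })
      colMeans(do.call(rbind, per))
    },
    GLSZM = {
      z <- cppZones(levels)
      .szFromPairs(z[, 1], z[, 2], np)
    },
    NGTDM = .ngtdmFeatures(cppNgtdm(levels, nLevels), nLevels),
    GLDM = {
      ## cppGldm column k+1 holds the count of pixels with k dependent
      ## neighbours; with the centre counted the dependence is j = k + 1,
      ## which is exactly that column's index.
      .gldmFromMatrix(cppGldm(levels, nLevels, 0L), np)
    })
}

#' Assemble the full per-case feature vector
#'
#' Computes the geometric block (ovality index, torsion angle, PPA area,
#' width, perimeter, disc-fovea distance) and, for each ROI (D, I, IT, OT)
#' and each CIELAB channel, the 19 first-order plus 24 GLCM, 16 GLRLM,
#' 16 GLSZM, 5 NGTDM and 14 GLDM texture features (94 per ROI x channel),
#' plus 10 channel-independent shape features per ROI. Intensity and
#' texture features are named `<ROI>_<channel>_<operator>` (for example
#' `IT_L_range`, `OT_A_skewness`); texture operators carry their family
#' prefix. Channels are affinely rescaled to 0-255 before fixed-bin-width
#' discretisation. An ROI left empty (fewer than 2 pixels) flags the case:
#' its features are `NA` and the returned vector carries attributes
#' `flagged = TRUE` and `flagReason`.
#'
#' @param image H x W x 3 RGB array.
#' @param annotation a [FundusAnnotation-class].
#' @param masks a [ROIMaskSet-class] from [buildRoiMasks()].
#' @param mag a [MagnificationModel-class].
#' @param binWidth texture discretisation bin width on the 0-255 scale.
#' @return Named numeric vector with a deterministic ordering.
#' @export
extractPool <- function(image, annotation, masks, mag, binWidth = 25) {
  lab <- rgbToLab(image)
  dg <- discShapeMetrics(annotation, mag)
  pg <- ppaMetrics(annotation, mag)
  out <- c(ovality_index = dg$ovalityIndex,
           torsion_angle = dg$torsionAngle,
           PPA_area = pg$area,
           PPA_width = pg$width,
           PPA_perimeter = pg$perimeter,
           disc_fovea_distance = pg$discFoveaDistance)
  flagged <- FALSE; reasons <- character()
  famPrefix <- c(GLRLM = "glrlm_", GLSZM = "glszm_",
                 NGTDM = "ngtdm_", GLDM = "gldm_")
  for (roi in c("D", "I", "IT", "OT")) {
    mk <- roiMask(masks, roi)
    emptyRoi <- sum(mk) < 2
    if (emptyRoi) { flagged <- TRUE; reasons <- c(reasons, paste0("empty ROI ", roi)) }
    sh <- if (emptyRoi) stats::setNames(rep(NA_real_, 10),
            names(shape2DFeatures(matrix(TRUE, 2, 2), mag)))
          else shape2DFeatures(mk, mag)
    names(sh) <- paste0(roi, "_shape_", names(sh))
    out <- c(out, sh)
    for (chn in c("L", "A", "B")) {
      if (emptyRoi) {
        blk <- rep(NA_real_, 94)
        names(blk) <- .poolBlockNames(roi, chn)
      } else {
        ## discretisation is ROI-local: masked values affinely rescaled to
        ## 0-255, then fixed bin width -- so features of one ROI never
        ## depend on pixels outside it
        ch <- lab[[chn]]
        v <- ch[mk]
        rng <- range(v)
        rs <- matrix(0, nrow(ch), ncol(ch))
        rs[mk] <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) * 255 else 0
        lev <- discretizeChannel(rs, mk, binWidth)
        nl <- attr(lev, "nLevels")
        ## first-order statistics on the raw CIELAB values; only their
        ## entropy/uniformity come from the discretised levels
        fo <- firstOrderFeatures(ch, mk, binWidth, mag@scale^2,
                                 levels = lev[mk])
        tx <- c(glcmFeatures(lev, nl),
                unlist(lapply(names(famPrefix), function(f) {
                  v <- textureMatrixFeatures(lev, f, nl)
                  names(v) <- paste0(famPrefix[f], names(v))
                  v
                })))
        names(tx)[1:24] <- paste0("glcm_", names(tx)[1:24])
        blk <- c(fo, tx)
        names(blk) <- paste0(roi, "_", chn, "_", names(blk))
      }
      out <- c(out, blk)
    }
  }
  if (flagged) {
    attr(out, "flagged") <- TRUE
    attr(out, "flagReason") <- paste(reasons, collapse = "; ")
  }
  out
}

.poolBlockNames <- function(roi, chn) {
  fo <- c("energy", "total_energy", "entropy", "minimum", "p10", "p90",
          "maximum", "mean", "median", "iqr", "range", "mad", "rmad", "rms",
          "sd", "skewness", "kurtosis", "variance", "uniformity")
  glcm <- paste0("glcm_", c("autocorrelation", "joint_average",
    "cluster_prominence", "cluster_shade", "cluster_tendency", "contrast",
    "correlation", "difference_average", "difference_entropy",
    "difference_variance", "joint_energy", "joint_entropy", "imc1", "imc2",
    "idm", "idmn", "id", "idn", "inverse_variance", "maximum_probability",
    "sum_average", "sum_entropy", "sum_squares", "mcc"))
  glrlm <- paste0("glrlm_", c("sre", "lre", "gln", "glnn", "rln", "rlnn",
    "rp", "glv", "rv", "re", "lglre", "hglre", "srlgle", "srhgle",
    "lrlgle", "lrhgle"))
  glszm <- paste0("glszm_", c("sae", "lae", "gln", "glnn", "szn", "sznn",
    "zp", "glv", "zv", "ze", "lglze", "hglze", "salgle", "sahgle",
    "lalgle", "lahgle"))
  ngtdm <- paste0("ngtdm_", c("coarseness", "contrast", "busyness",
    "complexity", "strength"))
  gldm <- paste0("gldm_", c("sde", "lde", "gln", "dn", "dnn", "glv", "dv",
    "de", "lgle", "hgle", "sdlgle", "sdhgle", "ldlgle", "ldhgle"))
  paste0(roi, "_", chn, "_", c(fo, glcm, glrlm, glszm, ngtdm, gldm))
}
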