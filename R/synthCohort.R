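## Synthetic cohort generator. Samples subjects whose clinical and
## morphometric marginals match the study cohort (axial length
## 25.51 +/- 1.34 mm, ovality 0.79 +/- 0.10, torsion 4.98 +/- 19.78 deg,
## PPA area 0.68 +/- 0.63 mm^2, mChT 211.00 +/- 62.03 um, pChT
## 143.33 +/- 45.58 um) and renders disc-centred fundus photographs in
## which a latent "atrophy factor" couples thin choroid to brighter,
## higher-contrast temporal peripapillary intensity.

#' Parameters of the synthetic cohort
#'
#' Defaults reproduce the study cohort's marginal means and standard
#' deviations. `signalFraction` is the fraction of choroidal-thickness
#' variance carried by the latent atrophy factor that also drives the
#' planted temporal image intensities; `alChtSlopeUmPerMm` is the
#' choroidal thinning per millimetre of axial elongation.
#'
#' @param nSubjects number of subjects (>= 2).
#' @param seed RNG seed.
#' @param alMeanMm,alSdMm axial length distribution, mm.
#' @param ovalityMean,ovalitySd ovality index; samples truncated to (0.4, 1].
#' @param torsionMeanDeg,torsionSdDeg torsion angle, degrees.
#' @param ppaAreaMeanMm2,ppaAreaSdMm2 PPA area, mm^2 (lognormal, matched
#'   moments, so samples stay positive).
#' @param mchtMeanUm,mchtSdUm macular choroidal thickness, um.
#' @param pchtMeanUm,pchtSdUm peripapillary choroidal thickness, um.
#' @param signalFraction in [0, 1].
#' @param alChtSlopeUmPerMm choroidal thinning slope against AL, um/mm.
#' @return Validated list of class `CohortParams`.
#' @export
cohortParams <- function(nSubjects = 300, seed = 1,
                         alMeanMm = 25.51, alSdMm = 1.34,
                         ovalityMean = 0.79, ovalitySd = 0.10,
                         torsionMeanDeg = 4.98, torsionSdDeg = 19.78,
                         ppaAreaMeanMm2 = 0.68, ppaAreaSdMm2 = 0.63,
                         mchtMeanUm = 211.00, mchtSdUm = 62.03,
                         pchtMeanUm = 143.33, pchtSdUm = 45.58,
                         signalFraction = 0.5, alChtSlopeUmPerMm = 20) {
  p <- list(nSubjects = as.integer(nSubjects), seed = as.integer(seed),
            alMeanMm = alMeanMm, alSdMm = alSdMm,
            ovalityMean = ovalityMean, ovalitySd = ovalitySd,
            torsionMeanDeg = torsionMeanDeg, torsionSdDeg = torsionSdDeg,
            ppaAreaMeanMm2 = ppaAreaMeanMm2, ppaAreaSdMm2 = ppaAreaSdMm2,
            mchtMeanUm = mchtMeanUm, mchtSdUm = mchtSdUm,
            pchtMeanUm = pchtMeanUm, pchtSdUm = pchtSdUm,
            signalFraction = signalFraction,
            alChtSlopeUmPerMm = alChtSlopeUmPerMm)
  if (p$nSubjects < 2) stop("nSubjects must be at least 2")
  sds <- c(p$alSdMm, p$ovalitySd, p$torsionSdDeg, p$ppaAreaSdMm2,
           p$mchtSdUm, p$pchtSdUm)
  if (any(sds < 0)) stop("standard deviations must be non-negative")
  if (p$signalFraction < 0 || p$signalFraction > 1)
    stop("signalFraction must lie in [0, 1]")
  class(p) <- "CohortParams"
  p
}

.truncNorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lo | x[bad] > hi]
  }
  x
}

#' Sample a synthetic cohort with ground truth
#'
#' Draws subjects from the configured marginals. A standard-normal latent
#' atrophy factor m is shared between the planted temporal intensity
#' parameters, the PPA area (Gaussian copula on the lognormal) and --
#' when `signalFraction` > 0 -- choroidal thickness:
#' ChT = mean - slope (AL - meanAL) - sd sqrt(f) m + e, with the residual
#' variance chosen so the marginal ChT variance matches its target (the
#' residual is clamped at zero if the AL slope already exhausts it).
#' Ovality is anti-correlated with axial length through a second copula.
#' Planted per-channel temporal intensity ranges and skewnesses are linear
#' in the (clamped) atrophy factor.
#'
#' @param params a [cohortParams()] object.
#' @return List with `subjects` (clinical data frame) and `truth`
#'   (per-case planted geometry, ChT and intensity parameters).
#' @export
sampleSubjects <- function(params) {
  stopifnot(inherits(params, "CohortParams"))
  set.seed(params$seed)
  n <- params$nSubjects
  zAl <- stats::rnorm(n)
  al <- params$alMeanMm + params$alSdMm * zAl
  m <- stats::rnorm(n)                     # latent atrophy factor
  ## ovality: anti-correlated with AL, truncated to (0.4, 1]
  rhoOv <- 0.5
  zOv <- -rhoOv * zAl + sqrt(1 - rhoOv^2) * stats::rnorm(n)
  ov <- params$ovalityMean + params$ovalitySd * zOv
  bad <- which(ov <= 0.4 | ov > 1)
  while (length(bad)) {
    ov[bad] <- params$ovalityMean + params$ovalitySd *
      (-rhoOv * zAl[bad] + sqrt(1 - rhoOv^2) * stats::rnorm(length(bad)))
    bad <- bad[ov[bad] <= 0.4 | ov[bad] > 1]
  }
  torsion <- .truncNorm(n, params$torsionMeanDeg, params$torsionSdDeg, -90, 90)
  ## PPA area: lognormal with matched mean/sd, coupled to m
  cv2 <- (params$ppaAreaSdMm2 / params$ppaAreaMeanMm2)^2
  sigL <- sqrt(log(1 + cv2))
  muL <- log(params$ppaAreaMeanMm2) - sigL^2 / 2
  rhoP <- 0.6
  ppa <- exp(muL + sigL * (rhoP * m + sqrt(1 - rhoP^2) * stats::rnorm(n)))
  ## choroidal thickness with planted signal
  f <- params$signalFraction
  cht <- function(meanT, sdT, slope) {
    resid2 <- sdT^2 * (1 - f) - slope^2 * params$alSdMm^2
    e <- stats::rnorm(n, 0, sqrt(max(0, resid2)))
    pmax(5, meanT - slope * (al - params$alMeanMm) - sdT * sqrt(f) * m + e)
  }
  mcht <- cht(params$mchtMeanUm, params$mchtSdUm, params$alChtSlopeUmPerMm)
  pcht <- cht(params$pchtMeanUm, params$pchtSdUm,
              params$alChtSlopeUmPerMm * params$pchtSdUm / params$mchtSdUm)
  ## clinical scalars
  age <- stats::runif(n, 16, 40)
  sex <- ifelse(stats::runif(n) < 0.5, "male", "female")
  sbp <- stats::rnorm(n, 115, 10)
  dbp <- stats::rnorm(n, 72, 8)
  iop <- .truncNorm(n, 14.0, 2.83, 7, 21)
  acd <- stats::rnorm(n, 3.60, 0.34)
  ser <- pmin(0.4, -2.2 * (al - 23.6) + stats::rnorm(n, 0, 0.8))
  cylinder <- -abs(stats::rnorm(n, 0.4, 0.3))
  sphere <- ser - cylinder / 2
  bcva <- .truncNorm(n, 0.02, 0.06, -0.2, Inf)
  mret <- stats::rnorm(n, 276.01, 12.72)
  prnflt <- stats::rnorm(n, 91.93, 10.04)
  ## planted rendering geometry
  ld <- .truncNorm(n, 1.80, 0.12, 1.4, 2.2)
  dfd <- .truncNorm(n, 4.50, 0.15, 4.2, 4.8)
  mc <- pmax(-2.5, pmin(2.5, m))
  subjects <- data.frame(
    id = sprintf("case_%04d", seq_len(n)),
    age = age, sex = sex, sbp = sbp, dbp = dbp,
    map = (sbp + 2 * dbp) / 3, iop = iop, acd = acd,
    sphere = sphere, cylinder = cylinder, ser = ser, bcva = bcva,
    al = al, mcht = mcht, pcht = pcht, mret = mret, prnflt = prnflt,
    stringsAsFactors = FALSE)
  truth <- data.frame(
    id = subjects$id,
    mcht = mcht, pcht = pcht,
    discSemiMajorMm = ld / 2, discSemiMinorMm = ld / 2 * ov,
    ovality = ov, torsionDeg = torsion, ppaAreaMm2 = ppa,
    dfdMm = dfd, atrophyFactor = m,
    rangeL = 28 + 7 * mc, rangeA = 10 + 2.5 * mc, rangeB = 14 + 3.5 * mc,
    skewL = pmax(-1.3, pmin(1.3, 0.45 * mc)),
    skewA = pmax(-1.3, pmin(1.3, 0.35 * mc)),
    skewB = pmax(-1.3, pmin(1.3, 0.35 * mc)),
    stringsAsFactors = FALSE)
  list(subjects = subjects, truth = truth)
}

## Exponent gamma such that u^gamma (u uniform) has the requested
## population skewness; gamma = 1 gives skew 0, larger gamma positive skew.
.gammaForSkew <- function(target) {
  skewOf <- function(g) {
    m1 <- 1 / (g + 1); m2 <- 1 / (2 * g + 1); m3 <- 1 / (3 * g + 1)
    v <- m2 - m1^2
    (m3 - 3 * m1 * v - m1^3) / v^1.5
  }
  target <- max(-1.6, min(1.9, target))
  stats::uniroot(function(g) skewOf(g) - target, c(0.02, 60), tol = 1e-9)$root
}

#' Default camera constant for a given image size
#'
#' Chosen so the photograph spans an 11-mm field at the cohort-mean axial
#' length of 25.51 mm, leaving room for the 6-mm ETDRS circle around the
#' disc plus the fovea inside the frame across the plausible AL range.
#'
#' @param imageSizePx image side length, pixels.
#' @return camera constant (mm per pixel per unit Littmann q).
#' @export
defaultCameraConstant <- function(imageSizePx) {
  (11 / imageSizePx) / (0.01306 * (25.51 - 1.82))
}

#' Render one synthetic fundus case
#'
#' Renders a disc-centred pseudo-fundus photograph for a sampled subject:
#' textured background, elliptical disc with the planted semi-axes and
#' torsion, a temporal PPA crescent whose area matches the planted value,
#' 4 to 8 dark vessel arcs with an exact vessel mask, a foveal darkening,
#' and temporal peripapillary pixels whose CIELAB per-channel range and
#' skewness match the planted intensity parameters (up to 8-bit
#' quantisation). Right-eye layout: the fovea lies temporally along +x.
#' Returns the exact rendering contours as the annotation.
#'
#' @param subject one row of the `subjects` data frame.
#' @param truth the matching row of the `truth` data frame.
#' @param imageSizePx side length of the square image (default 1024).
#' @param cameraConstant Littmann camera constant; default from
#'   [defaultCameraConstant()].
#' @param seed per-case RNG seed.
#' @return List with `image` (H x W x 3 array in [0, 1]), `annotation`
#'   (a [FundusAnnotation-class]) and `mag` (the case's
#'   [MagnificationModel-class]).
#' @export
renderFundusCase <- function(subject, truth, imageSizePx = 1024,
                             cameraConstant = defaultCameraConstant(imageSizePx),
                             seed = 1) {
  set.seed(seed)
  W <- H <- as.integer(imageSizePx)
  mag <- littmannScale(subject$al, cameraConstant)
  s <- mag@scale
  if (3.05 / s > W * 0.45 || 3.05 / s > H / 2 - 2)
    stop("6-mm circle does not fit inside the image at this scale")
  cx <- 3.05 / s
  cy <- (H - 1) / 2
  fx <- cx + truth$dfdMm / s
  if (fx > W - 2) stop("fovea does not fit inside the image at this scale")
  ## pixel grids (0-based, x = col, y = row)
  xs <- rep(0:(W - 1), each = H)
  ys <- rep(0:(H - 1), times = W)
  dx <- xs - cx; dy <- ys - cy
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)               # 0 points temporally (+x)
  ## background: warm fundus colour with low-frequency value noise
  noiseField <- function(amplitude, gridN = 9) {
    g <- matrix(stats::runif(gridN * gridN, -1, 1), gridN, gridN)
    gx <- (xs / (W - 1)) * (gridN - 1) + 1
    gy <- (ys / (H - 1)) * (gridN - 1) + 1
    i0 <- pmin(floor(gy), gridN - 1); j0 <- pmin(floor(gx), gridN - 1)
    ty <- gy - i0; tx <- gx - j0
    v <- g[cbind(i0, j0)] * (1 - tx) * (1 - ty) +
      g[cbind(i0, j0 + 1)] * tx * (1 - ty) +
      g[cbind(i0 + 1, j0)] * (1 - tx) * ty +
      g[cbind(i0 + 1, j0 + 1)] * tx * ty
    amplitude * v
  }
  nf <- noiseField(0.04) + stats::rnorm(W * H, 0, 0.01)
  R <- 0.80 + nf; G <- 0.45 + nf * 0.8; B <- 0.28 + nf * 0.6
  ## disc ellipse: long axis tilted by the planted torsion from vertical,
  ## positive torsion tips the superior end nasally (-x; y points down)
  tau <- truth$torsionDeg * pi / 180
  u <- c(-sin(tau), -cos(tau))         # long-axis direction, superior end
  v <- c(-u[2], u[1])
  a <- truth$discSemiMajorMm / s; b <- truth$discSemiMinorMm / s
  tt <- seq(0, 2 * pi, length.out = 129)[-129]
  discContour <- cbind(cx + a * cos(tt) * u[1] + b * sin(tt) * v[1],
                       cy + a * cos(tt) * u[2] + b * sin(tt) * v[2])
  ## rasterise the disc from the same polygon the annotation reports, so
  ## downstream polygon-based ROI masks agree with the rendering exactly
  discIn <- .maskFromPolygon(discContour, H, W)
  dg <- 0.9 + nf * 0.75
  R[discIn] <- pmin(1, (1.00 * dg)[discIn])
  G[discIn] <- pmin(1, (0.80 * dg)[discIn])
  B[discIn] <- pmin(1, (0.55 * dg)[discIn])
  ## disc boundary radius as a function of polar angle
  discRadiusAt <- function(th) {
    cu <- cos(th) * u[1] + sin(th) * u[2]
    cv <- cos(th) * v[1] + sin(th) * v[2]
    1 / sqrt((cu / a)^2 + (cv / b)^2)
  }
  ## temporal PPA crescent with planted area (root-find the max width)
  ppaContour <- matrix(numeric(), 0, 2)
  ppaIn <- rep(FALSE, W * H)
  targetPx2 <- truth$ppaAreaMm2 / s^2
  if (targetPx2 > 4) {
    thq <- seq(-pi / 2, pi / 2, length.out = 257)
    Rq <- discRadiusAt(thq)
    areaOf <- function(w0) {
      wq <- w0 * cos(thq)
      sum((Rq * wq + wq^2 / 2)) * (thq[2] - thq[1])
    }
    w0 <- stats::uniroot(function(w) areaOf(w) - targetPx2,
                         c(1e-3, 6 / s), extendInt = "upX")$root
    Rt <- discRadiusAt(theta)
    wt <- w0 * pmax(0, cos(theta))
    ppaIn <- r > Rt & r <= Rt + wt & abs(theta) < pi / 2
    thc <- seq(-pi / 2 + 0.12, pi / 2 - 0.12, length.out = 48)
    Rc <- discRadiusAt(thc)
    outer_ <- cbind(cx + (Rc + w0 * cos(thc)) * cos(thc),
                    cy + (Rc + w0 * cos(thc)) * sin(thc))
    inner_ <- cbind(cx + rev(Rc) * cos(rev(thc)), cy + rev(Rc) * sin(rev(thc)))
    ppaContour <- rbind(outer_, inner_)
  }
  ## temporal peripapillary band: plant per-channel LAB range and skewness
  Rt <- discRadiusAt(theta)
  band <- r > Rt & r * s <= 3 & abs(theta) <= pi / 4 + 0.03
  nb <- sum(band)
  if (nb > 8) {
    uu <- stats::runif(nb)
    labBand <- cbind(
      54 + 2 * pmax(-2.5, min(2.5, truth$atrophyFactor)) +
        truth$rangeL * (uu^.gammaForSkew(truth$skewL) - 0.5),
      30 + truth$rangeA * (uu^.gammaForSkew(truth$skewA) - 0.5),
      32 + truth$rangeB * (uu^.gammaForSkew(truth$skewB) - 0.5))
    rgbBand <- grDevices::convertColor(labBand, from = "Lab", to = "sRGB")
    rgbBand[rgbBand < 0] <- 0; rgbBand[rgbBand > 1] <- 1
    R[band] <- rgbBand[, 1]; G[band] <- rgbBand[, 2]; B[band] <- rgbBand[, 3]
  }
  ## foveal darkening
  fr <- sqrt((xs - fx)^2 + (ys - cy)^2) * s
  fsel <- fr < 0.25
  R[fsel] <- R[fsel] * 0.82; G[fsel] <- G[fsel] * 0.82; B[fsel] <- B[fsel] * 0.82
  ## vessels: 4-8 dark arcs leaving the disc, exact mask
  nv <- sample(4:8, 1)
  vmask <- rep(FALSE, W * H)
  halfwidthPx <- max(1, round(0.05 / s))
  off <- expand.grid(ox = -(halfwidthPx):halfwidthPx,
                     oy = -(halfwidthPx):halfwidthPx)
  off <- off[off$ox^2 + off$oy^2 <= halfwidthPx^2, ]
  for (k in seq_len(nv)) {
    side <- if (k %% 2 == 0) 1 else -1
    phi0 <- side * stats::runif(1, 0.3 * pi, 0.7 * pi)
    d0 <- c(cos(phi0), sin(phi0))
    p0 <- c(cx, cy) + d0 * 0.3 * b
    len <- stats::runif(1, 2.5, 3.4) / s
    bend <- stats::runif(1, -0.6, 0.6)
    p1 <- p0 + d0 * len * 0.5 + c(-d0[2], d0[1]) * bend * len * 0.25
    p2 <- p0 + d0 * len + c(-d0[2], d0[1]) * bend * len * 0.6
    ts2 <- seq(0, 1, length.out = max(64, ceiling(len * 1.5)))
    bez <- outer((1 - ts2)^2, p0) + outer(2 * ts2 * (1 - ts2), p1) +
      outer(ts2^2, p2)
    px <- round(rep(bez[, 1], each = nrow(off)) + off$ox)
    py <- round(rep(bez[, 2], each = nrow(off)) + off$oy)
    keep <- px >= 0 & px < W & py >= 0 & py < H
    vmask[px[keep] * H + py[keep] + 1] <- TRUE
  }
  shade <- 0.45 + 0.1 * stats::runif(sum(vmask))
  R[vmask] <- 0.50 * shade; G[vmask] <- 0.14 * shade
  B[vmask] <- 0.12 * shade
  ## quantise to 8 bit
  img <- array(0, c(H, W, 3))
  img[, , 1] <- round(pmin(1, pmax(0, R)) * 255) / 255
  img[, , 2] <- round(pmin(1, pmax(0, G)) * 255) / 255
  img[, , 3] <- round(pmin(1, pmax(0, B)) * 255) / 255
  ann <- fundusAnnotation(
    discContour = discContour,
    ppaContour = ppaContour,
    fovea = c(fx, cy),
    vesselMask = matrix(vmask, H, W),
    eye = "right")
  list(image = img, annotation = ann, mag = mag)
}

#' Generate a synthetic dataset on disk
#'
#' Writes one PNG image and one annotation JSON per case, a subject CSV, a
#' ground-truth CSV and a manifest JSON listing every file with its MD5
#' checksum. Identical parameters and seed give byte-identical output.
#'
#' @param params a [cohortParams()] object.
#' @param outDir output directory (created if needed).
#' @param imageSizePx image side length, pixels.
#' @param cameraConstant Littmann camera constant.
#' @return The manifest, invisibly (list with `cases`, `files`).
#' @export
generateDataset <- function(params, outDir, imageSizePx = 1024,
                            cameraConstant = defaultCameraConstant(imageSizePx)) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  coh <- sampleSubjects(params)
  files <- character()
  for (i in seq_len(params$nSubjects)) {
    cs <- renderFundusCase(coh$subjects[i, ], coh$truth[i, ], imageSizePx,
                           cameraConstant,
                           seed = (params$seed * 10007L + i) %% 2147483647L)
    imgPath <- file.path(outDir, paste0(coh$subjects$id[i], ".png"))
    annPath <- file.path(outDir, paste0(coh$subjects$id[i], ".json"))
    png::writePNG(cs$image, imgPath)
    writeAnnotation(cs$annotation, annPath)
    files <- c(files, imgPath, annPath)
  }
  subjPath <- file.path(outDir, "subjects.csv")
  truthPath <- file.path(outDir, "truth.csv")
  .writeCsv(coh$subjects, subjPath)
  .writeCsv(coh$truth, truthPath)
  files <- c(files, subjPath, truthPath)
  manifest <- list(
    schema = "fundusIOD-manifest-1",
    nCases = params$nSubjects,
    imageSizePx = imageSizePx,
    cameraConstant = cameraConstant,
    params = unclass(params),
    files = lapply(files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
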