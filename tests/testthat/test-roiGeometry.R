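test_that("Littmann/Bennett ocular factor and scale behave as specified", {
  m <- littmannScale(23.82, cameraConstant = 1)
  expect_equal(m@q, 0.28732, tolerance = 1e-12)
  expect_equal(mmPerPixel(m), 0.28732)
  ## linear in (al - 1.82): doubling the distance doubles q
  q1 <- littmannScale(1.82 + 15, 1)@q
  q2 <- littmannScale(1.82 + 30, 1)@q
  expect_equal(q2, 2 * q1)
  ## monotone increasing
  als <- seq(16, 39, by = 0.5)
  qs <- vapply(als, function(a) littmannScale(a)@q, 0)
  expect_true(all(diff(qs) > 0))
  expect_error(littmannScale(1.82), "range")
  expect_error(littmannScale(45), "range")
})

test_that("disc shape metrics recover analytic ellipses and circles", {
  s <- 0.01  # mm per pixel
  mag <- magAtScale(s)
  ## circle: ovality 1, torsion 0 by convention
  ann <- makeAnnotation(ellipseContour(100, 128, 90, 90), foveaXY = c(250, 128))
  g <- discShapeMetrics(ann, mag)
  expect_equal(g$ovalityIndex, 1.0, tolerance = 0.02)
  expect_identical(g$torsionAngle, 0)
  ## ellipse 0.90/0.72 mm semi-axes, long axis vertical (the reference
  ## perpendicular): LD 1.80, SD 1.44, ovality 0.80
  ann <- makeAnnotation(ellipseContour(100, 128, 90, 72, angleDeg = 90),
                        foveaXY = c(250, 128))
  g <- discShapeMetrics(ann, mag)
  expect_equal(g$LD, 1.80, tolerance = 0.02 * 1.80)
  expect_equal(g$SD, 1.44, tolerance = 0.02 * 1.44)
  expect_equal(g$ovalityIndex, 0.80, tolerance = 0.02 * 0.80)
  expect_equal(g$torsionAngle, 0, tolerance = 0.5)
})

test_that("torsion sign follows the superonasal-positive convention", {
  s <- 0.01
  mag <- magAtScale(s)
  ## fovea at +x (temporal). ellipseContour's angle runs from +x towards
  ## +y, which points DOWN, so a long axis at 90 - 10 deg has its upper
  ## (superior) end tipped towards nasal (-x): positive torsion.
  ann <- makeAnnotation(ellipseContour(100, 128, 90, 72, angleDeg = 90 - 10),
                        foveaXY = c(250, 128))
  expect_equal(discShapeMetrics(ann, mag)$torsionAngle, 10, tolerance = 0.5)
  ## opposite tilt: superior end towards the fovea, inferotemporal torsion
  ann2 <- makeAnnotation(ellipseContour(100, 128, 90, 72, angleDeg = 90 + 10),
                         foveaXY = c(250, 128))
  expect_equal(discShapeMetrics(ann2, mag)$torsionAngle, -10, tolerance = 0.5)
  ## mirroring the whole case (fovea included) swaps eye laterality but
  ## keeps the torsion anatomically superonasal: the sign is preserved
  mirr <- ellipseContour(100, 128, 90, 72, angleDeg = 90 - 10)
  mirr[, 1] <- 255 - mirr[, 1]
  ann3 <- makeAnnotation(mirr, foveaXY = c(5, 128))
  expect_equal(discShapeMetrics(ann3, mag)$torsionAngle, 10, tolerance = 0.5)
})

test_that("ovality is invariant under rotation and translation", {
  mag <- magAtScale(0.01)
  base <- discShapeMetrics(
    makeAnnotation(ellipseContour(100, 128, 90, 60, angleDeg = 0),
                   foveaXY = c(250, 128)), mag)$ovalityIndex
  for (ang in c(17, 63, 118)) {
    g <- discShapeMetrics(
      makeAnnotation(ellipseContour(110, 120, 90, 60, angleDeg = ang),
                     foveaXY = c(250, 128)), mag)
    expect_equal(g$ovalityIndex, base, tolerance = 0.01)
  }
})

test_that("degenerate disc contours are rejected", {
  expect_error(makeAnnotation(ellipseContour(100, 100, 50, 50, n = 5),
                              foveaXY = c(200, 100)), "8 points")
  bowtie <- cbind(c(0, 10, 0, 10, 0, 10, 0, 10) * 3,
                  c(0, 10, 10, 0, 2, 8, 8, 2) * 3)
  expect_error(makeAnnotation(bowtie, foveaXY = c(200, 100)),
               "self-intersecting")
})

test_that("PPA morphometry matches analytic annulus-sector formulas", {
  s <- 0.01
  mag <- magAtScale(s, al = 20)  # al chosen so 2x the ocular factor stays in range
  ## empty PPA: zeros plus a positive disc-fovea distance
  ann <- makeAnnotation(ellipseContour(100, 128, 90, 90),
                        foveaXY = c(250, 128))
  pm <- ppaMetrics(ann, mag)
  expect_equal(pm$area, 0)
  expect_equal(pm$perimeter, 0)
  expect_equal(pm$width, 0)
  expect_equal(pm$discFoveaDistance, 150 * s)
  ## temporal half-annulus crescent 0.9-1.2 mm around a 0.9-mm disc
  cres <- halfAnnulusContour(100, 128, 90, 120)
  ann <- makeAnnotation(ellipseContour(100, 128, 90, 90), cres,
                        foveaXY = c(250, 128))
  pm <- ppaMetrics(ann, mag)
  expect_equal(pm$area, pi * (1.2^2 - 0.9^2) / 2, tolerance = 0.03)
  expect_equal(pm$width, 0.3, tolerance = 0.05 * 0.3)
  ## dimensional analysis: doubling q doubles lengths, quadruples areas
  mag2 <- littmannScale(1.82 + 2 * (mag@al - 1.82), mag@cameraConstant)
  pm2 <- ppaMetrics(ann, mag2)
  expect_equal(pm2$area, 4 * pm$area, tolerance = 1e-10)
  expect_equal(pm2$width, 2 * pm$width, tolerance = 1e-10)
  expect_equal(pm2$perimeter, 2 * pm$perimeter, tolerance = 1e-10)
})

test_that("a PPA contour fully inside the disc is an error", {
  ann <- makeAnnotation(ellipseContour(100, 128, 90, 90),
                        ellipseContour(100, 128, 30, 30),
                        foveaXY = c(250, 128))
  expect_error(ppaMetrics(ann, magAtScale(0.01)), "inside the disc")
})

test_that("ROI masks partition the peripapillary region correctly", {
  s <- 0.03
  mag <- magAtScale(s)
  ann <- makeAnnotation(ellipseContour(102, 128, 30, 30),
                        foveaXY = c(250, 128))
  masks <- buildRoiMasks(ann, mag)
  D <- roiMask(masks, "D"); I <- roiMask(masks, "I")
  IT <- roiMask(masks, "IT"); OT <- roiMask(masks, "OT")
  ## disc, inner ring and outer temporal are pairwise disjoint; the inner
  ## temporal quadrant is inside the inner ring
  expect_false(any(D & I)); expect_false(any(D & OT))
  expect_false(any(I & OT))
  expect_true(all(which(IT) %in% which(I)))
  ## all ring pixels lie inside the 6-mm circle
  idx <- which(I | OT, arr.ind = TRUE)
  r <- sqrt((idx[, 2] - 1 - 102)^2 + (idx[, 1] - 1 - 128)^2) * s
  expect_true(all(r <= 3 + 1e-9))
  ## the full partition has eight ring-quadrant regions (plus the disc)
  part <- peripapillaryPartition(ann, mag)
  expect_length(part, 8)
  expect_true(all(vapply(part, sum, 0L) > 0))
  ## partition regions are pairwise disjoint and union to I + outer ring
  tot <- Reduce(`+`, lapply(part, function(m) m * 1L))
  expect_true(all(tot <= 1L))
})

test_that("vessel exclusion removes exactly the vessel pixels", {
  s <- 0.03
  mag <- magAtScale(s)
  ann0 <- makeAnnotation(ellipseContour(102, 128, 30, 30),
                         foveaXY = c(250, 128))
  m0 <- buildRoiMasks(ann0, mag, excludeVessels = FALSE)
  it0 <- roiMask(m0, "IT")
  vm <- matrix(FALSE, 256, 256)
  sel <- which(it0)
  vm[sel[seq_len(floor(length(sel) / 10))]] <- TRUE
  ann <- fundusAnnotation(discContour = discContour(ann0),
                          fovea = fovea(ann0), vesselMask = vm, eye = "right")
  m1 <- buildRoiMasks(ann, mag)
  expect_identical(sum(it0) - sum(roiMask(m1, "IT")),
                   as.integer(floor(length(sel) / 10)))
})

test_that("fovea coincident with the disc centre is rejected", {
  ann <- makeAnnotation(ellipseContour(100, 128, 30, 30),
                        foveaXY = c(100, 128))
  expect_error(buildRoiMasks(ann, magAtScale(0.03)), "temporal direction")
})

test_that("ETDRS sector means: constants, counts and gradients", {
  mag <- magAtScale(0.03)
  mp <- matrix(200, 256, 256)
  sm <- etdrsSectorMeans(mp, c(128, 128), mag, "macula", c(1, 0))
  expect_length(sm, 9)
  expect_true(all(abs(sm - 200) < 1e-12))
  sp <- etdrsSectorMeans(mp, c(128, 128), mag, "peripapillary", c(1, 0))
  expect_length(sp, 4)
  ## linear gradient along the temporal axis: sector means match the
  ## analytic sector integrals of x over each region
  xs <- matrix(rep(0:255 - 128, each = 256), 256, 256) * 0.03
  sg <- etdrsSectorMeans(xs, c(128, 128), mag, "peripapillary", c(1, 0))
  meanX <- function(r1, r2) {
    ## mean of r cos(theta) over 90-degree sector centred on +x
    (r2^3 - r1^3) / 3 * 2 * sin(pi / 4) / ((r2^2 - r1^2) / 2 * pi / 2)
  }
  expect_equal(unname(sg["outer_temporal"]), meanX(1.5, 3), tolerance = 0.01)
  expect_equal(unname(sg["outer_nasal"]), -meanX(1.5, 3), tolerance = 0.01)
  expect_lt(sg["outer_nasal"], sg["outer_temporal"])
  expect_equal(unname(sg["outer_superior"]), 0, tolerance = 0.01)
})
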