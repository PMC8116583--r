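test_that("cohort parameter validation rejects bad inputs", {
  expect_error(cohortParams(nSubjects = 1), "at least 2")
  expect_error(cohortParams(alSdMm = -1), "non-negative")
  expect_error(cohortParams(signalFraction = 1.5), "signalFraction")
})

test_that("sampled marginals match the cohort targets at n = 2000", {
  p <- cohortParams(nSubjects = 2000, seed = 1)
  coh <- sampleSubjects(p)
  s <- coh$subjects; tr <- coh$truth
  expect_equal(mean(s$al), 25.51, tolerance = 0.1 / 25.51)
  expect_lt(abs(sd(s$al) - 1.34), 0.1)
  ## all planted marginals within 10% of target mean/sd
  chk <- function(x, m, sdv) {
    expect_lt(abs(mean(x) - m), 0.1 * max(abs(m), sdv))
    expect_lt(abs(sd(x) - sdv), 0.1 * sdv)
  }
  chk(tr$mcht, 211.00, 62.03)
  chk(tr$pcht, 143.33, 45.58)
  chk(tr$ovality, 0.79, 0.10)
  chk(tr$torsionDeg, 4.98, 19.78)
  chk(tr$ppaAreaMm2, 0.68, 0.63)
  expect_true(all(tr$mcht > 0 & tr$pcht > 0))
  expect_true(all(tr$ovality > 0.4 & tr$ovality <= 1))
  expect_true(all(s$age >= 16 & s$age <= 40))
  expect_equal(s$map, (s$sbp + 2 * s$dbp) / 3)
})

test_that("same seed gives identical cohorts; signal fraction controls coupling", {
  p <- cohortParams(nSubjects = 200, seed = 9)
  expect_identical(sampleSubjects(p), sampleSubjects(p))
  ## signalFraction = 0: planted intensity parameters decoupled from ChT
  p0 <- cohortParams(nSubjects = 2000, seed = 2, signalFraction = 0)
  c0 <- sampleSubjects(p0)
  expect_lt(abs(cor(c0$truth$rangeL, c0$truth$mcht)), 0.1)
  expect_lt(abs(cor(c0$truth$skewA, c0$truth$pcht)), 0.1)
  ## coupling strengthens monotonically in signalFraction
  rAt <- function(f) {
    cc <- sampleSubjects(cohortParams(nSubjects = 2000, seed = 2,
                                      signalFraction = f))
    abs(cor(cc$truth$rangeL, cc$truth$mcht))
  }
  rs <- vapply(c(0, 0.25, 0.5, 0.75), rAt, 0)
  expect_true(all(diff(rs) > 0))
})

test_that("rendered cases carry the planted geometry", {
  p <- cohortParams(nSubjects = 4, seed = 31)
  coh <- sampleSubjects(p)
  for (i in 1:4) {
    cs <- renderFundusCase(coh$subjects[i, ], coh$truth[i, ], 256,
                           seed = 100 + i)
    g <- discShapeMetrics(cs$annotation, cs$mag)
    expect_equal(g$ovalityIndex, coh$truth$ovality[i], tolerance = 0.02)
    expect_equal(g$torsionAngle, coh$truth$torsionDeg[i], tolerance = 2,
                 ignore_attr = TRUE)
    pm <- ppaMetrics(cs$annotation, cs$mag)
    expect_equal(pm$area, coh$truth$ppaAreaMm2[i], tolerance = 0.05)
    expect_equal(pm$discFoveaDistance, coh$truth$dfdMm[i], tolerance = 0.02)
  }
})

test_that("a zero-area PPA yields an empty contour and zero metrics", {
  coh <- sampleSubjects(cohortParams(nSubjects = 2, seed = 5))
  tr <- coh$truth[1, ]
  tr$ppaAreaMm2 <- 0
  cs <- renderFundusCase(coh$subjects[1, ], tr, 192, seed = 4)
  expect_identical(nrow(ppaContour(cs$annotation)), 0L)
  pm <- ppaMetrics(cs$annotation, cs$mag)
  expect_equal(pm$area, 0)
  expect_equal(pm$width, 0)
})

test_that("planted temporal intensity statistics are recovered from pixels", {
  p <- cohortParams(nSubjects = 6, seed = 17)
  coh <- sampleSubjects(p)
  rngErr <- skwErr <- numeric()
  for (i in 1:6) {
    cs <- renderFundusCase(coh$subjects[i, ], coh$truth[i, ], 256,
                           seed = 300 + i)
    masks <- buildRoiMasks(cs$annotation, cs$mag)
    lab <- rgbToLab(cs$image)
    band <- roiMask(masks, "IT") | roiMask(masks, "OT")
    vL <- lab$L[band]
    rngErr <- c(rngErr, (max(vL) - min(vL)) / coh$truth$rangeL[i] - 1)
    m2 <- mean((vL - mean(vL))^2); m3 <- mean((vL - mean(vL))^3)
    skwErr <- c(skwErr, m3 / m2^1.5 - coh$truth$skewL[i])
  }
  ## 8-bit quantisation and finite sampling allow modest slack
  expect_true(all(abs(rngErr) < 0.15))
  expect_true(all(abs(skwErr) < 0.25))
})

test_that("renderFundusCase rejects geometry that cannot fit", {
  coh <- sampleSubjects(cohortParams(nSubjects = 2, seed = 5))
  ## a 64-px frame at a 256-px camera constant spans under 3 mm
  expect_error(renderFundusCase(coh$subjects[1, ], coh$truth[1, ],
                                imageSizePx = 64,
                                cameraConstant = defaultCameraConstant(256)),
               "does not fit")
})

test_that("generateDataset writes a complete, reproducible dataset", {
  p <- cohortParams(nSubjects = 6, seed = 7)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- generateDataset(p, d1, imageSizePx = 160)
  expect_length(list.files(d1, pattern = "^case_.*\\.png$"), 6)
  expect_length(list.files(d1, pattern = "^case_.*\\.json$"), 6)
  expect_true(file.exists(file.path(d1, "subjects.csv")))
  expect_true(file.exists(file.path(d1, "truth.csv")))
  expect_true(file.exists(file.path(d1, "manifest.json")))
  ## determinism: identical checksums on a re-run
  m2 <- generateDataset(p, d2, imageSizePx = 160)
  md5 <- function(m) vapply(m$files, function(f) f$md5, "")
  expect_identical(md5(m1), md5(m2))
  ## round trip through loadCase validates
  lc <- loadCase(file.path(d1, "case_0001.png"), file.path(d1, "case_0001.json"))
  expect_s4_class(lc$annotation, "FundusAnnotation")
  expect_identical(dim(lc$image)[3], 3L)
  unlink(c(d1, d2), recursive = TRUE)
})
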