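test_that("sRGB to CIELAB conversion hits the neutral axis anchors", {
  mk <- function(rgb) array(rep(rgb, each = 4), c(2, 2, 3))
  white <- rgbToLab(mk(c(255, 255, 255)))
  expect_equal(white$L[1, 1], 100, tolerance = 0.5)
  expect_equal(white$A[1, 1], 0, tolerance = 0.5)
  expect_equal(white$B[1, 1], 0, tolerance = 0.5)
  black <- rgbToLab(mk(c(0, 0, 0)))
  expect_equal(black$L[1, 1], 0, tolerance = 0.5)
  gray <- rgbToLab(mk(c(119, 119, 119)))
  expect_equal(gray$A[1, 1], 0, tolerance = 0.5)
  expect_equal(gray$B[1, 1], 0, tolerance = 0.5)
  expect_error(rgbToLab(matrix(0.5, 4, 4)), "3-channel")
})

test_that("fixed-bin-width discretisation uses half-open level intervals", {
  ch <- matrix(c(0, 24.9, 25, 50), 2, 2)
  mask <- matrix(TRUE, 2, 2)
  lev <- discretizeChannel(ch, mask, binWidth = 25)
  expect_identical(as.integer(lev), c(1L, 1L, 2L, 3L))
  expect_identical(attr(lev, "nLevels"), 3L)
  ## constant region: one level
  lev1 <- discretizeChannel(matrix(7, 3, 3), matrix(TRUE, 3, 3), 25)
  expect_identical(attr(lev1, "nLevels"), 1L)
  ## refining the bin width never decreases the level count
  set.seed(42)
  ch <- matrix(runif(64, 0, 255), 8, 8)
  m <- matrix(TRUE, 8, 8)
  nl <- vapply(c(64, 32, 16, 8, 4), function(w)
    attr(discretizeChannel(ch, m, w), "nLevels"), 0L)
  expect_true(all(diff(nl) >= 0))
  expect_error(discretizeChannel(ch, m, 0), "positive")
})

test_that("first-order features match hand-computed population moments", {
  v <- matrix(c(1, 2, 3, 4, 10), 1, 5)
  f <- firstOrderFeatures(v, matrix(TRUE, 1, 5))
  expect_equal(unname(f["range"]), 9)
  expect_equal(unname(f["mean"]), 4)
  expect_equal(unname(f["variance"]), 10)        # population m2
  expect_equal(unname(f["skewness"]), 36 / 10^1.5, tolerance = 1e-12)
  ## constant region: degenerate conventions
  fc <- firstOrderFeatures(matrix(5, 2, 3), matrix(TRUE, 2, 3))
  expect_equal(unname(fc[c("range", "variance", "skewness", "kurtosis")]),
               c(0, 0, 0, 0))
  expect_error(firstOrderFeatures(matrix(1, 1, 1), matrix(TRUE, 1, 1)),
               "2 masked pixels")
})

test_that("the 19 first-order features equal the direct-formula oracle", {
  set.seed(7)
  for (rep in 1:25) {
    ch <- matrix(runif(256, 0, 255), 16, 16)
    mask <- matrix(runif(256) < 0.85, 16, 16)
    if (sum(mask) < 4) next
    f <- firstOrderFeatures(ch, mask, binWidth = 25, pixelAreaMm2 = 0.01)
    o <- oracleFirstOrder(ch[mask], binWidth = 25, pixelArea = 0.01)
    expect_equal(f, o, tolerance = 1e-10)
  }
})

test_that("shape descriptors: circle, rectangle and scale behaviour", {
  mag <- magAtScale(0.01)
  ## rasterised 1-mm-radius circle: sphericity ~ 1
  xy <- expand.grid(x = 0:239, y = 0:239)
  circ <- matrix((xy$x - 120)^2 + (xy$y - 120)^2 <= 100^2, 240, 240)
  f <- shape2DFeatures(circ, mag)
  expect_equal(unname(f["sphericity"]), 1, tolerance = 0.02)
  expect_equal(unname(f["pixel_surface"]), pi, tolerance = 0.01)
  expect_equal(unname(f["maximum_diameter"]), 2, tolerance = 0.02)
  expect_equal(unname(f["elongation"]), 1, tolerance = 0.01)
  ## 2:1 rectangle: elongation = ratio of sqrt second moments = 0.5
  rect <- matrix(FALSE, 240, 240)
  rect[21:60, 21:100] <- TRUE
  fr <- shape2DFeatures(rect, mag)
  expect_equal(unname(fr["elongation"]), 0.5, tolerance = 0.025)
  expect_equal(unname(fr["major_axis_length"]),
               4 * sqrt(80^2 / 12) * 0.01, tolerance = 0.05)
  ## doubling the scale doubles lengths, quadruples surfaces
  mag2 <- magAtScale(0.02)
  f2 <- shape2DFeatures(circ, mag2)
  expect_equal(unname(f2["perimeter"]), 2 * unname(f["perimeter"]))
  expect_equal(unname(f2["mesh_surface"]), 4 * unname(f["mesh_surface"]))
  expect_error(shape2DFeatures(matrix(FALSE, 4, 4), mag), "empty")
})

test_that("GLCM worked example matches hand-counted pairs", {
  lv <- matrix(c(1L, 2L, 1L, 2L), 2, 2)  # rows: (1,1),(2,2)
  ## horizontal direction: pairs (1,1) and (2,2), symmetrised
  P <- fundusIOD:::cppGlcm(lv, 2L, 1L, 0L)
  expect_equal(P, matrix(c(2, 0, 0, 2), 2, 2))
  norm <- P / sum(P)
  expect_equal(norm[1, 1], 0.5)
  expect_equal(norm[2, 2], 0.5)
  ## zero contrast contribution in this direction
  f <- fundusIOD:::.glcmFromMatrix(P, 2L)
  expect_equal(unname(f["contrast"]), 0)
})

test_that("GLCM degenerate conventions on constant regions", {
  lv <- matrix(1L, 4, 4)
  f <- glcmFeatures(lv, 1L)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["correlation"]), 1)
  expect_equal(unname(f["mcc"]), 1)
})

test_that("all texture families equal brute-force oracles on random images", {
  set.seed(11)
  nRep <- 110
  for (rep in seq_len(nRep)) {
    lv <- randomLevelImage(8, 8, 4, pMask = if (rep %% 3) 0.85 else 0.55)
    ng <- 4L
    expect_equal(glcmFeatures(lv, ng), oracleGlcm(lv, ng),
                 tolerance = 1e-10)
    expect_equal(textureMatrixFeatures(lv, "GLRLM", ng), oracleGlrlm(lv, ng),
                 tolerance = 1e-10)
    expect_equal(textureMatrixFeatures(lv, "GLSZM", ng), oracleGlszm(lv, ng),
                 tolerance = 1e-10)
    expect_equal(textureMatrixFeatures(lv, "NGTDM", ng), oracleNgtdm(lv, ng),
                 tolerance = 1e-10)
    expect_equal(textureMatrixFeatures(lv, "GLDM", ng), oracleGldm(lv, ng),
                 tolerance = 1e-10)
  }
})

test_that("run-length and zone worked examples", {
  ## single row of three equal levels: one run of length 3
  lv <- matrix(c(1L, 1L, 1L), 1, 3)
  R <- fundusIOD:::cppGlrlm(lv, 1L, 1L, 0L)
  expect_equal(sum(R), 1)
  expect_equal(R[1, 3], 1)
  ## constant 4x4 region: a single 16-pixel zone
  z <- fundusIOD:::cppZones(matrix(2L, 4, 4))
  expect_equal(nrow(z), 1L)
  expect_equal(z[1, 2], 16L)
  ## family cardinalities
  lv <- randomLevelImage(8, 8, 4)
  expect_length(glcmFeatures(lv, 4L), 24)
  expect_length(textureMatrixFeatures(lv, "GLRLM", 4L), 16)
  expect_length(textureMatrixFeatures(lv, "GLSZM", 4L), 16)
  expect_length(textureMatrixFeatures(lv, "NGTDM", 4L), 5)
  expect_length(textureMatrixFeatures(lv, "GLDM", 4L), 14)
  expect_error(textureMatrixFeatures(lv, "GLXX"), "arg")
})

test_that("texture features are invariant to image embedding position", {
  set.seed(3)
  lv <- randomLevelImage(8, 8, 4, pMask = 1)
  big <- matrix(NA_integer_, 20, 20)
  big[7:14, 9:16] <- lv
  expect_equal(glcmFeatures(lv, 4L), glcmFeatures(big, 4L))
  for (fam in c("GLRLM", "GLSZM", "NGTDM", "GLDM"))
    expect_equal(textureMatrixFeatures(lv, fam, 4L),
                 textureMatrixFeatures(big, fam, 4L))
})

test_that("extractPool assembles the documented pool deterministically", {
  p <- cohortParams(nSubjects = 2, seed = 21)
  coh <- sampleSubjects(p)
  cs <- renderFundusCase(coh$subjects[1, ], coh$truth[1, ], 192, seed = 5)
  masks <- buildRoiMasks(cs$annotation, cs$mag)
  fv <- extractPool(cs$image, cs$annotation, masks, cs$mag)
  ## 6 geometry + 4 x (10 shape + 3 x 94 intensity/texture)
  expect_length(fv, 6 + 4 * (10 + 3 * 94))
  roiBlock <- function(roi) sum(startsWith(names(fv), paste0(roi, "_")))
  for (roi in c("D", "I", "IT", "OT"))
    expect_identical(roiBlock(roi), as.integer(10 + 3 * 94))
  ## Fig-4-style names are present
  expect_true(all(c("IT_L_range", "OT_A_range", "OT_B_range",
                    "OT_A_skewness", "I_B_skewness") %in% names(fv)))
  expect_true(all(is.finite(fv)))
  ## determinism
  fv2 <- extractPool(cs$image, cs$annotation, masks, cs$mag)
  expect_identical(fv, fv2)
  ## locality: brightening only OT pixels changes OT features only
  img2 <- cs$image
  ot <- roiMask(masks, "OT")
  for (k in 1:3) {
    ch <- img2[, , k]
    ch[ot] <- pmin(1, ch[ot] * 1.2 + 0.05)
    img2[, , k] <- ch
  }
  fv3 <- extractPool(img2, cs$annotation, masks, cs$mag)
  changed <- names(fv)[which(abs(fv3 - fv) > 1e-9)]
  expect_true(all(startsWith(changed, "OT_") | !grepl("^(D|I|IT)_", changed)))
  expect_false(any(startsWith(changed, "D_") | startsWith(changed, "I_") |
                     startsWith(changed, "IT_")))
  expect_gt(sum(startsWith(changed, "OT_")), 0)
})
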