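# Shape descriptors, radial profiles, engineered metrics, assembly and QC.

test_that("shapeFeatures returns circle identities on rasterized disks", {
  d <- diskMask(221L, 100L)
  sf <- shapeFeatures(d, 1)
  expect_lt(abs(sf[["circularity"]] - 1), 0.05)
  expect_lt(abs(sf[["area_um2"]] / (pi * 100^2) - 1), 0.02)
  expect_lt(abs(sf[["aspect_ratio"]] - 1), 0.05)
  expect_gt(sf[["solidity"]], 0.97)
  expect_lte(sf[["solidity"]], 1)
  expect_lt(abs(sf[["roundness"]] - 1), 0.06)
  expect_lt(abs(sf[["equivalent_diameter_um"]] - 200), 2)

  # calibration: lengths scale by px, areas by px^2
  sf2 <- shapeFeatures(d, 1.3)
  expect_equal(sf2[["area_um2"]], sf[["area_um2"]] * 1.69)
  expect_equal(sf2[["perimeter_um"]], sf[["perimeter_um"]] * 1.3)
})

test_that("shapeFeatures measures ellipse aspect ratio", {
  e <- outer(1:161, 1:161, function(r, c)
    ((r - 81) / 30)^2 + ((c - 81) / 60)^2 <= 1)   # 2:1 axis-aligned
  sf <- shapeFeatures(e, 1)
  expect_lt(abs(sf[["aspect_ratio"]] - 2), 0.05)
  expect_lt(abs(sf[["major_axis_um"]] - 120), 2)
  expect_lt(abs(abs(sf[["orientation_rad"]]) - pi / 2), 0.05)
})

test_that("tiny regions flag perimeter-based features undefined", {
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  sf <- shapeFeatures(m, 1)
  expect_true(is.na(sf[["perimeter_um"]]))
  expect_true(is.na(sf[["circularity"]]))
  expect_equal(sf[["shape_undefined"]], 1)
  expect_equal(sf[["area_um2"]], 1)
  expect_error(shapeFeatures(matrix(FALSE, 3, 3)), "empty")
})

test_that("radialProfile satisfies its exact identities", {
  m <- diskMask(81L, 35L)
  # uniform intensity: mean_frac = 1 in every ring, fractions sum to 1
  rp <- radialProfile(matrix(1, 81, 81), m)
  expect_equal(rp$mean_frac, rep(1, 6), tolerance = 1e-12)
  expect_equal(sum(rp$frac_at_d), 1, tolerance = 1e-9)

  # all intensity at the centroid pixel lands in ring 1
  ctr <- matrix(0, 81, 81); ctr[41, 41] <- 7
  expect_equal(radialProfile(ctr, m)$frac_at_d, c(1, 0, 0, 0, 0, 0))

  # a thin ring at d = 0.55 concentrates in ring 4 ((0.5, 0.667])
  rad <- sqrt(outer(1:81, 1:81, function(r, c) (r - 41)^2 + (c - 41)^2))
  ring <- exp(-(rad - 0.55 * 35)^2 / 0.5); ring[!m] <- 0
  expect_gte(radialProfile(ring, m)$frac_at_d[4L], 0.95)

  # zero-intensity object: flagged all-zero profile
  z <- radialProfile(matrix(0, 81, 81), m)
  expect_true(attr(z, "zero_total"))
  expect_equal(z$frac_at_d, rep(0, 6))
})

test_that("radialProfile matches the brute-force per-pixel oracle to 1e-9", {
  set.seed(77)
  for (i in 1:50) {
    m <- randomBlobMask()
    img <- matrix(runif(61 * 61), 61, 61)
    rp <- radialProfile(img, m)
    orc <- radialOracle(img, m)
    expect_equal(rp$frac_at_d, orc$frac, tolerance = 1e-9)
    expect_equal(rp$mean_frac, orc$meanFrac, tolerance = 1e-9)
    expect_equal(sum(rp$frac_at_d), 1, tolerance = 1e-9)
  }
})

test_that("feature extraction is invariant to translation and 90-degree rotation", {
  set.seed(42)
  size <- 101L
  m <- matrix(FALSE, size, size)
  m[21:60, 26:65] <- randomBlobMask(40L, 15, 0.15)[1:40, 1:40]
  img <- matrix(0, size, size)
  img[m] <- runif(sum(m)) + 0.5
  base <- c(shapeFeatures(m, 1)[1:12],
            rad = radialProfile(img, m)$mean_frac,
            zern = zernikeMoments(img, m))

  # translation by (7, 9)
  mT <- matrix(FALSE, size, size); imT <- matrix(0, size, size)
  mT[28:67, 35:74] <- m[21:60, 26:65]
  imT[28:67, 35:74] <- img[21:60, 26:65]
  shifted <- c(shapeFeatures(mT, 1)[1:12],
               rad = radialProfile(imT, mT)$mean_frac,
               zern = zernikeMoments(imT, mT))
  keep <- setdiff(names(base), c("centroid_row_um", "centroid_col_um"))
  expect_equal(base[keep], shifted[keep], tolerance = 1e-9)

  # 90-degree rotation
  mR <- t(m)[, size:1]; imR <- t(img)[, size:1]
  rot <- c(shapeFeatures(mR, 1)[1:12],
           rad = radialProfile(imR, mR)$mean_frac,
           zern = zernikeMoments(imR, mR))
  scalars <- setdiff(names(base),
                     c("centroid_row_um", "centroid_col_um", "orientation_rad"))
  rel <- abs(rot[scalars] - base[scalars]) /
    pmax(abs(base[scalars]), 0.05)
  expect_lt(max(rel[!grepl("zern", scalars)]), 0.01)
  expect_lt(max(rel[grepl("zern", scalars)]), 0.02)
})

test_that("maxNormalizeProfiles rescales rows to unit maximum", {
  expect_equal(maxNormalizeProfiles(c(2, 4, 1, 1, 1, 1)),
               c(0.5, 1, 0.25, 0.25, 0.25, 0.25))
  v <- c(0.2, 1, 0.4, 0.1, 0.05, 0)
  expect_equal(maxNormalizeProfiles(v), v)     # idempotent on normalized input
  m <- rbind(a = c(1, 2, 4, 2, 1, 0), b = rep(0, 6))
  out <- maxNormalizeProfiles(m)
  expect_equal(unname(out["a", 3L]), 1)
  expect_equal(unname(out["b", ]), rep(0, 6))
  expect_equal(attr(out, "flagged_zero"), c(b = 2L))
})

test_that("areaRatioSqrt is exact, clipped and monotone", {
  expect_equal(as.numeric(areaRatioSqrt(0, 100)), 0)
  expect_equal(as.numeric(areaRatioSqrt(100, 100)), 1)
  expect_equal(as.numeric(areaRatioSqrt(25, 100)), 0.5)
  out <- areaRatioSqrt(c(50, 101), c(100, 100))
  expect_equal(as.numeric(out[2L]), 1)
  expect_equal(attr(out, "clipped"), 2L)
  expect_error(areaRatioSqrt(10, 0), "positive")
  lum <- seq(0, 100, by = 5)
  expect_true(all(diff(as.numeric(areaRatioSqrt(lum, 100))) > 0))
})

test_that("assembleRecords produces >400 deterministic feature columns", {
  cfg <- simulationConfig(fieldShapePx = c(320L, 320L),
                          nOrganoidsPerField = c(2L, 2L), fusionProb = 0)
  out <- renderField(cfg, wellCondition("VPA", 200), seed = 77)
  fld <- out$field
  org <- segmentOrganoids(getChannel(fld, "counterstain"), 1.3)
  lum <- segmentLumens(getChannel(fld, "lumen_marker"), org)
  rec <- assembleRecords(fld, org, lum)
  expect_gt(length(featureColumns(rec)), 400L)
  expect_false(anyNA(rec[, featureColumns(rec)]))
  rec2 <- assembleRecords(fld, org, lum)
  expect_identical(rec, rec2)

  # organoid without a lumen is retained with flagged sentinels
  lum0 <- segmentLumens(matrix(0, 320, 320), org)
  rec0 <- assembleRecords(fld, org, lum0)
  expect_equal(nrow(rec0), nrow(rec))
  expect_true(all(rec0$lumen_missing))
  expect_true(all(is.na(rec0$area_ratio_sqrt)))
  expect_true(all(rec0$lumen_count == 0))
  expect_false(anyNA(rec0$org_shape_area_um2))
})

test_that("qcFilter applies the inclusive single-lumen area window", {
  rec <- data.frame(
    org_shape_area_um2 = c(7853, 7854, 31415, 31416, 20000, 20000, 20000,
                           15000, 9000, 12000),
    lumen_count = c(1, 1, 1, 1, 1, 2, 0, 1, 1, 1),
    border = c(rep(FALSE, 7), TRUE, FALSE, FALSE),
    unmapped = c(rep(FALSE, 9), TRUE))
  out <- qcFilter(rec)
  # brute-force reference filter
  ref <- with(rec, lumen_count == 1 & org_shape_area_um2 >= 7854 &
                org_shape_area_um2 <= 31415 & !border & !unmapped)
  expect_equal(nrow(out$retained), sum(ref))
  expect_equal(out$retained$org_shape_area_um2,
               rec$org_shape_area_um2[ref])
  counts <- setNames(out$report$count, out$report$reason)
  expect_equal(unname(counts[c("retained", "multi_lumen", "no_lumen",
                               "too_small", "too_large", "border",
                               "unmapped")]),
               c(4, 1, 1, 1, 1, 1, 1))
  expect_equal(sum(out$report$count), nrow(rec))

  # boundary cases: 7853 out, 7854 in, 31415 in, 31416 out
  expect_true(7854 %in% out$retained$org_shape_area_um2)
  expect_true(31415 %in% out$retained$org_shape_area_um2)
  expect_false(7853 %in% out$retained$org_shape_area_um2)
  expect_false(31416 %in% out$retained$org_shape_area_um2)
})

test_that("qcFilter equals brute-force filtering on random tables", {
  set.seed(123)
  for (i in 1:20) {
    rec <- data.frame(
      org_shape_area_um2 = runif(40, 5000, 35000),
      lumen_count = sample(0:3, 40, replace = TRUE,
                           prob = c(0.1, 0.7, 0.15, 0.05)))
    out <- qcFilter(rec)
    ref <- rec[rec$lumen_count == 1 & rec$org_shape_area_um2 >= 7854 &
                 rec$org_shape_area_um2 <= 31415, ]
    expect_equal(out$retained$org_shape_area_um2, ref$org_shape_area_um2)
  }
})
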