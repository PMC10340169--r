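# Generative models and the synthetic field / mosaic renderers.

test_that("Hill dose-response hits its anchors and is strictly monotone", {
  m <- simulationConfig()$lumenModel
  expect_equal(lumenFractionFromDose(0, m), m$rho0)
  expect_equal(lumenFractionFromDose(m$ec50Um, m),
               m$rho0 + (m$rhoMax - m$rho0) / 2)
  grid <- seq(0, 1000, by = 0.5)
  rho <- lumenFractionFromDose(grid, m)
  expect_true(all(diff(rho) > 0))
  expect_true(all(rho > m$rho0 - 1e-12 & rho < m$rhoMax))
  expect_error(lumenFractionFromDose(-1, m))
})

test_that("knockout gene-dose response is linear below saturation and flat above", {
  m <- simulationConfig()$lumenModel
  expect_equal(lumenFractionFromKO(0, m), m$rho0)
  # the 75% and 100% knockout conditions are generated identically
  expect_identical(lumenFractionFromKO(0.75, m), m$rhoMax)
  expect_identical(lumenFractionFromKO(1, m), m$rhoMax)
  expect_equal(lumenFractionFromKO(0.375, m),
               m$rho0 + 0.5 * (m$rhoMax - m$rho0))
  f <- seq(0, m$fSat, by = 0.01)
  expect_true(all(diff(lumenFractionFromKO(f, m)) > 0))
  expect_error(lumenFractionFromKO(1.2, m), "\\[0, 1\\]")
})

test_that("simulationConfig validates its invariants", {
  expect_error(simulationConfig(lumenModel = list(rho0 = 0.7, rhoMax = 0.6)),
               "rho0 < rhoMax")
  expect_error(simulationConfig(fusionProb = 1.5), "fusionProb")
  expect_error(simulationConfig(bogus = 1), "unknown")
})

test_that("renderField draws the specified geometry (noise off)", {
  # one centered organoid, rho = 0.2: counterstain disk area within 2% of
  # pi r^2, marker ring peaking at 0.2 r from the centre
  cfg <- noiseFreeConfig(fieldShapePx = c(256L, 256L),
                         nOrganoidsPerField = c(1L, 1L), rhoSd = 0,
                         organoidRadiusUm = list(mean = 75, sd = 0,
                                                 min = 75, max = 75))
  cfg$lumenModel$rho0 <- 0.2
  out <- renderField(cfg, wellCondition("vehicle", 0), seed = 5)
  tr <- truthOrganoids(out$truth)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$rho, 0.2)
  counter <- getChannel(out$field, "counterstain")
  areaUm2 <- sum(counter > 0) * pixelSize(out$field)^2
  expect_lt(abs(areaUm2 / (pi * 75^2) - 1), 0.02)
  expect_lt(abs(tr$body_area_um2 / (pi * 75^2) - 1), 0.02)
  # ring location: peak marker intensity at radius 15 um from the centre
  marker <- getChannel(out$field, "lumen_marker")
  pk <- which(marker == max(marker), arr.ind = TRUE)[1L, ]
  rpk <- sqrt((pk[1L] - tr$center_row_px)^2 + (pk[2L] - tr$center_col_px)^2) *
    pixelSize(out$field)
  expect_lt(abs(rpk - 0.2 * 75), 2 * pixelSize(out$field))
})

test_that("forced fusion yields one body with two lumens in the truth", {
  cfg <- noiseFreeConfig(fieldShapePx = c(420L, 420L),
                         nOrganoidsPerField = c(1L, 1L), fusionProb = 1)
  out <- renderField(cfg, wellCondition("vehicle", 0), seed = 8)
  tr <- truthOrganoids(out$truth)
  expect_equal(tr$lumen_count, 2L)
  expect_true(tr$fused)
  expect_length(truthPolygons(out$truth)[[1L]]$lumens, 2L)
  # the rendered counterstain is one 8-connected component
  counter <- getChannel(out$field, "counterstain")
  lab <- segmentOrganoids(counter, pixelSizeUm = 1.3, sigmaPx = 0)
  expect_equal(nObjects(lab), 1L)
})

test_that("rendering is bit-reproducible for identical config and seed", {
  cfg <- simulationConfig(fieldShapePx = c(192L, 192L),
                          nOrganoidsPerField = c(2L, 2L))
  a <- renderField(cfg, wellCondition("VPA", 300), seed = 42)
  b <- renderField(cfg, wellCondition("VPA", 300), seed = 42)
  expect_identical(a$field@pixels, b$field@pixels)
  expect_identical(truthOrganoids(a$truth), truthOrganoids(b$truth))
})

test_that("truth rasterization matches polygon areas and conserves pixels", {
  cfg <- noiseFreeConfig(fieldShapePx = c(512L, 512L),
                         nOrganoidsPerField = c(5L, 5L))
  out <- renderField(cfg, wellCondition("VPA", 400), seed = 31)
  tr <- truthOrganoids(out$truth)
  lab <- rasterizeTruth(out$truth, c(512L, 512L), 1.3, "body")
  pxA <- tabulate(lab[lab > 0L], nrow(tr)) * 1.3^2
  # polygon areas agree with their rasterization within discretization error
  expect_true(all(abs(pxA / tr$body_area_um2 - 1) < 0.02))
  # no overlaps: per-organoid pixel sums equal total foreground
  expect_identical(sum(tabulate(lab[lab > 0L], nrow(tr))), sum(lab > 0L))
})

test_that("true lumen burden rises with dose and knockout fraction, saturating at 75%", {
  cfg <- simulationConfig()
  doses <- c(50, 100, 200, 300, 400, 600, 800, 1000)
  mu <- vapply(seq_along(doses), function(i) {
    g <- sampleOrganoidGeometry(300L, wellCondition("VPA", doses[i]), cfg,
                                seed = 500 + i)
    mean(g$area_ratio)
  }, 0)
  expect_true(all(diff(mu) > 0))

  fr <- c(0, 0.125, 0.25, 0.5, 0.75, 1)
  muK <- vapply(seq_along(fr), function(i) {
    g <- sampleOrganoidGeometry(300L, wellCondition(genotype = "mosaic",
                                                    koFraction = fr[i]),
                                cfg, seed = 600 + i)
    mean(g$area_ratio)
  }, 0)
  expect_true(all(diff(muK[1:5]) > 0))

  # saturation: f = 0.75 and f = 1.0 are distributionally identical
  g75 <- sampleOrganoidGeometry(200L, wellCondition(genotype = "mosaic",
                                                    koFraction = 0.75),
                                cfg, seed = 700)
  g100 <- sampleOrganoidGeometry(200L, wellCondition(genotype = "mosaic",
                                                     koFraction = 1),
                                 cfg, seed = 701)
  ks <- suppressWarnings(ks.test(g75$lumen_area_um2, g100$lumen_area_um2))
  expect_gt(ks$p.value, 0.01)
})

test_that("apical mosaic truth matches the configured mean areas", {
  cfg <- simulationConfig()
  wt <- renderApicalMosaic(cfg, "WT", seed = 5)
  ko <- renderApicalMosaic(cfg, "KO", seed = 6)
  cw <- truthCells(wt$truth); ck <- truthCells(ko$truth)
  expect_gt(nrow(cw), 300L)
  expect_gt(nrow(ck), 300L)
  expect_lt(abs(mean(cw$area_um2) / 2.5 - 1), 0.05)
  expect_lt(abs(mean(ck$area_um2) / 7.7 - 1), 0.05)
  expect_gte(mean(ck$area_um2) / mean(cw$area_um2), 3)
  # determinism
  wt2 <- renderApicalMosaic(cfg, "WT", seed = 5)
  expect_identical(wt$image, wt2$image)
  # regular grid seeds: jitter-free spacing-s tessellation gives s^2 cells
  expect_error(renderApicalMosaic(simulationConfig(
    apicalModel = list(mosaicShapePx = c(8L, 8L))), "WT"), "degenerate")
})

test_that("simulatePlate emits matching plate map, truth and fields", {
  cfg <- simulationConfig(fieldShapePx = c(256L, 256L),
                          nOrganoidsPerField = c(2L, 3L))
  plate <- simulatePlate(cfg, mosaicDesign(), seed = 9)
  expect_equal(sort(unique(plate$plateMap$ko_fraction)),
               c(0, 0.125, 0.25, 0.5, 0.75, 1))
  expect_equal(nrow(plate$plateMap), 6L)
  expect_length(plate$fields, 6L)
  expect_setequal(unique(truthOrganoids(plate$truth)$well),
                  plate$plateMap$well)

  empty <- simulatePlate(cfg, list(), seed = 9)
  expect_length(empty$fields, 0L)
  expect_equal(nrow(empty$plateMap), 0L)
  expect_equal(nrow(truthOrganoids(empty$truth)), 0L)
})
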