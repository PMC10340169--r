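# Independent oracles and shared fixtures for the test suite.

options(rosetteScreen.verbose = FALSE)

# ---- brute-force radial-profile oracle -------------------------------------
# Plain-loop reimplementation of the six-ring radial distribution: for every
# in-object pixel, interpolate the contour radius at the pixel's angle by a
# linear scan over the sorted contour angles, bin by ceiling(d * nRings), and
# accumulate intensity and pixel counts.
radialOracle <- function(intensity, mask, nRings = 6L) {
  w <- which(mask > 0, arr.ind = TRUE)
  cr <- mean(w[, 1L]); cc <- mean(w[, 2L])
  ct <- EBImage::ocontour(EBImage::Image((mask > 0) * 1))[[1L]] + 1
  th <- atan2(ct[, 1L] - cr, ct[, 2L] - cc)
  rd <- sqrt((ct[, 1L] - cr)^2 + (ct[, 2L] - cc)^2)
  o <- order(th, -rd)
  th <- th[o]; rd <- rd[o]
  keep <- !duplicated(th)
  th <- th[keep]; rd <- rd[keep]
  k <- length(th)
  thExt <- c(th[k] - 2 * pi, th, th[1L] + 2 * pi)
  rdExt <- c(rd[k], rd, rd[1L])
  interp <- function(q) {
    for (i in seq_len(length(thExt) - 1L)) {
      if (q >= thExt[i] && q <= thExt[i + 1L]) {
        f <- if (thExt[i + 1L] > thExt[i])
          (q - thExt[i]) / (thExt[i + 1L] - thExt[i]) else 0
        return(rdExt[i] * (1 - f) + rdExt[i + 1L] * f)
      }
    }
    rdExt[length(rdExt)]
  }
  sums <- numeric(nRings); counts <- integer(nRings)
  for (j in seq_len(nrow(w))) {
    pth <- atan2(w[j, 1L] - cr, w[j, 2L] - cc)
    prr <- sqrt((w[j, 1L] - cr)^2 + (w[j, 2L] - cc)^2)
    d <- min(max(prr / max(interp(pth), 1e-9), 0), 1)
    ring <- min(max(ceiling(d * nRings), 1L), nRings)
    sums[ring] <- sums[ring] + intensity[w[j, 1L], w[j, 2L]]
    counts[ring] <- counts[ring] + 1L
  }
  total <- sum(sums)
  frac <- if (total > 0) sums / total else rep(0, nRings)
  pixFrac <- counts / nrow(w)
  list(frac = frac,
       meanFrac = ifelse(pixFrac > 0, frac / pixFrac, 0))
}

# random smooth star-shaped blob mask (centroid inside by construction)
randomBlobMask <- function(size = 61L, baseRadius = 22, amp = 0.18) {
  ctr <- (size + 1) / 2
  a1 <- runif(1, 0, amp); a2 <- runif(1, 0, amp / 2)
  p1 <- runif(1, 0, 2 * pi); p2 <- runif(1, 0, 2 * pi)
  r <- outer(seq_len(size) - ctr, seq_len(size) - ctr,
             function(dr, dc) sqrt(dr^2 + dc^2))
  th <- outer(seq_len(size) - ctr, seq_len(size) - ctr, atan2)
  r <= baseRadius * (1 + a1 * cos(3 * th + p1) + a2 * cos(5 * th + p2))
}

# rasterized disk mask
diskMask <- function(size, radiusPx, center = (size + 1) / 2) {
  outer(seq_len(size), seq_len(size),
        function(r, c) (r - center)^2 + (c - center)^2 <= radiusPx^2)
}

# ---- shared expensive fixtures (built once per test run) -------------------
.fixtures <- new.env(parent = emptyenv())

# default-conditions 8-dose plate with full features (the headline
# parameter-recovery fixture; ~40 retained organoids per dose)
dosePlateFixture <- function() {
  if (is.null(.fixtures$dose)) {
    cfg <- simulationConfig(fieldsPerWell = 2L)
    plate <- simulatePlate(cfg, doseDesign(), seed = 101)
    res <- runAnalyze(plate$fields, plate$plateMap)
    .fixtures$dose <- list(plate = plate, res = res)
  }
  .fixtures$dose
}

# 6-level mosaic knockout plate (radial-centric families for speed)
mosaicPlateFixture <- function() {
  if (is.null(.fixtures$mosaic)) {
    cfg <- simulationConfig(fieldsPerWell = 3L)
    plate <- simulatePlate(cfg, mosaicDesign(), seed = 202)
    res <- runAnalyze(plate$fields, plate$plateMap,
                      families = c("shape", "intensity", "radial",
                                   "engineered"))
    .fixtures$mosaic <- list(plate = plate, res = res)
  }
  .fixtures$mosaic
}

# small noise-free config for geometry-accuracy tests
noiseFreeConfig <- function(...) {
  simulationConfig(fieldShapePx = c(512L, 512L),
                   nOrganoidsPerField = c(6L, 6L), fusionProb = 0,
                   bodyWobbleAmp = 0,
                   noise = list(gaussianSd = 0, poissonScale = 0,
                                psfSigmaPx = 0), ...)
}
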