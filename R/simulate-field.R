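# Synthetic two-channel organoid field renderer.
#
# Each organoid is a star-shaped body (counterstain channel) containing a
# single bright lumen-boundary ring (marker channel). Knockout conditions
# get lobed lumens and a basal marker rim; fusion events merge two bodies
# into one object carrying two lumens. Image formation is Gaussian PSF blur
# followed by Poisson and Gaussian noise.

# per-organoid generative parameters (no placement, no rasterization)
#' @noRd
drawOrganoidParams <- function(n, condition, config) {
  if (n == 0L) {
    return(data.frame(radius_um = numeric(0), rho = numeric(0),
                      lobe_amp = numeric(0), lobe_phase = numeric(0),
                      brightness = numeric(0)))
  }
  rr <- config$organoidRadiusUm
  radius <- rnorm(n, rr$mean, rr$sd)
  radius <- pmin(pmax(radius, rr$min), rr$max)
  cr <- conditionRho(condition, config)
  amp <- config$dysmorphology$lobeAmpMax * cr$effect
  # lumens sit off-centre in real rosettes; offset as a fraction of the
  # organoid radius, capped so the lumen stays interior
  offFrac <- runif(n, 0, config$lumenOffsetMax)
  rho <- rnorm(n, cr$rho, config$rhoSd)
  rho <- pmin(pmax(rho, 0.05), (0.85 - offFrac) / (1 + amp))
  data.frame(
    radius_um = radius, rho = rho,
    lobe_amp = rep(amp, n),
    lobe_phase = runif(n, 0, 2 * pi),
    wobble_amp = runif(n, 0, config$bodyWobbleAmp),
    wobble_phase = runif(n, 0, 2 * pi),
    off_frac = offFrac,
    off_angle = runif(n, 0, 2 * pi),
    brightness = rlnorm(n, 0, 0.1),
    stain = rlnorm(n, 0, config$stainSd)
  )
}

#' Sample ground-truth organoid geometry without rendering
#'
#' Fast path drawing per-organoid generative truth (radius, lumen fraction,
#' analytic areas) for a condition, without rasterizing images. Useful for
#' studying the generative model itself at large n.
#'
#' @param n number of organoids.
#' @param condition a [wellCondition()].
#' @param config a [simulationConfig()].
#' @param seed integer seed.
#' @return data.frame with one row per organoid: `radius_um`, `rho`,
#'   `body_area_um2`, `lumen_area_um2`, `area_ratio` and the condition labels.
#' @export
sampleOrganoidGeometry <- function(n, condition, config = simulationConfig(),
                                   seed = config$seed) {
  set.seed(seed)
  p <- drawOrganoidParams(n, condition, config)
  # area of r(theta) = rho R (1 + a cos(k theta + phi)) is pi rho^2 R^2 (1 + a^2/2)
  body <- pi * p$radius_um^2 * (1 + p$wobble_amp^2 / 2)
  lumen <- pi * (p$rho * p$radius_um)^2 * (1 + p$lobe_amp^2 / 2)
  data.frame(
    radius_um = p$radius_um, rho = p$rho,
    body_area_um2 = body, lumen_area_um2 = lumen,
    area_ratio = lumen / body,
    drug = condition$drug, concentration_um = condition$concentrationUm,
    genotype = condition$genotype, ko_fraction = condition$koFraction
  )
}

# boundary radius functions (px) for one organoid subunit
#' @noRd
bodyRadiusPx <- function(theta, p, px) {
  p$radius_um / px * (1 + p$wobble_amp * cos(2 * theta + p$wobble_phase))
}
#' @noRd
lumenRadiusPx <- function(theta, p, px, nLobes) {
  p$rho * p$radius_um / px *
    (1 + p$lobe_amp * cos(nLobes * theta + p$lobe_phase))
}

# rasterize one subunit into the field accumulators (by reference semantics:
# returns updated list). center = c(row, col) in px.
#' @noRd
paintSubunit <- function(acc, center, p, config) {
  px <- config$pixelSizeUm
  nL <- config$dysmorphology$nLobes
  rmaxPx <- p$radius_um / px * (1 + p$wobble_amp) + 2
  nr <- nrow(acc$counterstain); nc <- ncol(acc$counterstain)
  r0 <- max(1L, floor(center[1L] - rmaxPx)); r1 <- min(nr, ceiling(center[1L] + rmaxPx))
  c0 <- max(1L, floor(center[2L] - rmaxPx)); c1 <- min(nc, ceiling(center[2L] + rmaxPx))
  rows <- r0:r1; cols <- c0:c1
  dr <- matrix(rows - center[1L], length(rows), length(cols))
  dc <- matrix(cols - center[2L], length(rows), length(cols), byrow = TRUE)
  rad <- sqrt(dr^2 + dc^2)
  theta <- atan2(dr, dc)
  Ro <- bodyRadiusPx(theta, p, px)
  inBody <- rad <= Ro
  # lumen centre sits off the body centre by off_frac of the radius
  offPx <- p$off_frac * p$radius_um / px
  drL <- dr - offPx * sin(p$off_angle)
  dcL <- dc - offPx * cos(p$off_angle)
  radL <- sqrt(drL^2 + dcL^2)
  thetaL <- atan2(drL, dcL)
  Rl <- lumenRadiusPx(thetaL, p, px, nL)
  inLumen <- radL <= Rl
  sigma <- config$ringSigmaUm / px
  ring <- p$stain * config$ringIntensity *
    exp(-(radL - Rl)^2 / (2 * sigma^2))
  ring[!inBody] <- 0
  counter <- ifelse(inBody, config$bodyIntensity * p$brightness, 0)
  markerBase <- p$stain *
    ifelse(inLumen, config$lumenInteriorIntensity,
           ifelse(inBody, config$cytoplasmIntensity, 0))
  if (p$lobe_amp > 0 || p$basal_gain > 0) {
    rim <- inBody & rad > 0.9 * Ro
    markerBase[rim] <- markerBase[rim] + p$stain * p$basal_gain
  }
  marker <- pmax(markerBase, ring)
  acc$counterstain[rows, cols] <- pmax(acc$counterstain[rows, cols], counter)
  acc$marker[rows, cols] <- pmax(acc$marker[rows, cols], marker)
  acc
}

# closed polygon (um, field coordinates) of a subunit boundary
#' @noRd
subunitPolygon <- function(center, p, config, what = c("body", "lumen"),
                           nTheta = 256L) {
  what <- match.arg(what)
  px <- config$pixelSizeUm
  theta <- seq(0, 2 * pi, length.out = nTheta + 1L)[-(nTheta + 1L)]
  if (what == "body") {
    rpx <- bodyRadiusPx(theta, p, px)
    ctr <- center
  } else {
    rpx <- lumenRadiusPx(theta, p, px, config$dysmorphology$nLobes)
    offPx <- p$off_frac * p$radius_um / px
    ctr <- center + offPx * c(sin(p$off_angle), cos(p$off_angle))
  }
  cbind(x_um = (ctr[2L] + rpx * cos(theta)) * px,
        y_um = (ctr[1L] + rpx * sin(theta)) * px)
}

# area of the union of two circles (um^2) at centre distance d
#' @noRd
circleUnionArea <- function(r1, r2, d) {
  if (d >= r1 + r2) return(pi * (r1^2 + r2^2))
  if (d <= abs(r1 - r2)) return(pi * max(r1, r2)^2)
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  lens <- a1 + a2 - 0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) *
                               (d - r1 + r2) * (d + r1 + r2))
  pi * (r1^2 + r2^2) - lens
}

#' Render one synthetic two-channel field
#'
#' Draws a field of single-rosette organoids under one well condition:
#' counterstain channel = filled organoid bodies; marker channel = bright
#' ring at each lumen boundary plus dim cytoplasm. Knockout-bearing
#' conditions get lobed (dysmorphic) lumens and a basal marker rim whose
#' strength scales with the knockout fraction; with probability
#' \code{fusionProb} an organoid is rendered as a fusion of two bodies
#' carrying two lumens. The image is then blurred by a Gaussian PSF and
#' corrupted by Poisson and Gaussian noise. Identical (config, condition,
#' seed) produce bit-identical output.
#'
#' @param config a [simulationConfig()].
#' @param condition a [wellCondition()].
#' @param seed integer seed (defaults to `config$seed`).
#' @param plateWell,fieldIndex provenance attached to the output field.
#' @return list with elements `field` ([FieldImage-class], channels
#'   counterstain + lumen_marker) and `truth` ([GroundTruth-class]).
#' @examples
#' cfg <- simulationConfig(fieldShapePx = c(192, 192),
#'                         nOrganoidsPerField = c(2L, 2L))
#' out <- renderField(cfg, wellCondition("VPA", 400), seed = 7)
#' truthOrganoids(out$truth)
#' @export
renderField <- function(config, condition, seed = config$seed,
                        plateWell = "A01", fieldIndex = 1L) {
  set.seed(seed)
  shape <- config$fieldShapePx
  px <- config$pixelSizeUm
  nRange <- config$nOrganoidsPerField
  n <- if (nRange[1L] == nRange[2L]) nRange[1L] else
    sample(seq.int(nRange[1L], nRange[2L]), 1L)
  params <- drawOrganoidParams(n, condition, config)
  cr <- conditionRho(condition, config)
  params$basal_gain <- config$basalGainMax * cr$effect
  fused <- runif(n) < config$fusionProb

  acc <- list(counterstain = matrix(0, shape[1L], shape[2L]),
              marker = matrix(0, shape[1L], shape[2L]))
  truth <- list(); polys <- list()
  centers <- matrix(numeric(0), 0L, 2L); extents <- numeric(0)

  for (i in seq_len(n)) {
    p <- params[i, ]
    if (fused[i]) {
      p2 <- drawOrganoidParams(1L, condition, config)
      p2$basal_gain <- p$basal_gain
      dPx <- 0.75 * (p$radius_um + p2$radius_um) / px
      extent <- max((p$radius_um / px) * (1 + p$wobble_amp),
                    dPx + (p2$radius_um / px) * (1 + p2$wobble_amp))
    } else {
      extent <- (p$radius_um / px) * (1 + p$wobble_amp)
    }
    ok <- FALSE
    for (try in seq_len(200L)) {
      if (shape[1L] - 2 * extent - 6 <= 0 || shape[2L] - 2 * extent - 6 <= 0)
        break   # cannot fit this organoid at all
      ctr <- c(runif(1, extent + 3, shape[1L] - extent - 3),
               runif(1, extent + 3, shape[2L] - extent - 3))
      if (nrow(centers)) {
        dd <- sqrt((centers[, 1L] - ctr[1L])^2 + (centers[, 2L] - ctr[2L])^2)
        if (any(dd < (extents + extent) * 1.05 + 4)) next
      }
      ok <- TRUE; break
    }
    if (!ok) next   # field too crowded; organoid dropped after retry cap
    centers <- rbind(centers, ctr); extents <- c(extents, extent)
    id <- length(truth) + 1L
    if (fused[i]) {
      ang <- runif(1, 0, 2 * pi)
      ctr2 <- ctr + dPx * c(sin(ang), cos(ang))
      acc <- paintSubunit(acc, ctr, p, config)
      acc <- paintSubunit(acc, ctr2, p2, config)
      bodyArea <- circleUnionArea(p$radius_um, p2$radius_um, dPx * px)
      lumArea <- pi * (p$rho * p$radius_um)^2 * (1 + p$lobe_amp^2 / 2) +
                 pi * (p2$rho * p2$radius_um)^2 * (1 + p2$lobe_amp^2 / 2)
      polys[[id]] <- list(body = list(subunitPolygon(ctr, p, config, "body"),
                                      subunitPolygon(ctr2, p2, config, "body")),
                          lumens = list(subunitPolygon(ctr, p, config, "lumen"),
                                        subunitPolygon(ctr2, p2, config, "lumen")))
      truth[[id]] <- data.frame(
        id = id, center_row_px = ctr[1L], center_col_px = ctr[2L],
        radius_um = p$radius_um, rho = p$rho,
        body_area_um2 = bodyArea, lumen_area_um2 = lumArea,
        lumen_count = 2L, fused = TRUE)
    } else {
      acc <- paintSubunit(acc, ctr, p, config)
      bp <- subunitPolygon(ctr, p, config, "body")
      lp <- subunitPolygon(ctr, p, config, "lumen")
      polys[[id]] <- list(body = list(bp), lumens = list(lp))
      truth[[id]] <- data.frame(
        id = id, center_row_px = ctr[1L], center_col_px = ctr[2L],
        radius_um = p$radius_um, rho = p$rho,
        body_area_um2 = polygonArea(bp[, 1L], bp[, 2L]),
        lumen_area_um2 = polygonArea(lp[, 1L], lp[, 2L]),
        lumen_count = 1L, fused = FALSE)
    }
  }

  counter <- acc$counterstain; marker <- acc$marker
  nz <- config$noise
  if (nz$psfSigmaPx > 0) {
    counter <- as.matrix(EBImage::gblur(counter, sigma = nz$psfSigmaPx))
    marker <- as.matrix(EBImage::gblur(marker, sigma = nz$psfSigmaPx))
  }
  if (nz$poissonScale > 0) {
    counter <- matrix(rpois(length(counter), pmax(counter, 0) * nz$poissonScale),
                      shape[1L], shape[2L]) / nz$poissonScale
    marker <- matrix(rpois(length(marker), pmax(marker, 0) * nz$poissonScale),
                     shape[1L], shape[2L]) / nz$poissonScale
  }
  if (nz$gaussianSd > 0) {
    counter <- counter + rnorm(length(counter), 0, nz$gaussianSd)
    marker <- marker + rnorm(length(marker), 0, nz$gaussianSd)
  }
  counter <- pmax(counter, 0); marker <- pmax(marker, 0)

  truthDf <- if (length(truth)) do.call(rbind, truth) else
    data.frame(id = integer(0), center_row_px = numeric(0),
               center_col_px = numeric(0), radius_um = numeric(0),
               rho = numeric(0), body_area_um2 = numeric(0),
               lumen_area_um2 = numeric(0), lumen_count = integer(0),
               fused = logical(0))
  if (nrow(truthDf)) {
    truthDf$drug <- condition$drug
    truthDf$concentration_um <- condition$concentrationUm
    truthDf$genotype <- condition$genotype
    truthDf$ko_fraction <- condition$koFraction
    truthDf$well <- plateWell
    truthDf$field_index <- fieldIndex
  }
  pxArr <- array(0, c(shape[1L], shape[2L], 1L, 2L))
  pxArr[, , 1L, 1L] <- counter; pxArr[, , 1L, 2L] <- marker
  field <- fieldImage(pxArr, c("counterstain", "lumen_marker"), px,
                      plateWell, fieldIndex)
  truthObj <- new("GroundTruth", organoids = truthDf,
                  cells = data.frame(), polygons = polys)
  list(field = field, truth = truthObj)
}

#' Rasterize ground-truth polygons into a label mask
#'
#' Even-odd point-in-polygon rasterization of the simulator's body (or
#' lumen) polygons, for oracle comparisons against segmentation output.
#'
#' @param truth a [GroundTruth-class] from [renderField()].
#' @param shapePx field shape in pixels, c(rows, cols).
#' @param pixelSizeUm micrometres per pixel used at render time.
#' @param what `"body"` or `"lumen"`.
#' @return integer label matrix; fused bodies share one label, each lumen of
#'   a fused body gets its own label offset by the organoid id.
#' @export
rasterizeTruth <- function(truth, shapePx, pixelSizeUm,
                           what = c("body", "lumen")) {
  what <- match.arg(what)
  lab <- matrix(0L, shapePx[1L], shapePx[2L])
  polys <- truthPolygons(truth)
  k <- 0L
  for (i in seq_along(polys)) {
    ps <- if (what == "body") polys[[i]]$body else polys[[i]]$lumens
    for (pg in ps) {
      if (what == "body") lb <- i else { k <- k + 1L; lb <- k }
      xr <- range(pg[, 2L]) / pixelSizeUm; xc <- range(pg[, 1L]) / pixelSizeUm
      rows <- max(1L, floor(xr[1L])):min(shapePx[1L], ceiling(xr[2L]))
      cols <- max(1L, floor(xc[1L])):min(shapePx[2L], ceiling(xc[2L]))
      inside <- pointsInPolygon(
        rep(rows, times = length(cols)) * pixelSizeUm,
        rep(cols, each = length(rows)) * pixelSizeUm,
        pg[, 2L], pg[, 1L])
      sel <- matrix(inside, length(rows), length(cols))
      blk <- lab[rows, cols]
      blk[sel] <- lb
      lab[rows, cols] <- blk
    }
  }
  lab
}

# even-odd rule point-in-polygon test, vectorized over query points
#' @noRd
pointsInPolygon <- function(py, pxx, vy, vx) {
  n <- length(vy)
  inside <- logical(length(py))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vy[i] > py) != (vy[j] > py)) &
      (pxx < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}
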