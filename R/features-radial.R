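# Six-ring radial intensity distribution of a channel within an object.

# piecewise-linear periodic interpolation of contour radius vs angle
#' @noRd
contourRadiusInterp <- function(theta, rad) {
  o <- order(theta, -rad)
  th <- theta[o]; rr <- rad[o]
  # collapse exactly duplicated angles to their maximum radius
  keep <- !duplicated(th)
  th <- th[keep]; rr <- rr[keep]
  thExt <- c(th[length(th)] - 2 * pi, th, th[1L] + 2 * pi)
  rrExt <- c(rr[length(rr)], rr, rr[1L])
  function(q) {
    i <- findInterval(q, thExt, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), length(thExt) - 1L)
    t0 <- thExt[i]; t1 <- thExt[i + 1L]
    f <- ifelse(t1 > t0, (q - t0) / (t1 - t0), 0)
    rrExt[i] * (1 - f) + rrExt[i + 1L] * f
  }
}

#' Radial intensity profile in six concentric rings
#'
#' For every pixel of an object, the normalized radial coordinate is
#' \eqn{d = \lVert p - c\rVert / R(\theta_p)}: the distance to the object
#' centroid divided by the centroid-to-edge distance along the same ray
#' (piecewise-linear interpolation of the object contour radius over
#' angle), clipped to [0, 1]. Ring i covers \eqn{((i-1)/n, i/n]} with d = 0
#' falling in ring 1. `frac_at_d[i]` is the fraction of the object's total
#' intensity in ring i (summing to 1 for any object with signal);
#' `mean_frac[i]` divides that by ring i's pixel fraction, so a uniformly
#' lit object scores 1 in every ring. Edge-scaled rings make profiles
#' comparable across organoid sizes.
#'
#' If the centroid falls outside the object (pathological shapes) the
#' normalization falls back to the Euclidean distance transform
#' (\eqn{d = 1 - DT(p)/\max DT}) and the profile is flagged.
#'
#' @param intensity 2D numeric matrix.
#' @param mask logical matrix marking the object (same shape).
#' @param nRings number of rings (default 6).
#' @return data.frame with columns `ring`, `frac_at_d`, `mean_frac`,
#'   `pixel_frac`, plus attributes `flagged` (logical) and `zero_total`.
#' @examples
#' m <- outer(1:41, 1:41, function(r, c) (r - 21)^2 + (c - 21)^2 <= 18^2)
#' radialProfile(matrix(1, 41, 41), m)$mean_frac
#' @export
radialProfile <- function(intensity, mask, nRings = 6L) {
  mask <- mask > 0
  stopIfNot(any(mask), "region is empty")
  stopIfNot(all(dim(intensity) == dim(mask)), "shape mismatch")
  w <- which(mask, arr.ind = TRUE)
  cr <- mean(w[, 1L]); cc <- mean(w[, 2L])
  vals <- intensity[mask]
  total <- sum(vals)
  flagged <- FALSE
  ri <- as.integer(round(cr)); ci <- as.integer(round(cc))
  centroidInside <- ri >= 1L && ri <= nrow(mask) && ci >= 1L &&
    ci <= ncol(mask) && mask[ri, ci]
  if (centroidInside && nrow(w) > 2L) {
    ct <- maskContour(mask)
    dth <- atan2(ct[, 1L] - cr, ct[, 2L] - cc)
    drr <- sqrt((ct[, 1L] - cr)^2 + (ct[, 2L] - cc)^2)
    R <- contourRadiusInterp(dth, drr)
    pth <- atan2(w[, 1L] - cr, w[, 2L] - cc)
    prr <- sqrt((w[, 1L] - cr)^2 + (w[, 2L] - cc)^2)
    Rp <- pmax(R(pth), 1e-9)
    d <- pmin(pmax(prr / Rp, 0), 1)
  } else {
    flagged <- TRUE
    dt <- as.matrix(EBImage::distmap(EBImage::Image(mask * 1)))
    dmax <- max(dt[mask])
    d <- if (dmax > 0) 1 - dt[mask] / dmax else rep(0, nrow(w))
  }
  ring <- pmin(pmax(ceiling(d * nRings), 1L), nRings)
  nPix <- tabulate(ring, nRings)
  pixelFrac <- nPix / nrow(w)
  if (total > 0) {
    sums <- vapply(seq_len(nRings), function(i) sum(vals[ring == i]), 0)
    frac <- sums / total
    zeroTotal <- FALSE
  } else {
    frac <- rep(0, nRings)
    zeroTotal <- TRUE
  }
  meanFrac <- ifelse(pixelFrac > 0, frac / pixelFrac, 0)
  out <- data.frame(ring = seq_len(nRings), frac_at_d = frac,
                    mean_frac = meanFrac, pixel_frac = pixelFrac)
  attr(out, "flagged") <- flagged
  attr(out, "zero_total") <- zeroTotal
  out
}

#' Max-normalize group-mean radial profiles
#'
#' Divides each condition's 6-ring mean-fraction vector by its own maximum
#' entry, the normalization used to draw cross-condition radial heatmaps:
#' outputs lie in [0, 1] with at least one entry equal to 1 per condition.
#' All-zero vectors are left as zeros and flagged.
#'
#' @param profiles numeric matrix (conditions x rings) or a single vector.
#' @return object of the same shape, normalized row-wise; attribute
#'   `flagged_zero` names all-zero rows.
#' @examples
#' maxNormalizeProfiles(rbind(a = c(2, 4, 1, 1, 1, 1)))
#' @export
maxNormalizeProfiles <- function(profiles) {
  vec <- is.null(dim(profiles))
  m <- if (vec) matrix(profiles, nrow = 1L) else as.matrix(profiles)
  mx <- apply(m, 1L, max)
  zero <- mx <= 0
  out <- m
  out[!zero, ] <- m[!zero, , drop = FALSE] / mx[!zero]
  attr(out, "flagged_zero") <- which(zero)
  if (vec) out[1L, ] else out
}

#' Square-root-transformed normalized lumen area
#'
#' The engineered phenotype metric: \eqn{\sqrt{A_{lumen}/A_{organoid}}}.
#' Lumen areas marginally above the organoid area (mask discretization) are
#' clipped to the organoid area with a warning attribute.
#'
#' @param lumenAreaUm2,organoidAreaUm2 areas in square micrometres
#'   (vectorized; organoid area must be positive).
#' @return values in [0, 1].
#' @examples
#' areaRatioSqrt(c(0, 2500), c(10000, 10000))
#' @export
areaRatioSqrt <- function(lumenAreaUm2, organoidAreaUm2) {
  if (any(organoidAreaUm2 <= 0)) stop("organoid area must be positive",
                                      call. = FALSE)
  if (any(lumenAreaUm2 < 0)) stop("lumen area must be non-negative",
                                  call. = FALSE)
  clipped <- lumenAreaUm2 > organoidAreaUm2
  ratio <- pmin(lumenAreaUm2 / organoidAreaUm2, 1)
  out <- sqrt(ratio)
  attr(out, "clipped") <- which(clipped)
  out
}
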