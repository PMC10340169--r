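# Zernike moment magnitudes of the intensity distribution within a region.

# (n, m) index pairs with n <= maxDegree, m >= 0, n - m even
#' @noRd
zernikeIndices <- function(maxDegree = 9L) {
  idx <- list()
  for (n in 0:maxDegree) for (m in seq(n %% 2L, n, by = 2L))
    idx[[length(idx) + 1L]] <- c(n, m)
  do.call(rbind, idx)
}

# radial polynomial R_nm evaluated at r (vectorized)
#' @noRd
zernikeRadial <- function(n, m, r) {
  out <- numeric(length(r))
  for (s in 0:((n - m) %/% 2L)) {
    coef <- (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m) %/% 2L - s) *
         factorial((n - m) %/% 2L - s))
    out <- out + coef * r^(n - 2L * s)
  }
  out
}

#' Zernike moment magnitudes of a masked intensity image
#'
#' Projects the intensity distribution inside a region onto the Zernike
#' polynomial basis on the unit disk (region scaled by its centroid and
#' maximum radius, intensities normalized to unit sum) and returns the
#' rotation-invariant magnitudes for all degrees n <= `maxDegree` (30
#' values for the default degree 9).
#'
#' @param intensity 2D numeric matrix.
#' @param mask logical matrix marking the region.
#' @param maxDegree maximum polynomial degree (default 9).
#' @return named numeric vector `z_n<k>_m<l>` of moment magnitudes.
#' @export
zernikeMoments <- function(intensity, mask, maxDegree = 9L) {
  mask <- mask > 0
  stopIfNot(any(mask), "region is empty")
  w <- which(mask, arr.ind = TRUE)
  cr <- mean(w[, 1L]); cc <- mean(w[, 2L])
  dy <- w[, 1L] - cr; dx <- w[, 2L] - cc
  rr <- sqrt(dy^2 + dx^2)
  rmax <- max(rr, 1e-9)
  r <- rr / rmax
  th <- atan2(dy, dx)
  vals <- intensity[mask]
  tot <- sum(vals)
  wgt <- if (tot > 0) vals / tot else rep(1 / length(vals), length(vals))
  idx <- zernikeIndices(maxDegree)
  out <- numeric(nrow(idx))
  nms <- character(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    n <- idx[i, 1L]; m <- idx[i, 2L]
    Rnm <- zernikeRadial(n, m, r)
    re <- sum(wgt * Rnm * cos(m * th))
    im <- -sum(wgt * Rnm * sin(m * th))
    out[i] <- (n + 1) / pi * sqrt(re^2 + im^2)
    nms[i] <- sprintf("z_n%d_m%d", n, m)
  }
  setNames(out, nms)
}
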