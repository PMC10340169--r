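# Organoid-body and lumen segmentation from 2D projected fields.

#' Segment organoid bodies from the counterstain channel
#'
#' Gaussian smoothing, thresholding (automatic Otsu by default, or a manual
#' min/max intensity window), binary hole filling, small-object removal and
#' 8-connected labeling. Border-touching objects are kept in the mask but
#' recorded in the mask's `borderLabels` so downstream statistics can
#' exclude their censored areas. An all-background image yields an empty
#' mask (0 objects), not an error. The procedure is fully deterministic.
#'
#' @param counterstain 2D numeric matrix, or a [FieldImage-class] (its
#'   counterstain channel is used after maximum projection).
#' @param pixelSizeUm micrometres per pixel (ignored when a FieldImage is
#'   supplied).
#' @param sigmaPx Gaussian smoothing sigma in pixels (default 2).
#' @param threshold `"otsu"` or a numeric c(min, max) intensity window:
#'   pixels with min <= intensity <= max become foreground.
#' @param minAreaUm2 objects smaller than this are removed (default 1000).
#' @return a [LabeledMask-class].
#' @seealso [segmentLumens()], [assignLumens()]
#' @export
segmentOrganoids <- function(counterstain, pixelSizeUm = 1.3, sigmaPx = 2,
                             threshold = "otsu", minAreaUm2 = 1000) {
  if (is(counterstain, "FieldImage")) {
    pixelSizeUm <- pixelSize(counterstain)
    counterstain <- getChannel(maxProject(counterstain), "counterstain")
  }
  stopIfNot(is.matrix(counterstain), "counterstain must be a 2D image")
  img <- counterstain
  if (sigmaPx > 0) img <- as.matrix(EBImage::gblur(img, sigma = sigmaPx))
  if (identical(threshold, "otsu")) {
    rng <- range(img)
    if (rng[2L] <= rng[1L]) {
      bin <- matrix(FALSE, nrow(img), ncol(img))       # constant image
    } else {
      sc <- (img - rng[1L]) / (rng[2L] - rng[1L])
      bin <- sc > EBImage::otsu(EBImage::Image(sc))
    }
  } else {
    stopIfNot(is.numeric(threshold) && length(threshold) == 2L,
              "threshold must be 'otsu' or c(min, max)")
    bin <- img >= threshold[1L] & img <= threshold[2L]
  }
  if (!any(bin))
    return(labeledMask(matrix(0L, nrow(img), ncol(img)), pixelSizeUm,
                       "counterstain"))
  filled <- EBImage::fillHull(EBImage::Image(bin * 1)) > 0.5
  lab <- label8(filled)
  areas <- tabulate(lab[lab > 0L])
  drop <- which(areas * pixelSizeUm^2 < minAreaUm2)
  if (length(drop)) lab[lab %in% drop] <- 0L
  labeledMask(lab, pixelSizeUm, "counterstain")
}

#' Segment apical lumens within organoid footprints
#'
#' Within each organoid's footprint the lumen-marker channel is thresholded
#' (Otsu on the in-footprint intensities), the resulting boundary ring is
#' morphologically closed and hole-filled, and the lumen is taken as the
#' region enclosed by the ring: the filled component is eroded back to the
#' ring's centreline radius (half the ring thickness, estimated per
#' component from the filled and interior equivalent radii) via a Euclidean
#' distance-transform threshold. Lumens are confined to organoid footprints
#' by construction; components smaller than `minLumenAreaUm2` are
#' discarded. An organoid with no detectable marker signal simply yields no
#' lumens.
#'
#' @param marker 2D numeric matrix of the lumen-marker channel, or a
#'   [FieldImage-class] (its lumen_marker channel after maximum projection).
#' @param organoids [LabeledMask-class] from [segmentOrganoids()].
#' @param sigmaPx Gaussian smoothing sigma (default 1).
#' @param closeRadiusPx radius of the morphological closing brush applied to
#'   the ring (default 3).
#' @param minLumenAreaUm2 minimum lumen area retained (default 50).
#' @param marginFraction fraction of the organoid's equivalent radius
#'   stripped from its margin before ring detection (default 0.12). The
#'   lumen is an interior structure; excluding the basal margin keeps
#'   basally localized marker signal (seen under knockout of apical
#'   constriction genes) from being mistaken for a lumen boundary.
#' @return a [LabeledMask-class] of lumens.
#' @export
segmentLumens <- function(marker, organoids, sigmaPx = 1, closeRadiusPx = 3,
                          minLumenAreaUm2 = 50, marginFraction = 0.12) {
  if (is(marker, "FieldImage"))
    marker <- getChannel(maxProject(marker), "lumen_marker")
  lab <- maskLabels(organoids)
  stopIfNot(all(dim(marker) == dim(lab)),
            "marker and organoid mask shapes differ")
  px <- pixelSize(organoids)
  out <- matrix(0L, nrow(lab), ncol(lab))
  img <- if (sigmaPx > 0) as.matrix(EBImage::gblur(marker, sigma = sigmaPx))
         else marker
  brush <- EBImage::makeBrush(2L * as.integer(closeRadiusPx) + 1L, "disc")
  nextLab <- 0L
  for (k in seq_len(nObjects(organoids))) {
    foot <- lab == k
    if (marginFraction > 0) {
      rEq <- sqrt(sum(foot) / pi)
      fb <- bbox(foot, pad = 1L)
      fsubm <- foot[fb[1L]:fb[2L], fb[3L]:fb[4L]]
      dtf <- as.matrix(EBImage::distmap(EBImage::Image(fsubm * 1)))
      core <- matrix(FALSE, nrow(foot), ncol(foot))
      core[fb[1L]:fb[2L], fb[3L]:fb[4L]] <- dtf > marginFraction * rEq
      foot <- foot & core
      if (!any(foot)) next
    }
    vals <- img[foot]
    rng <- range(vals)
    if (rng[2L] <= rng[1L]) next
    sc <- (vals - rng[1L]) / (rng[2L] - rng[1L])
    th <- EBImage::otsu(EBImage::Image(matrix(sc, ncol = 1L)))
    ring <- foot & ((img - rng[1L]) / (rng[2L] - rng[1L])) > th
    ring[!foot] <- FALSE
    if (!any(ring)) next
    bb <- bbox(ring, pad = as.integer(closeRadiusPx) + 2L)
    sub <- ring[bb[1L]:bb[2L], bb[3L]:bb[4L]]
    closed <- EBImage::closing(EBImage::Image(sub * 1), brush) > 0.5
    filledI <- EBImage::fillHull(EBImage::Image(closed * 1)) > 0.5
    comp <- label8(filledI)
    for (cid in seq_len(max(comp, 0L))) {
      cm <- comp == cid
      aFill <- sum(cm)
      interior <- cm & !closed
      aInt <- sum(interior)
      if (aFill * px^2 < minLumenAreaUm2) next
      rOut <- sqrt(aFill / pi); rIn <- sqrt(max(aInt, 0L) / pi)
      wHalf <- max((rOut - rIn) / 2, 0)
      dt <- EBImage::distmap(EBImage::Image(cm * 1))
      lum <- cm & as.matrix(dt) > wHalf
      if (!any(lum)) lum <- cm   # sub-resolution lumen: keep the blob core
      nextLab <- nextLab + 1L
      blk <- out[bb[1L]:bb[2L], bb[3L]:bb[4L]]
      # confine to this organoid's footprint
      fsub <- foot[bb[1L]:bb[2L], bb[3L]:bb[4L]]
      blk[lum & fsub] <- nextLab
      out[bb[1L]:bb[2L], bb[3L]:bb[4L]] <- blk
    }
  }
  labeledMask(out, px, "lumen_marker")
}

#' Assign lumens to organoids
#'
#' Each lumen is assigned to the organoid whose footprint contains the
#' lumen's centroid; a lumen whose centroid falls on background is flagged
#' as an orphan and excluded from per-organoid counts.
#'
#' @param organoids,lumens [LabeledMask-class] objects sharing shape and
#'   calibration.
#' @return list with `assignment` (named list organoid label -> integer
#'   vector of lumen labels), `lumenCount` (integer vector, one entry per
#'   organoid) and `orphans` (integer vector of orphan lumen labels).
#' @export
assignLumens <- function(organoids, lumens) {
  ol <- maskLabels(organoids); ll <- maskLabels(lumens)
  stopIfNot(all(dim(ol) == dim(ll)), "mask shapes differ")
  stopIfNot(isTRUE(all.equal(pixelSize(organoids), pixelSize(lumens))),
            "mask calibrations differ")
  nOrg <- nObjects(organoids); nLum <- nObjects(lumens)
  assignment <- setNames(rep(list(integer(0)), nOrg),
                         as.character(seq_len(nOrg)))
  orphans <- integer(0)
  if (nLum) {
    w <- which(ll > 0L, arr.ind = TRUE)
    labv <- ll[ll > 0L]
    cr <- tapply(w[, 1L], labv, mean)
    cc <- tapply(w[, 2L], labv, mean)
    for (j in seq_len(nLum)) {
      r <- as.integer(round(cr[[as.character(j)]]))
      c <- as.integer(round(cc[[as.character(j)]]))
      host <- ol[max(1L, min(r, nrow(ol))), max(1L, min(c, ncol(ol)))]
      if (host > 0L) assignment[[host]] <- c(assignment[[host]], j)
      else orphans <- c(orphans, j)
    }
  }
  list(assignment = assignment,
       lumenCount = vapply(assignment, length, integer(1L)),
       orphans = orphans)
}

#' Write a label mask and its objects table
#'
#' Emits the mask as a 16-bit TIFF plus a CSV of per-object label, centroid
#' (pixels), calibrated area and border flag.
#'
#' @param mask a [LabeledMask-class].
#' @param tiffPath,csvPath output paths (`NULL` skips either output).
#' @return the objects data.frame, invisibly.
#' @export
writeMask <- function(mask, tiffPath = NULL, csvPath = NULL) {
  lab <- maskLabels(mask)
  if (!is.null(tiffPath))
    tiff::writeTIFF(lab / 65535, tiffPath, bits.per.sample = 16L)
  df <- maskObjects(mask)
  if (!is.null(csvPath)) write.csv(df, csvPath, row.names = FALSE)
  invisible(df)
}

#' @rdname writeMask
#' @export
maskObjects <- function(mask) {
  lab <- maskLabels(mask)
  n <- nObjects(mask)
  if (!n)
    return(data.frame(label = integer(0), centroid_row_px = numeric(0),
                      centroid_col_px = numeric(0), area_um2 = numeric(0),
                      border = logical(0)))
  w <- which(lab > 0L, arr.ind = TRUE)
  labv <- lab[lab > 0L]
  data.frame(
    label = seq_len(n),
    centroid_row_px = as.numeric(tapply(w[, 1L], labv, mean)),
    centroid_col_px = as.numeric(tapply(w[, 2L], labv, mean)),
    area_um2 = tabulate(labv, n) * pixelSize(mask)^2,
    border = seq_len(n) %in% mask@borderLabels)
}
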