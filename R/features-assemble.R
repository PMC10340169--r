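# Assembly of the per-organoid feature vector.

CHANNEL_ABBREV <- c(counterstain = "cs", lumen_marker = "lm", aux = "aux")

# 20 summary statistics of a vector of pixel intensities
#' @noRd
intensityStats <- function(v) {
  m <- mean(v)
  s <- if (length(v) > 1L) sd(v) else 0
  q <- quantile(v, c(0.01, 0.05, 0.10, 0.25, 0.5, 0.75, 0.90, 0.95, 0.99),
                names = FALSE)
  z <- if (s > 0) (v - m) / s else rep(0, length(v))
  c(mean = m, sd = s, mad = mad(v), median = q[5L], min = min(v),
    max = max(v), q01 = q[1L], q05 = q[2L], q10 = q[3L], q25 = q[4L],
    q75 = q[6L], q90 = q[7L], q95 = q[8L], q99 = q[9L],
    iqr = q[6L] - q[4L], cv = if (m != 0) s / m else 0,
    skew = mean(z^3), kurt = mean(z^4) - 3,
    integrated = sum(v), upper_decile_mean = mean(v[v >= q[7L]]))
}

# Haralick texture features for all objects of a label mask on one channel,
# at three co-occurrence scales; rows indexed by object label.
#' @noRd
haralickFeatures <- function(labels, ref, scales = c(1L, 2L, 4L),
                             n = max(labels, 0L)) {
  mx <- max(ref)
  refN <- if (mx > 0) ref / mx else ref
  if (max(labels, 0L) == 0L) return(NULL)
  h <- EBImage::computeFeatures.haralick(
    EBImage::Image(labels), EBImage::Image(refN), haralick.scales = scales)
  # one row per label 1..max(labels) (absent labels yield NA rows);
  # re-shape to exactly n rows
  out <- matrix(NA_real_, n, ncol(h), dimnames = list(NULL, colnames(h)))
  m <- min(nrow(h), n)
  out[seq_len(m), ] <- h[seq_len(m), , drop = FALSE]
  out
}

#' Assemble per-organoid feature records for one field
#'
#' Concatenates the feature families measured on both masks (organoid body
#' and primary lumen) and both channels (counterstain, lumen marker) into
#' one row per organoid:
#' shape descriptors ([shapeFeatures()]), 20 intensity summaries per
#' channel/mask, the six-ring radial distribution ([radialProfile()];
#' `frac` and `mfrac` per ring), Zernike moment magnitudes to degree 9
#' ([zernikeMoments()]), Haralick texture at three co-occurrence scales,
#' and the engineered lumen metrics (`lumen_count`, [areaRatioSqrt()],
#' lumen-centroid offset) — over 400 numeric feature columns in total
#' (see [featureColumns()]).
#'
#' Organoids without a detectable lumen are retained with their
#' lumen-derived features set to `NA` and `lumen_missing = 1`. When an
#' organoid holds several lumens, lumen-mask features are measured on the
#' largest one while `lumen_count` records them all.
#'
#' @param field a 2D [FieldImage-class] (stacks are max-projected).
#' @param organoids [LabeledMask-class] from [segmentOrganoids()].
#' @param lumens [LabeledMask-class] from [segmentLumens()].
#' @param assignment optional result of [assignLumens()] (recomputed when
#'   missing).
#' @param families character subset of
#'   `c("shape", "intensity", "radial", "zernike", "texture", "engineered")`
#'   to compute (default all; trimming families speeds up large screens
#'   when only some metrics are needed).
#' @return data.frame with one row per organoid: metadata columns
#'   (`organoid_id`, `well`, `field_index`, `border`, `lumen_missing`,
#'   `radial_fallback`) plus the numeric feature columns.
#' @export
assembleRecords <- function(field, organoids, lumens, assignment = NULL,
                            families = c("shape", "intensity", "radial",
                                         "zernike", "texture", "engineered")) {
  families <- match.arg(families, several.ok = TRUE)
  field <- maxProject(field)
  px <- pixelSize(organoids)
  roles <- intersect(c("counterstain", "lumen_marker"), channelRoles(field))
  chans <- lapply(roles, function(r) getChannel(field, r))
  names(chans) <- CHANNEL_ABBREV[roles]
  olab <- maskLabels(organoids)
  llab <- maskLabels(lumens)
  if (is.null(assignment)) assignment <- assignLumens(organoids, lumens)
  nOrg <- nObjects(organoids)
  if (nOrg == 0L) return(data.frame())

  # primary (largest) lumen per organoid, relabeled to the organoid id
  lumAreasPx <- tabulate(llab[llab > 0L], nObjects(lumens))
  primary <- integer(nOrg)
  for (k in seq_len(nOrg)) {
    ls <- assignment$assignment[[k]]
    if (length(ls)) primary[k] <- ls[which.max(lumAreasPx[ls])]
  }
  plab <- matrix(0L, nrow(llab), ncol(llab))
  for (k in seq_len(nOrg)) if (primary[k] > 0L)
    plab[llab == primary[k]] <- k

  useTex <- "texture" %in% families
  texOrg <- texLum <- list()
  if (useTex) {
    for (ab in names(chans)) {
      texOrg[[ab]] <- haralickFeatures(olab, chans[[ab]], n = nOrg)
      texLum[[ab]] <- haralickFeatures(plab, chans[[ab]], n = nOrg)
    }
  }

  rows <- vector("list", nOrg)
  for (k in seq_len(nOrg)) {
    omask <- olab == k
    bb <- bbox(omask, pad = 2L)
    oSub <- omask[bb[1L]:bb[2L], bb[3L]:bb[4L]]
    lmaskSub <- plab[bb[1L]:bb[2L], bb[3L]:bb[4L]] == k
    hasLumen <- any(lmaskSub)
    chSub <- lapply(chans, function(m) m[bb[1L]:bb[2L], bb[3L]:bb[4L]])
    feat <- numeric(0)
    radialFallback <- 0

    maskSet <- list(org = oSub, lum = if (hasLumen) lmaskSub else NULL)
    for (mk in names(maskSet)) {
      msk <- maskSet[[mk]]
      if ("shape" %in% families) {
        sf <- if (!is.null(msk)) shapeFeatures(msk, px) else
          setNames(rep(NA_real_, 15L), names(shapeFeatures(oSub, px)))
        names(sf) <- paste0(mk, "_shape_", names(sf))
        feat <- c(feat, sf[!grepl("shape_undefined", names(sf))],
                  sf[grepl("shape_undefined", names(sf))])
      }
      for (ab in names(chSub)) {
        if ("intensity" %in% families) {
          iv <- if (!is.null(msk)) intensityStats(chSub[[ab]][msk]) else
            setNames(rep(NA_real_, 20L), names(intensityStats(0)))
          names(iv) <- paste0(mk, "_int_", ab, "_", names(iv))
          feat <- c(feat, iv)
        }
        if ("radial" %in% families) {
          if (!is.null(msk)) {
            rp <- radialProfile(chSub[[ab]], msk)
            if (isTRUE(attr(rp, "flagged"))) radialFallback <- 1
            rv <- c(setNames(rp$frac_at_d, sprintf("frac_r%d", rp$ring)),
                    setNames(rp$mean_frac, sprintf("mfrac_r%d", rp$ring)))
          } else {
            rv <- setNames(rep(NA_real_, 12L),
                           c(sprintf("frac_r%d", 1:6), sprintf("mfrac_r%d", 1:6)))
          }
          names(rv) <- paste0(mk, "_rad_", ab, "_", names(rv))
          feat <- c(feat, rv)
        }
        if ("zernike" %in% families) {
          zv <- if (!is.null(msk)) zernikeMoments(chSub[[ab]], msk) else
            setNames(rep(NA_real_, 30L), names(zernikeMoments(matrix(1), matrix(TRUE))))
          names(zv) <- paste0(mk, "_zern_", ab, "_", names(zv))
          feat <- c(feat, zv)
        }
        if (useTex) {
          tx <- if (mk == "org") texOrg[[ab]][k, ] else if (hasLumen)
            texLum[[ab]][k, ] else
              setNames(rep(NA_real_, ncol(texOrg[[ab]])), colnames(texOrg[[ab]]))
          names(tx) <- paste0(mk, "_tex_", ab, "_", names(tx))
          feat <- c(feat, tx)
        }
      }
    }
    if ("engineered" %in% families) {
      orgArea <- sum(oSub) * px^2
      if (hasLumen) {
        lumArea <- sum(lmaskSub) * px^2
        wo <- which(oSub, arr.ind = TRUE); wl <- which(lmaskSub, arr.ind = TRUE)
        off <- sqrt((mean(wo[, 1L]) - mean(wl[, 1L]))^2 +
                    (mean(wo[, 2L]) - mean(wl[, 2L]))^2) * px
        eng <- c(lumen_count = length(assignment$assignment[[k]]),
                 area_ratio_sqrt = as.numeric(areaRatioSqrt(lumArea, orgArea)),
                 lumen_offset_um = off)
      } else {
        eng <- c(lumen_count = 0, area_ratio_sqrt = NA_real_,
                 lumen_offset_um = NA_real_)
      }
      feat <- c(feat, eng)
    }
    rows[[k]] <- c(feat, radial_fallback = radialFallback)
  }
  mat <- do.call(rbind, rows)
  out <- data.frame(
    organoid_id = seq_len(nOrg),
    well = plateWell(field),
    field_index = field@fieldIndex,
    border = seq_len(nOrg) %in% organoids@borderLabels,
    lumen_missing = primary == 0L,
    mat,
    check.names = FALSE)
  out
}

#' Names of the numeric feature columns of a record table
#'
#' Every column produced by [assembleRecords()] that is a measured feature
#' (shape, intensity, radial, Zernike, texture, engineered), excluding
#' identifier/QC columns and boolean flags.
#'
#' @param records data.frame from [assembleRecords()].
#' @return character vector of column names.
#' @export
featureColumns <- function(records) {
  meta <- c("organoid_id", "well", "field_index", "border", "lumen_missing",
            "radial_fallback", "unmapped", "drug", "concentration_um",
            "genotype", "ko_fraction", "cell_line",
            "org_shape_shape_undefined", "lum_shape_shape_undefined")
  setdiff(names(records)[vapply(records, is.numeric, TRUE)], meta)
}

#' Feature family of each feature column
#'
#' Maps feature column names to their family (`shape`, `intensity`,
#' `radial`, `zernike`, `texture`, `engineered`), used for importance
#' roll-ups.
#'
#' @param columns character vector of feature column names.
#' @return character vector of family labels.
#' @export
featureFamily <- function(columns) {
  fam <- rep("engineered", length(columns))
  fam[grepl("_shape_", columns)] <- "shape"
  fam[grepl("_int_", columns)] <- "intensity"
  fam[grepl("_rad_", columns)] <- "radial"
  fam[grepl("_zern_", columns)] <- "zernike"
  fam[grepl("_tex_", columns)] <- "texture"
  fam
}
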