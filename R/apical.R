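# Apical cell-surface measurement from high-magnification tight-junction
# images: ridge enhancement, space-filling cell segmentation, selection of
# the ~30 central non-edge cells, and per-condition summaries.

#' Enhance tight junctions in a high-magnification marker image
#'
#' Background-subtracted, lightly smoothed ridge map in which junction
#' pixels score higher than cell interiors. The map is normalized to [0, 1],
#' so any monotone affine rescaling (gain/offset) of the input leaves the
#' downstream segmentation unchanged. A constant image yields an all-zero
#' map flagged `empty`.
#'
#' @param image 2D numeric matrix (ZO1/tight-junction channel).
#' @param sigmaPx smoothing sigma in pixels (default 1).
#' @return numeric matrix in [0, 1] with attribute `empty`.
#' @export
enhanceJunctions <- function(image, sigmaPx = 1) {
  stopIfNot(is.matrix(image), "image must be a 2D matrix")
  img <- if (sigmaPx > 0) as.matrix(EBImage::gblur(image, sigma = sigmaPx))
         else image
  img <- img - median(img)        # background level
  rng <- range(img)
  if (rng[2L] <= rng[1L]) {
    out <- matrix(0, nrow(image), ncol(image))
    attr(out, "empty") <- TRUE
    return(out)
  }
  out <- pmax(img, 0) / rng[2L]
  out[out < 1e-8] <- 0        # FFT-blur numerical speckle
  attr(out, "empty") <- FALSE
  out
}

#' Segment apical cells from a ridge map
#'
#' Cell interiors are the connected components of the sub-threshold part of
#' the ridge map (regional minima basins); the labels are then grown
#' outward over the junction pixels with a seeded watershed
#' (intensity-weighted propagation), producing space-filling labels inside
#' the ROI. Cells touching the ROI border are flagged as edge cells; cells
#' smaller than `minAreaPx` are removed before growing.
#'
#' @param ridge ridge map from [enhanceJunctions()].
#' @param pixelSizeUm micrometres per pixel (default 0.11, typical 100x).
#' @param roi optional logical matrix restricting the analysis.
#' @param seedQuantile interiors are ridge values below this quantile of the
#'   in-ROI ridge distribution (default 0.5).
#' @param minAreaPx minimum seed-region size in pixels (default 9).
#' @return list with `labels` (integer matrix) and `cells` (data.frame:
#'   `label`, `area_um2`, `centroid_row_px`, `centroid_col_px`,
#'   `edge_flag`).
#' @export
segmentApicalCells <- function(ridge, pixelSizeUm = 0.11, roi = NULL,
                               seedQuantile = 0.5, minAreaPx = 9L) {
  if (isTRUE(attr(ridge, "empty")))
    stop("empty ridge map: constant input image", call. = FALSE)
  nr <- nrow(ridge); nc <- ncol(ridge)
  if (is.null(roi)) roi <- matrix(TRUE, nr, nc)
  stopIfNot(all(dim(roi) == dim(ridge)), "roi shape mismatch")
  th <- quantile(ridge[roi], seedQuantile)
  interior <- ridge <= th & roi
  seeds <- label8(interior)
  areas <- tabulate(seeds[seeds > 0L])
  small <- which(areas < minAreaPx)
  if (length(small)) seeds[seeds %in% small] <- 0L
  seeds <- relabelConsecutive(seeds)
  if (max(seeds) == 0L)
    stop("no seeds found in ROI", call. = FALSE)
  lab <- EBImage::propagate(EBImage::Image(ridge), EBImage::Image(seeds),
                            mask = EBImage::Image(roi * 1))
  lab <- relabelConsecutive(matrix(as.integer(lab), nr, nc))
  n <- max(lab)
  w <- which(lab > 0L, arr.ind = TRUE)
  labv <- lab[lab > 0L]
  counts <- tabulate(labv, n)
  # edge = touching the ROI boundary (image border or a FALSE neighbour)
  roiEdge <- matrix(FALSE, nr, nc)
  roiEdge[1L, ] <- roiEdge[nr, ] <- TRUE
  roiEdge[, 1L] <- roiEdge[, nc] <- TRUE
  inner <- roi
  inner[2:(nr - 1L), 2:(nc - 1L)] <-
    roi[2:(nr - 1L), 2:(nc - 1L)] &
    roi[1:(nr - 2L), 2:(nc - 1L)] & roi[3:nr, 2:(nc - 1L)] &
    roi[2:(nr - 1L), 1:(nc - 2L)] & roi[2:(nr - 1L), 3:nc]
  touching <- sort(unique(lab[(roiEdge | (roi & !inner)) & lab > 0L]))
  cells <- data.frame(
    label = seq_len(n),
    area_um2 = counts * pixelSizeUm^2,
    centroid_row_px = as.numeric(tapply(w[, 1L], labv, mean)),
    centroid_col_px = as.numeric(tapply(w[, 2L], labv, mean)),
    edge_flag = seq_len(n) %in% touching)
  list(labels = lab, cells = cells)
}

#' Select the central non-edge apical cells
#'
#' The k non-edge cells nearest the lumen centre (all of them if fewer than
#' k exist), emulating the practice of measuring roughly 30 apical surfaces
#' in the centre of the lumen while avoiding the mosaic edges. Distance
#' ties break deterministically by label order.
#'
#' @param cells data.frame from [segmentApicalCells()].
#' @param lumenCenter c(row, col) of the lumen centre in pixels (defaults
#'   to the centroid of all cells).
#' @param k number of cells to select (default 30).
#' @return subset of `cells`, with a `distance_px` column added.
#' @export
selectCentralCells <- function(cells, lumenCenter = NULL, k = 30L) {
  if (is.null(lumenCenter))
    lumenCenter <- c(mean(cells$centroid_row_px), mean(cells$centroid_col_px))
  cells$distance_px <- sqrt((cells$centroid_row_px - lumenCenter[1L])^2 +
                            (cells$centroid_col_px - lumenCenter[2L])^2)
  pool <- cells[!cells$edge_flag, , drop = FALSE]
  pool <- pool[order(pool$distance_px, pool$label), , drop = FALSE]
  pool[seq_len(min(k, nrow(pool))), , drop = FALSE]
}

#' Summarize selected apical cell areas
#'
#' @param cells data.frame of selected cells (must be non-empty).
#' @param metadata optional named list/data.frame of condition metadata to
#'   attach (e.g. genotype, dose).
#' @return one-row data.frame: `n_cells`, `mean_area_um2`,
#'   `median_area_um2`, `sd_area_um2` (`NA`-flagged for a single cell) and
#'   any metadata columns.
#' @export
summarizeApical <- function(cells, metadata = NULL) {
  stopIfNot(nrow(cells) >= 1L, "no cells to summarize")
  out <- data.frame(
    n_cells = nrow(cells),
    mean_area_um2 = mean(cells$area_um2),
    median_area_um2 = median(cells$area_um2),
    sd_area_um2 = if (nrow(cells) > 1L) sd(cells$area_um2) else NA_real_)
  if (!is.null(metadata))
    out <- cbind(out, as.data.frame(metadata, stringsAsFactors = FALSE))
  out
}

#' Measure apical areas on one mosaic image end to end
#'
#' Convenience wrapper: [enhanceJunctions()] then [segmentApicalCells()]
#' then [selectCentralCells()] then [summarizeApical()].
#'
#' @param image 2D marker matrix.
#' @param pixelSizeUm micrometres per pixel.
#' @param k number of central cells (default 30).
#' @param metadata metadata passed to [summarizeApical()].
#' @return list with `cells` (all cells), `selected` and `summary`.
#' @export
measureApicalMosaic <- function(image, pixelSizeUm = 0.11, k = 30L,
                                metadata = NULL) {
  ridge <- enhanceJunctions(image)
  seg <- segmentApicalCells(ridge, pixelSizeUm)
  sel <- selectCentralCells(seg$cells, k = k)
  list(cells = seg$cells, selected = sel,
       summary = summarizeApical(sel, metadata))
}
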