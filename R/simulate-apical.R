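# Synthetic high-magnification apical tight-junction mosaic generator.
#
# Apical cell surfaces are modelled as a Voronoi tessellation of jittered
# grid seed points with density 1 / mean cell area; the marker channel
# draws intensity on the cell boundaries (tight junctions).

# exact discrete Voronoi labels via neighbourhood search on the seed grid:
# with jitter < 0.5 cell spacing the nearest seed of any pixel lies within
# a 5x5 block of grid cells around it.
#' @noRd
voronoiLabels <- function(shape, seeds, gridIndex, gridDim) {
  nr <- shape[1L]; nc <- shape[2L]
  prow <- rep(seq_len(nr), times = nc)
  pcol <- rep(seq_len(nc), each = nr)
  s <- attr(seeds, "spacing")
  gi <- pmin(pmax(floor(prow / s) + 1L, 1L), gridDim[1L])
  gj <- pmin(pmax(floor(pcol / s) + 1L, 1L), gridDim[2L])
  best <- rep(Inf, nr * nc); bestLab <- integer(nr * nc)
  for (di in -2L:2L) for (dj in -2L:2L) {
    ii <- gi + di; jj <- gj + dj
    ok <- ii >= 1L & ii <= gridDim[1L] & jj >= 1L & jj <= gridDim[2L]
    cand <- rep(NA_integer_, nr * nc)
    cand[ok] <- gridIndex[cbind(ii[ok], jj[ok])]
    has <- !is.na(cand)
    if (!any(has)) next
    d2 <- (prow[has] - seeds[cand[has], 1L])^2 +
          (pcol[has] - seeds[cand[has], 2L])^2
    upd <- d2 < best[has]
    idx <- which(has)[upd]
    best[idx] <- d2[upd]
    bestLab[idx] <- cand[has][upd]
  }
  matrix(bestLab, nr, nc)
}

#' Render a synthetic apical tight-junction mosaic
#'
#' Generates a high-magnification (100x-like) image of the apical surface:
#' jittered-grid seed points with density 1 / mean cell area are tessellated
#' into a Voronoi mosaic and the marker intensity is drawn on the cell
#' edges, emulating ZO1-labelled tight junctions. Ground truth carries every
#' cell's pixel-exact area and centroid (and its convex-hull polygon).
#'
#' @param config a [simulationConfig()]; the `apicalModel` block supplies
#'   geometry and the per-genotype mean cell areas (defaults 2.5 um^2 for
#'   WT, 7.7 um^2 for KO).
#' @param genotype `"WT"` or `"KO"`; ignored when `meanCellAreaUm2` given.
#' @param meanCellAreaUm2 optional explicit mean cell area, e.g. from
#'   [apicalAreaFromRho()] to couple a mosaic to a dose condition.
#' @param seed integer seed.
#' @return list with `image` (numeric matrix, junction marker), `labels`
#'   (integer matrix of true cell labels) and `truth`
#'   ([GroundTruth-class] with the `cells` slot filled).
#' @examples
#' mo <- renderApicalMosaic(simulationConfig(), "WT", seed = 2)
#' mean(truthCells(mo$truth)$area_um2)
#' @export
renderApicalMosaic <- function(config, genotype = c("WT", "KO"),
                               meanCellAreaUm2 = NULL, seed = config$seed) {
  a <- config$apicalModel
  if (is.null(meanCellAreaUm2)) {
    genotype <- match.arg(genotype)
    meanCellAreaUm2 <- if (genotype == "KO") a$meanCellAreaKoUm2 else
      a$meanCellAreaWtUm2
  } else genotype <- "custom"
  stopIfNot(meanCellAreaUm2 > 0, "mean cell area must be positive")
  set.seed(seed)
  shape <- a$mosaicShapePx
  px <- a$pixelSizeUm
  s <- sqrt(meanCellAreaUm2) / px          # grid spacing in pixels
  gr <- floor(shape[1L] / s); gc <- floor(shape[2L] / s)
  if (gr * gc < 3L) stop("degenerate tessellation: fewer than 3 seeds",
                         call. = FALSE)
  jit <- 0.35 * s
  ctrR <- (outer(seq_len(gr) - 0.5, rep(1, gc)) * s)
  ctrC <- (outer(rep(1, gr), seq_len(gc) - 0.5) * s)
  seedR <- ctrR + runif(gr * gc, -jit, jit)
  seedC <- ctrC + runif(gr * gc, -jit, jit)
  seeds <- cbind(as.numeric(seedR), as.numeric(seedC))
  attr(seeds, "spacing") <- s
  gridIndex <- matrix(seq_len(gr * gc), gr, gc)
  lab <- voronoiLabels(shape, seeds, gridIndex, c(gr, gc))

  # junction mask: pixels whose 4-neighbour has a different label
  nr <- shape[1L]; nc <- shape[2L]
  edge <- matrix(FALSE, nr, nc)
  edge[-nr, ] <- edge[-nr, ] | (lab[-nr, ] != lab[-1L, ])
  edge[, -nc] <- edge[, -nc] | (lab[, -nc] != lab[, -1L])
  img <- matrix(0.05, nr, nc)
  img[edge] <- 1
  if (a$junctionSigmaPx > 0)
    img <- as.matrix(EBImage::gblur(img, sigma = a$junctionSigmaPx))
  if (a$gaussianSd > 0)
    img <- img + rnorm(length(img), 0, a$gaussianSd)
  img <- pmax(img, 0)

  pxArea <- px^2
  counts <- tabulate(lab, nbins = gr * gc)
  w <- which(lab > 0, arr.ind = TRUE)
  sumR <- tapply(w[, 1L], lab[lab > 0], sum)
  sumC <- tapply(w[, 2L], lab[lab > 0], sum)
  keep <- which(counts > 0L)
  cells <- data.frame(
    label = keep,
    area_um2 = counts[keep] * pxArea,
    centroid_row_px = as.numeric(sumR[as.character(keep)]) / counts[keep],
    centroid_col_px = as.numeric(sumC[as.character(keep)]) / counts[keep],
    genotype = genotype,
    mean_area_truth_um2 = meanCellAreaUm2)
  # convex polygons of the Voronoi cells (cells are convex, so the hull of
  # member pixels is the cell polygon up to discretization)
  polysByCell <- lapply(keep, function(lb) {
    pts <- which(lab == lb, arr.ind = TRUE)
    pts[chull(pts), , drop = FALSE] * px
  })
  truth <- new("GroundTruth", organoids = data.frame(), cells = cells,
               polygons = polysByCell)
  list(image = img, labels = lab, truth = truth)
}
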