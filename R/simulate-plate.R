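#' Simulate a plate of synthetic fields
#'
#' Renders one or more fields per well for a list of (well, condition)
#' pairs, emitting the matching plate map and pooled ground truth. Each
#' field gets its own reproducible substream seed derived from the master
#' seed, so the whole plate is bit-reproducible.
#'
#' @param config a [simulationConfig()].
#' @param design named list: names are well ids, values [wellCondition()]s.
#' @param seed master integer seed (defaults to `config$seed`).
#' @return list with `fields` (list of [FieldImage-class]), `plateMap`
#'   (data.frame), and `truth` ([GroundTruth-class] pooling all fields).
#' @examples
#' cfg <- simulationConfig(fieldShapePx = c(256, 256),
#'                         nOrganoidsPerField = c(3L, 4L))
#' design <- list(A01 = wellCondition("VPA", 0),
#'                A02 = wellCondition("VPA", 400))
#' plate <- simulatePlate(cfg, design, seed = 3)
#' plate$plateMap
#' @export
simulatePlate <- function(config, design, seed = config$seed) {
  wells <- names(design)
  stopIfNot(length(wells) == length(unique(wells)), "design wells must be unique")
  fields <- list(); truthDfs <- list(); polys <- list()
  pmRows <- list()
  k <- 0L
  for (w in seq_along(design)) {
    cond <- design[[w]]
    pmRows[[w]] <- data.frame(
      well = wells[w], drug = cond$drug,
      concentration_um = cond$concentrationUm, genotype = cond$genotype,
      ko_fraction = cond$koFraction, cell_line = cond$cellLine,
      stringsAsFactors = FALSE)
    for (f in seq_len(config$fieldsPerWell)) {
      k <- k + 1L
      out <- renderField(config, cond, seed = subSeed(seed, k),
                         plateWell = wells[w], fieldIndex = f)
      fields[[k]] <- out$field
      tdf <- truthOrganoids(out$truth)
      if (nrow(tdf)) {
        tdf$field_id <- k
        truthDfs[[length(truthDfs) + 1L]] <- tdf
        polys[[k]] <- truthPolygons(out$truth)
      } else polys[[k]] <- list()
    }
  }
  truthDf <- if (length(truthDfs)) do.call(rbind, truthDfs) else data.frame()
  plateMap <- if (length(pmRows)) do.call(rbind, pmRows) else
    data.frame(well = character(0), drug = character(0),
               concentration_um = numeric(0), genotype = character(0),
               ko_fraction = numeric(0), cell_line = character(0))
  if (nrow(truthDf))
    msg(sprintf("simulated %d field(s), %d organoid(s) across %d condition(s)",
                length(fields), nrow(truthDf), length(design)))
  list(fields = fields, plateMap = plateMap,
       truth = new("GroundTruth", organoids = truthDf, cells = data.frame(),
                   polygons = polys))
}

#' Standard screening designs
#'
#' Convenience builders for the two study designs the generator emulates: an
#' 8-point valproic-acid dose series (50-1000 uM plus vehicle wells as dose
#' 0 when requested) and the 6-level mosaic knockout mixing series
#' (0, 12.5, 25, 50, 75, 100 percent knockout cells).
#'
#' @param doses numeric vector of concentrations in micromolar.
#' @param fractions numeric vector of knockout fractions in [0, 1].
#' @return named list of [wellCondition()]s keyed by well id.
#' @export
doseDesign <- function(doses = c(50, 100, 200, 300, 400, 600, 800, 1000)) {
  wells <- sprintf("A%02d", seq_along(doses))
  setNames(lapply(doses, function(d) wellCondition("VPA", d)), wells)
}

#' @rdname doseDesign
#' @export
mosaicDesign <- function(fractions = c(0, 0.125, 0.25, 0.5, 0.75, 1)) {
  wells <- sprintf("B%02d", seq_along(fractions))
  setNames(lapply(fractions, function(f)
    wellCondition("vehicle", 0, genotype = if (f > 0) "mosaic" else "WT",
                  koFraction = f)), wells)
}
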