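#' Simulation configuration
#'
#' Builds the configuration object that fixes the study conditions of the
#' synthetic generator: field geometry, the organoid population, the
#' dose/gene-dose lumen models, knockout dysmorphology, image formation
#' (PSF, Poisson and Gaussian noise) and the apical tight-junction mosaic.
#' Values override the defaults by name; unknown names are an error.
#'
#' The lumen model couples condition to the lumen radius fraction
#' \eqn{\rho} (lumen radius / organoid radius):
#' \itemize{
#'   \item dose (Hill): \eqn{\rho(c) = \rho_0 + (\rho_{max}-\rho_0)\,
#'     c^h / (c^h + EC_{50}^h)} — see [lumenFractionFromDose()];
#'   \item knockout fraction (piecewise linear, saturating at
#'     \code{fSat}): see [lumenFractionFromKO()].
#' }
#'
#' @param ... named overrides of the defaults listed below.
#' @return a list of class `simulationConfig`.
#'
#' @details Defaults: 768x768 px fields at 1.3 um/px; 20-40 organoids per
#' field with radius ~ N(75, 15) um truncated to [45, 105]; lumen model
#' rho0 = 0.15, rhoMax = 0.60, ec50Um = 300, hillH = 1.5, fSat = 0.75, with
#' per-organoid biological scatter rhoSd = 0.035, lumen-centre eccentricity
#' up to lumenOffsetMax = 0.15 of the organoid radius, and per-organoid
#' marker staining variability stainSd = 0.15 (log scale); knockout
#' dysmorphology
#' via 5-lobe radial perturbation of amplitude lobeAmpMax * min(f/fSat, 1)
#' and a basal marker rim of gain basalGainMax * min(f/fSat, 1) over the
#' outer 10 percent of the radius; fusionProb = 0.05; ring half-width
#' ringSigmaUm = 2.5; PSF sigma 1.2 px, Poisson scale 200, Gaussian sd 0.01
#' (SNR ~ 10 at the ring); apical mosaic 512x512 px at 0.11 um/px with mean
#' cell areas 2.5 (WT) and 7.7 (KO) um^2.
#' @examples
#' cfg <- simulationConfig(fieldShapePx = c(256, 256), nOrganoidsPerField = c(3, 5))
#' lumenFractionFromDose(300, cfg$lumenModel)
#' @export
simulationConfig <- function(...) {
  cfg <- list(
    fieldShapePx = c(768L, 768L),
    pixelSizeUm = 1.3,
    nOrganoidsPerField = c(20L, 40L),
    organoidRadiusUm = list(mean = 75, sd = 15, min = 45, max = 105),
    lumenModel = list(rho0 = 0.15, rhoMax = 0.60, ec50Um = 300,
                      hillH = 1.5, fSat = 0.75),
    rhoSd = 0.035,
    lumenOffsetMax = 0.15,
    stainSd = 0.15,
    dysmorphology = list(nLobes = 5L, lobeAmpMax = 0.22),
    basalGainMax = 0.25,
    fusionProb = 0.05,
    bodyIntensity = 0.8,
    cytoplasmIntensity = 0.12,
    lumenInteriorIntensity = 0.05,
    ringIntensity = 1.0,
    ringSigmaUm = 2.5,
    bodyWobbleAmp = 0.015,
    noise = list(gaussianSd = 0.01, poissonScale = 200, psfSigmaPx = 1.2),
    apicalModel = list(meanCellAreaWtUm2 = 2.5, meanCellAreaKoUm2 = 7.7,
                       mosaicShapePx = c(512L, 512L), pixelSizeUm = 0.11,
                       junctionSigmaPx = 0.8, gaussianSd = 0.01),
    fieldsPerWell = 1L,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown simulationConfig field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  # apply overrides in call order (a repeated name: the later value wins)
  for (i in seq_along(dots)) {
    nm <- names(dots)[i]
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(dots[[i]]))
      modifyList(cfg[[nm]], dots[[i]]) else dots[[i]]
  }
  validateSimulationConfig(cfg)
  class(cfg) <- "simulationConfig"
  cfg
}

#' @noRd
validateSimulationConfig <- function(cfg) {
  m <- cfg$lumenModel
  stopIfNot(m$rho0 > 0 && m$rho0 < m$rhoMax && m$rhoMax < 1,
            "lumen model requires 0 < rho0 < rhoMax < 1")
  stopIfNot(m$ec50Um > 0, "ec50Um must be positive")
  stopIfNot(m$hillH > 0, "hillH must be positive")
  stopIfNot(m$fSat > 0 && m$fSat <= 1, "fSat must lie in (0, 1]")
  stopIfNot(cfg$fusionProb >= 0 && cfg$fusionProb <= 1,
            "fusionProb must lie in [0, 1]")
  stopIfNot(cfg$pixelSizeUm > 0, "pixelSizeUm must be positive")
  invisible(cfg)
}

#' Lumen radius fraction from drug dose (Hill model)
#'
#' Monotone dose-response of the lumen radius fraction \eqn{\rho}:
#' \eqn{\rho(c) = \rho_0 + (\rho_{max} - \rho_0)\, c^h / (c^h + EC_{50}^h)},
#' strictly increasing in the concentration and bounded by
#' \eqn{(\rho_0, \rho_{max})}.
#'
#' @param concentrationUm concentration(s) in micromolar, >= 0 (vectorized).
#' @param model the `lumenModel` block of a [simulationConfig()].
#' @return numeric vector of lumen radius fractions in (0, 1).
#' @examples
#' m <- simulationConfig()$lumenModel
#' lumenFractionFromDose(0, m)                     # rho0
#' lumenFractionFromDose(m$ec50Um, m)              # Hill midpoint
#' @export
lumenFractionFromDose <- function(concentrationUm, model) {
  stopIfNot(all(concentrationUm >= 0), "concentration must be >= 0")
  ch <- concentrationUm^model$hillH
  model$rho0 + (model$rhoMax - model$rho0) * ch / (ch + model$ec50Um^model$hillH)
}

#' Lumen radius fraction from mosaic knockout fraction
#'
#' Piecewise-linear gene-dose response with saturation:
#' \eqn{\rho(f) = \rho_0 + (\rho_{max} - \rho_0)\min(f / f_{sat}, 1)}.
#' It is strictly increasing on \eqn{[0, f_{sat}]} and exactly
#' \eqn{\rho_{max}} for \eqn{f \ge f_{sat}} (default \code{fSat = 0.75}), so
#' the 75 and 100 percent knockout conditions are generated identically.
#'
#' @param koFraction knockout cell fraction(s) in [0, 1] (vectorized).
#' @param model the `lumenModel` block of a [simulationConfig()].
#' @return numeric vector of lumen radius fractions.
#' @examples
#' m <- simulationConfig()$lumenModel
#' lumenFractionFromKO(c(0, 0.375, 0.75, 1), m)
#' @export
lumenFractionFromKO <- function(koFraction, model) {
  if (any(koFraction < 0 | koFraction > 1))
    stop("koFraction must lie in [0, 1]", call. = FALSE)
  model$rho0 + (model$rhoMax - model$rho0) * pmin(koFraction / model$fSat, 1)
}

# saturating effect scale shared by all knockout-dependent knobs
#' @noRd
koEffect <- function(koFraction, model) pmin(koFraction / model$fSat, 1)

#' Condition-mean apical cell area from the latent lumen fraction
#'
#' Couples the apical mosaic to the lumen model: the condition-mean apical
#' cell area is linear in the true lumen area fraction \eqn{\rho^2}, pinned
#' to the wild-type mean at \eqn{\rho_0} and the knockout mean at
#' \eqn{\rho_{max}}. This mirrors the empirically linear relation between
#' lumen area and mean apical surface area.
#'
#' @param rho lumen radius fraction(s).
#' @param config a [simulationConfig()].
#' @return mean apical cell area(s) in square micrometres.
#' @export
apicalAreaFromRho <- function(rho, config) {
  m <- config$lumenModel; a <- config$apicalModel
  a$meanCellAreaWtUm2 + (a$meanCellAreaKoUm2 - a$meanCellAreaWtUm2) *
    (rho^2 - m$rho0^2) / (m$rhoMax^2 - m$rho0^2)
}

#' Describe a well condition
#'
#' Helper assembling the per-well condition the simulator consumes: either a
#' drug dose (micromolar) or a mosaic knockout fraction.
#'
#' @param drug drug name (`"vehicle"`, `"VPA"`, ...).
#' @param concentrationUm dose in micromolar (0 for vehicle).
#' @param genotype `"WT"` or `"KO"`.
#' @param koFraction mosaic knockout fraction in [0, 1], or `NA` for pure
#'   drug conditions.
#' @param cellLine cell line label.
#' @return a list of class `wellCondition`.
#' @export
wellCondition <- function(drug = "vehicle", concentrationUm = 0,
                          genotype = "WT", koFraction = NA_real_,
                          cellLine = "AICS-0023") {
  structure(list(drug = drug, concentrationUm = concentrationUm,
                 genotype = genotype, koFraction = koFraction,
                 cellLine = cellLine),
            class = "wellCondition")
}

# resolve the latent lumen fraction and knockout effect of a condition
#' @noRd
conditionRho <- function(condition, config) {
  m <- config$lumenModel
  if (!is.na(condition$koFraction)) {
    f <- condition$koFraction
  } else if (identical(condition$genotype, "KO")) {
    f <- 1
  } else {
    f <- 0
  }
  if (f > 0) {
    list(rho = lumenFractionFromKO(f, m), effect = koEffect(f, m), ko = f)
  } else {
    list(rho = lumenFractionFromDose(condition$concentrationUm, m),
         effect = 0, ko = 0)
  }
}
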