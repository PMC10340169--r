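#' FieldImage: one multi-channel imaging field
#'
#' Container for a single imaging field: a numeric pixel array indexed
#' \code{[row, col, z, channel]}, the biological role of each channel, the
#' isotropic pixel pitch in micrometres, and plate-well provenance. A 2D
#' field simply has z-depth 1.
#'
#' @slot pixels numeric 4D array \code{[row, col, z, channel]}; finite,
#'   non-negative intensities on a common scale.
#' @slot channelRoles character vector, one of \code{"counterstain"},
#'   \code{"lumen_marker"}, \code{"aux"} per channel.
#' @slot pixelSizeUm micrometres per pixel (isotropic, positive).
#' @slot plateWell well identifier (e.g. \code{"B02"}).
#' @slot fieldIndex integer index of the field within its well.
#'
#' @seealso [fieldImage()], [maxProject()], [getChannel()]
#' @export
setClass("FieldImage",
  representation(
    pixels = "array",
    channelRoles = "character",
    pixelSizeUm = "numeric",
    plateWell = "character",
    fieldIndex = "integer"
  )
)

setValidity("FieldImage", function(object) {
  msgs <- character()
  d <- dim(object@pixels)
  if (length(d) != 4L)
    msgs <- c(msgs, "pixels must be a 4D [row, col, z, channel] array")
  else {
    if (d[4L] != length(object@channelRoles))
      msgs <- c(msgs, sprintf("channel count (%d) does not match channelRoles (%d)",
                              d[4L], length(object@channelRoles)))
  }
  if (!all(object@channelRoles %in% c("counterstain", "lumen_marker", "aux")))
    msgs <- c(msgs, "channelRoles must be counterstain/lumen_marker/aux")
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    msgs <- c(msgs, "pixelSizeUm must be a single positive number")
  px <- object@pixels
  if (anyNA(px) || any(!is.finite(px)) || any(px < 0))
    msgs <- c(msgs, "pixel intensities must be finite and non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Construct a FieldImage
#'
#' @param pixels numeric array: \code{[row, col]} (single channel, 2D),
#'   \code{[row, col, channel]} (multi-channel 2D) or
#'   \code{[row, col, z, channel]}.
#' @param channelRoles character vector of channel roles
#'   (\code{"counterstain"}, \code{"lumen_marker"}, \code{"aux"}).
#' @param pixelSizeUm micrometres per pixel.
#' @param plateWell well identifier.
#' @param fieldIndex integer field index within the well.
#' @return a [FieldImage-class] object.
#' @examples
#' f <- fieldImage(array(0, c(16, 16, 1, 1)), "counterstain", 1.3)
#' zDepth(f)
#' @export
fieldImage <- function(pixels, channelRoles, pixelSizeUm = 1.3,
                       plateWell = "A01", fieldIndex = 1L) {
  d <- dim(pixels)
  if (is.null(d)) stop("pixels must be an array", call. = FALSE)
  if (length(d) == 2L) dim(pixels) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(pixels) <- c(d[1L], d[2L], 1L, d[3L])
  new("FieldImage", pixels = pixels, channelRoles = channelRoles,
      pixelSizeUm = pixelSizeUm, plateWell = as.character(plateWell),
      fieldIndex = as.integer(fieldIndex))
}

#' LabeledMask: labeled object mask for one field
#'
#' Integer label matrix (0 = background, k = object k) with calibration and
#' provenance. Objects are 8-connected components with consecutive labels;
#' labels touching the field border are recorded in \code{borderLabels}.
#'
#' @slot labels integer matrix of object labels.
#' @slot pixelSizeUm micrometres per pixel.
#' @slot channel character, the channel role the mask was derived from.
#' @slot borderLabels integer vector of labels touching the field border.
#' @seealso [segmentOrganoids()], [segmentLumens()], [nObjects()]
#' @export
setClass("LabeledMask",
  representation(
    labels = "matrix",
    pixelSizeUm = "numeric",
    channel = "character",
    borderLabels = "integer"
  )
)

setValidity("LabeledMask", function(object) {
  msgs <- character()
  lab <- object@labels
  if (!is.integer(lab)) msgs <- c(msgs, "labels must be an integer matrix")
  else {
    if (any(lab < 0L)) msgs <- c(msgs, "labels must be non-negative")
    u <- sort(unique(lab[lab > 0L]))
    if (length(u) && !identical(u, seq_len(max(u))))
      msgs <- c(msgs, "labels must be consecutive positive integers")
  }
  if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
    msgs <- c(msgs, "pixelSizeUm must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' @noRd
labeledMask <- function(labels, pixelSizeUm, channel = "counterstain") {
  labels <- relabelConsecutive(matrix(as.integer(labels), nrow(labels), ncol(labels)))
  border <- sort(unique(c(labels[1L, ], labels[nrow(labels), ],
                          labels[, 1L], labels[, ncol(labels)])))
  new("LabeledMask", labels = labels, pixelSizeUm = pixelSizeUm,
      channel = channel, borderLabels = as.integer(border[border > 0L]))
}

#' GroundTruth: simulator-side truth for a rendered field or mosaic
#'
#' Per-object geometry emitted by the synthetic generator: one row per
#' rendered body in \code{organoids} (centre, equivalent radius, polygon
#' areas in square micrometres, lumen count, condition labels), the boundary
#' and lumen polygons in \code{polygons}, and, for apical mosaics, one row
#' per cell in \code{cells}.
#'
#' @slot organoids data.frame of per-organoid truth.
#' @slot cells data.frame of per-apical-cell truth (mosaics only).
#' @slot polygons list of per-object boundary/lumen polygon coordinates (um).
#' @seealso [renderField()], [renderApicalMosaic()], [simulatePlate()]
#' @export
setClass("GroundTruth",
  representation(
    organoids = "data.frame",
    cells = "data.frame",
    polygons = "list"
  )
)

#' ModelReport: cross-validated random-forest fit summary
#'
#' @slot mode \code{"regression"} or \code{"classification"}.
#' @slot scoreTrain training-set score (R-squared or accuracy).
#' @slot scoreCV out-of-fold cross-validated score.
#' @slot importance named numeric vector of variable importances, normalized
#'   to sum to 100.
#' @slot nTrees number of trees per forest.
#' @slot seed integer seed the fit was run under.
#' @slot folds integer vector of fold assignments, one per row.
#' @slot predictions data.frame with observed, out-of-fold predicted values
#'   and fold ids.
#' @seealso [fitRandomForest()], [rankImportance()]
#' @export
setClass("ModelReport",
  representation(
    mode = "character",
    scoreTrain = "numeric",
    scoreCV = "numeric",
    importance = "numeric",
    nTrees = "integer",
    seed = "integer",
    folds = "integer",
    predictions = "data.frame"
  )
)

setValidity("ModelReport", function(object) {
  msgs <- character()
  if (!object@mode %in% c("regression", "classification"))
    msgs <- c(msgs, "mode must be regression or classification")
  imp <- object@importance
  if (length(imp)) {
    if (any(imp < 0)) msgs <- c(msgs, "importances must be non-negative")
    if (abs(sum(imp) - 100) > 1e-6)
      msgs <- c(msgs, "importances must sum to 100")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "FieldImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("FieldImage %dx%d px, z=%d, %d channel(s) [%s]\n",
              d[1L], d[2L], d[3L], d[4L],
              paste(object@channelRoles, collapse = ", ")))
  cat(sprintf("  pixel size %.3f um/px, well %s field %d\n",
              object@pixelSizeUm, object@plateWell, object@fieldIndex))
})

setMethod("show", "LabeledMask", function(object) {
  cat(sprintf("LabeledMask %dx%d px, %d object(s) from %s channel (%.3f um/px)\n",
              nrow(object@labels), ncol(object@labels),
              max(object@labels, 0L), object@channel, object@pixelSizeUm))
  if (length(object@borderLabels))
    cat(sprintf("  border-touching labels: %s\n",
                paste(object@borderLabels, collapse = ", ")))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d organoid(s), %d apical cell(s)\n",
              nrow(object@organoids), nrow(object@cells)))
})

setMethod("show", "ModelReport", function(object) {
  lab <- if (object@mode == "regression") "R2" else "accuracy"
  cat(sprintf("ModelReport (%s, %d trees, seed %d)\n", object@mode,
              object@nTrees, object@seed))
  cat(sprintf("  train %s = %.3f, %d-fold CV %s = %.3f\n", lab,
              object@scoreTrain, length(unique(object@folds)), lab,
              object@scoreCV))
  top <- head(sort(object@importance, decreasing = TRUE), 5L)
  cat("  top importances (%):\n")
  for (i in seq_along(top))
    cat(sprintf("    %-40s %6.2f\n", names(top)[i], top[i]))
})
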