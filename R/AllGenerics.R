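#' Number of channels, z-depth and calibration accessors
#'
#' Accessors for [FieldImage-class] and [LabeledMask-class] objects.
#'
#' @param x a FieldImage or LabeledMask.
#' @return `nChannels` and `zDepth` return integers; `channelRoles` a
#'   character vector; `pixelSize` the pixel pitch in micrometres;
#'   `plateWell` the well id; `nObjects` the object count of a mask;
#'   `maskLabels` the integer label matrix.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("zDepth", function(x) standardGeneric("zDepth"))
#' @rdname accessors
#' @export
setGeneric("channelRoles", function(x) standardGeneric("channelRoles"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("plateWell", function(x) standardGeneric("plateWell"))
#' @rdname accessors
#' @export
setGeneric("nObjects", function(x) standardGeneric("nObjects"))
#' @rdname accessors
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))

#' @rdname accessors
setMethod("nChannels", "FieldImage", function(x) dim(x@pixels)[4L])
#' @rdname accessors
setMethod("zDepth", "FieldImage", function(x) dim(x@pixels)[3L])
#' @rdname accessors
setMethod("channelRoles", "FieldImage", function(x) x@channelRoles)
#' @rdname accessors
setMethod("pixelSize", "FieldImage", function(x) x@pixelSizeUm)
#' @rdname accessors
setMethod("pixelSize", "LabeledMask", function(x) x@pixelSizeUm)
#' @rdname accessors
setMethod("plateWell", "FieldImage", function(x) x@plateWell)
#' @rdname accessors
setMethod("nObjects", "LabeledMask", function(x) max(x@labels, 0L))
#' @rdname accessors
setMethod("maskLabels", "LabeledMask", function(x) x@labels)

#' Ground-truth table accessors
#'
#' @param x a [GroundTruth-class] object.
#' @return `truthOrganoids` and `truthCells` return data.frames;
#'   `truthPolygons` the list of polygon coordinates.
#' @name truth-accessors
NULL

#' @rdname truth-accessors
#' @export
setGeneric("truthOrganoids", function(x) standardGeneric("truthOrganoids"))
#' @rdname truth-accessors
#' @export
setGeneric("truthCells", function(x) standardGeneric("truthCells"))
#' @rdname truth-accessors
#' @export
setGeneric("truthPolygons", function(x) standardGeneric("truthPolygons"))
#' @rdname truth-accessors
setMethod("truthOrganoids", "GroundTruth", function(x) x@organoids)
#' @rdname truth-accessors
setMethod("truthCells", "GroundTruth", function(x) x@cells)
#' @rdname truth-accessors
setMethod("truthPolygons", "GroundTruth", function(x) x@polygons)

#' Maximum intensity projection
#'
#' Collapse the z dimension of a field by taking, per channel, the maximum
#' intensity over z at every (row, col). Idempotent on 2D input and
#' metadata-preserving.
#'
#' @param x a [FieldImage-class].
#' @return a FieldImage with z-depth 1.
#' @examples
#' f <- fieldImage(array(runif(16 * 16 * 4), c(16, 16, 4, 1)), "counterstain")
#' zDepth(maxProject(f))
#' @export
setGeneric("maxProject", function(x) standardGeneric("maxProject"))

#' Extract one channel plane
#'
#' @param x a [FieldImage-class].
#' @param channel channel role name (e.g. \code{"lumen_marker"}) or index.
#' @param z z-plane index (default 1; use [maxProject()] first for stacks).
#' @return numeric matrix \code{[row, col]}.
#' @export
setGeneric("getChannel", function(x, channel, z = 1L) standardGeneric("getChannel"))

setMethod("maxProject", "FieldImage", function(x) {
  d <- dim(x@pixels)
  if (d[3L] == 1L) return(x)
  out <- array(0, c(d[1L], d[2L], 1L, d[4L]))
  for (ch in seq_len(d[4L]))
    out[, , 1L, ch] <- apply(x@pixels[, , , ch, drop = FALSE], c(1L, 2L), max)
  initialize(x, pixels = out)
})

setMethod("getChannel", "FieldImage", function(x, channel, z = 1L) {
  if (is.character(channel)) {
    idx <- which(x@channelRoles == channel)
    if (!length(idx))
      stop("no channel with role '", channel, "'", call. = FALSE)
    channel <- idx[1L]
  }
  x@pixels[, , z, channel]
})
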