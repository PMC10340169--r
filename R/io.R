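#' Read a single- or multi-page TIFF field
#'
#' Reads a TIFF file into a [FieldImage-class]. Pages are interpreted in
#' channel blocks: all z-planes of channel 1, then all z-planes of channel 2,
#' and so on; the page count must therefore be a multiple of
#' \code{length(channelRoles)}. Integer TIFFs are rescaled by the `tiff`
#' package to a common [0, 1] intensity scale regardless of bit depth; float
#' TIFFs are read as stored.
#'
#' @param path path to a readable TIFF file.
#' @param channelRoles character vector of channel roles in page-block order.
#' @param pixelSizeUm micrometres per pixel (default 1.3, typical of a 10x
#'   high-content objective; see [defaultRunConfig()]).
#' @param plateWell,fieldIndex provenance metadata attached to the field.
#' @return a [FieldImage-class].
#' @seealso [writeField()], [maxProject()]
#' @export
readField <- function(path, channelRoles, pixelSizeUm = 1.3,
                      plateWell = "A01", fieldIndex = 1L) {
  if (!file.exists(path))
    stop("TIFF file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # collapse grey-stored-as-RGB
    if (!is.numeric(p)) stop("non-numeric pixel data in ", path, call. = FALSE)
    p
  })
  nch <- length(channelRoles)
  if (length(pages) %% nch != 0L)
    stop(sprintf("channel-count mismatch in %s: %d page(s) cannot be split into %d channel(s)",
                 path, length(pages), nch), call. = FALSE)
  nz <- length(pages) %/% nch
  d <- dim(pages[[1L]])
  px <- array(0, c(d[1L], d[2L], nz, nch))
  for (ch in seq_len(nch)) for (z in seq_len(nz))
    px[, , z, ch] <- pages[[(ch - 1L) * nz + z]]
  fieldImage(px, channelRoles, pixelSizeUm, plateWell, fieldIndex)
}

#' Write a FieldImage as a multi-page float TIFF
#'
#' Pages are written in channel blocks (all z of channel 1 first), matching
#' the convention [readField()] expects. TIFF float storage is defined on
#' [0, 1], so a field whose maximum exceeds 1 is divided by that maximum
#' before writing (fluorescence intensities are relative); fields already
#' in [0, 1] round-trip losslessly.
#'
#' @param field a [FieldImage-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeField <- function(field, path) {
  d <- dim(field@pixels)
  mx <- max(field@pixels)
  scale <- if (mx > 1) mx else 1
  pages <- list()
  for (ch in seq_len(d[4L])) for (z in seq_len(d[3L]))
    pages[[length(pages) + 1L]] <- field@pixels[, , z, ch] / scale
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 32L), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("cannot write TIFF to ", path, call. = FALSE)
  invisible(path)
}

PLATE_MAP_COLUMNS <- c("well", "drug", "concentration_um", "genotype",
                       "ko_fraction", "cell_line")

#' Read a plate map
#'
#' A plate map is a delimited text table with one row per well and required
#' columns `well`, `drug`, `concentration_um`, `genotype`, `ko_fraction`,
#' `cell_line`; extra columns pass through untouched. The delimiter is
#' chosen from the file extension (`.tsv`/`.txt` = tab, otherwise comma).
#'
#' @param path path to the plate-map file.
#' @return data.frame with one row per well.
#' @seealso [joinMetadata()]
#' @export
readPlateMap <- function(path) {
  if (!file.exists(path)) stop("plate map not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  pm <- read.csv(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  validatePlateMap(pm)
  pm
}

#' @noRd
validatePlateMap <- function(pm) {
  missing <- setdiff(PLATE_MAP_COLUMNS, names(pm))
  if (length(missing))
    stop("plate map lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(pm$well))
    stop("duplicate wells in plate map: ",
         paste(unique(pm$well[duplicated(pm$well)]), collapse = ", "),
         call. = FALSE)
  conc <- pm$concentration_um
  if (any(!is.na(conc) & conc < 0))
    stop("plate map concentrations must be non-negative", call. = FALSE)
  ko <- pm$ko_fraction
  if (any(!is.na(ko) & (ko < 0 | ko > 1)))
    stop("plate map ko_fraction must lie in [0, 1]", call. = FALSE)
  invisible(pm)
}

#' Join experimental metadata onto per-organoid records
#'
#' Annotates each record with the drug, concentration, genotype, knockout
#' fraction and cell line of its well. Records whose well is absent from the
#' plate map are flagged `unmapped = TRUE` and retained, never dropped
#' silently; the record count is always preserved.
#'
#' @param records data.frame of per-organoid rows carrying a `well` column.
#' @param plateMap data.frame as returned by [readPlateMap()].
#' @return `records` with the plate-map columns and an `unmapped` flag added.
#' @export
joinMetadata <- function(records, plateMap) {
  validatePlateMap(plateMap)
  stopIfNot(is.data.frame(records), "records must be a data.frame")
  if (nrow(records) && !"well" %in% names(records))
    stop("records must carry a 'well' column", call. = FALSE)
  addCols <- setdiff(names(plateMap), "well")
  if (!nrow(records)) {
    for (cl in c(addCols, "unmapped")) records[[cl]] <- logical(0)
    return(records)
  }
  idx <- match(records$well, plateMap$well)
  for (cl in addCols) records[[cl]] <- plateMap[[cl]][idx]
  records$unmapped <- is.na(idx)
  records
}

#' Write / read a per-organoid feature table
#'
#' Plain CSV with a header row, one row per organoid and a stable column
#' order; values round-trip through [readFeatureTable()] within float
#' formatting precision (15 significant digits).
#'
#' @param records data.frame, or list of data.frames sharing one schema.
#' @param path output path.
#' @return `path` invisibly (writer); a data.frame (reader).
#' @export
writeFeatureTable <- function(records, path) {
  if (is.list(records) && !is.data.frame(records)) {
    schemas <- lapply(records, names)
    if (length(unique(vapply(schemas, paste, "", collapse = "\r"))) > 1L)
      stop("records have mismatched column schemas", call. = FALSE)
    records <- do.call(rbind, records)
  }
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2L) != 0L)
    stop("unwritable path: ", path, call. = FALSE)
  old <- options(digits = 15L); on.exit(options(old))
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path, call. = FALSE)
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
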