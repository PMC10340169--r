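#' Quality-control filter on per-organoid records
#'
#' Retains exactly the organoids the downstream statistics use: a single
#' lumen and a projected body area inside the inclusive window
#' [`minAreaUm2`, `maxAreaUm2`]. The default window 7854-31,415 um^2 is the
#' circle-area conversion of a 100-200 um diameter gate
#' (\eqn{\pi 50^2 \approx 7854}, \eqn{\pi 100^2 \approx 31415}); outside it,
#' objects are predominantly fragments or fusions of two monolayer pieces.
#' Border-touching organoids (censored areas) and records whose well is not
#' in the plate map can also be excluded.
#'
#' The report counts each exclusion reason once per excluded organoid, in
#' the precedence order `border`, `unmapped`, `no_lumen`, `multi_lumen`,
#' `too_small`, `too_large`.
#'
#' @param records data.frame from [assembleRecords()] (optionally after
#'   [joinMetadata()]) carrying `lumen_count` and `org_shape_area_um2`.
#' @param minAreaUm2,maxAreaUm2 inclusive area bounds (defaults 7854 and
#'   31415).
#' @param requireSingleLumen require exactly one lumen (default TRUE).
#' @param excludeBorder drop border-touching organoids (default TRUE).
#' @param excludeUnmapped drop records flagged `unmapped` (default TRUE).
#' @return list with `retained` (data.frame), `excluded` (data.frame with a
#'   `qc_reason` column) and `report` (data.frame of reason counts).
#' @examples
#' rec <- data.frame(org_shape_area_um2 = c(8000, 40000), lumen_count = c(1, 1))
#' qcFilter(rec)$report
#' @export
qcFilter <- function(records, minAreaUm2 = 7854, maxAreaUm2 = 31415,
                     requireSingleLumen = TRUE, excludeBorder = TRUE,
                     excludeUnmapped = TRUE) {
  n <- nrow(records)
  area <- records$org_shape_area_um2
  lc <- records$lumen_count
  stopIfNot(!is.null(area) && !is.null(lc),
            "records must carry org_shape_area_um2 and lumen_count")
  reason <- rep(NA_character_, n)
  mark <- function(cond, why) {
    sel <- is.na(reason) & cond %in% TRUE
    reason[sel] <<- why
  }
  if (excludeBorder && !is.null(records$border)) mark(records$border, "border")
  if (excludeUnmapped && !is.null(records$unmapped))
    mark(records$unmapped, "unmapped")
  if (requireSingleLumen) {
    mark(lc == 0, "no_lumen")
    mark(lc > 1, "multi_lumen")
  }
  mark(area < minAreaUm2, "too_small")
  mark(area > maxAreaUm2, "too_large")
  keep <- is.na(reason)
  report <- data.frame(
    reason = c("retained", "border", "unmapped", "no_lumen", "multi_lumen",
               "too_small", "too_large"),
    count = c(sum(keep), sum(reason == "border", na.rm = TRUE),
              sum(reason == "unmapped", na.rm = TRUE),
              sum(reason == "no_lumen", na.rm = TRUE),
              sum(reason == "multi_lumen", na.rm = TRUE),
              sum(reason == "too_small", na.rm = TRUE),
              sum(reason == "too_large", na.rm = TRUE)))
  excluded <- records[!keep, , drop = FALSE]
  if (nrow(excluded)) excluded$qc_reason <- reason[!keep]
  else excluded$qc_reason <- character(0)
  list(retained = records[keep, , drop = FALSE], excluded = excluded,
       report = report)
}
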