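# internal helpers shared across the pipeline

#' @noRd
msg <- function(..., verbose = getOption("rosetteScreen.verbose", TRUE)) {
  if (isTRUE(verbose)) message("[rosetteScreen] ", ...)
}

# derive a reproducible 32-bit substream seed from a master seed and an index
#' @noRd
subSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 10007) %% 2147483647L)
}

# shoelace polygon area; x, y vertex coordinates (closed implicitly)
#' @noRd
polygonArea <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(0)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# 8-connected labeling built on EBImage's 4-connected bwlabel:
# diagonal-adjacent 4-components are merged by union-find over label pairs.
#' @noRd
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  nlab <- max(lab)
  if (nlab < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1L, -1L]   # down-right diagonal
  a2 <- lab[-nr, -1L]; b2 <- lab[-1L, -nc]   # down-left diagonal
  keep1 <- a1 > 0L & b1 > 0L & a1 != b1
  keep2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(nlab), find, integer(1L))
  remap <- match(root, sort(unique(root)))
  out <- lab
  out[out > 0L] <- remap[out[out > 0L]]
  out
}

# relabel a label matrix to consecutive 1..k preserving first-appearance order
#' @noRd
relabelConsecutive <- function(lab) {
  u <- sort(unique(lab[lab > 0L]))
  if (!length(u)) return(lab)
  out <- lab
  out[out > 0L] <- match(lab[lab > 0L], u)
  out
}

# bounding box (row/col ranges) of TRUE pixels, with optional padding
#' @noRd
bbox <- function(mask, pad = 0L) {
  w <- which(mask, arr.ind = TRUE)
  r <- range(w[, 1L]); c <- range(w[, 2L])
  c(max(1L, r[1L] - pad), min(nrow(mask), r[2L] + pad),
    max(1L, c[1L] - pad), min(ncol(mask), c[2L] + pad))
}

#' @noRd
stopIfNot <- function(cond, ...) if (!isTRUE(cond)) stop(..., call. = FALSE)
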