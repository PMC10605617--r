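# Microbubble detection and sub-pixel localization.

#' Detect microbubbles in one contrast frame
#'
#' Finds local intensity maxima above `relThreshold` times the frame
#' maximum, suppresses weaker maxima within `minSeparation`, and refines
#' each surviving peak to sub-pixel precision with an intensity-weighted
#' centroid over a square window. The centroid of a symmetric Gaussian
#' blob recovers its center to well under a tenth of a pixel.
#'
#' @param frame 2D numeric matrix `[nz, nx]`.
#' @param pxSize pixel size in mm.
#' @param relThreshold fraction of the frame maximum in (0, 1).
#' @param minSeparation minimum distance between detections in mm
#'   (>= pixel size).
#' @param window centroid window side in pixels (odd, default 5).
#' @param origin physical (x, z) of the frame's top-left corner in mm.
#' @param minAmplitude absolute intensity floor (default 0). On frames
#'   that happen to contain no bubble the frame maximum is just noise,
#'   so a relative threshold alone would accept noise peaks; any
#'   amplitude floor above the noise ceiling suppresses them.
#' @param maxPeaks cap on candidate maxima per frame, keeping the
#'   brightest (guards against pathological noise-only frames).
#' @return data.frame with columns `frame` (NA, filled by callers),
#'   `x_mm`, `z_mm`, `amplitude`. An all-zero frame yields zero rows.
#' @export
detectMicrobubbles <- function(frame, pxSize, relThreshold = 0.3,
                               minSeparation = 2 * pxSize, window = 5L,
                               origin = c(0, 0), minAmplitude = 0,
                               maxPeaks = 500L) {
  stopifnot(relThreshold > 0, relThreshold < 1, minSeparation >= pxSize)
  nz <- nrow(frame); nx <- ncol(frame)
  empty <- data.frame(frame = integer(), x_mm = numeric(), z_mm = numeric(),
                      amplitude = numeric())
  fmax <- max(frame)
  if (fmax <= 0 || fmax < minAmplitude) return(empty)
  thr <- max(relThreshold * fmax, minAmplitude)

  # strict local maxima over the 8-neighborhood (border excluded)
  core <- frame[2:(nz - 1L), 2:(nx - 1L)]
  isMax <- core > thr
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- frame[(2:(nz - 1L)) + di, (2:(nx - 1L)) + dj]
    isMax <- isMax & (core >= nb)
    # demand strict dominance over at least the raster-order-later side
    if (di > 0 || (di == 0 && dj > 0)) isMax <- isMax & (core > nb)
  }
  idx <- which(isMax, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  pk <- data.frame(i = idx[, 1L] + 1L, j = idx[, 2L] + 1L)
  pk$amp <- frame[cbind(pk$i, pk$j)]
  pk <- pk[order(-pk$amp, pk$i, pk$j), ]
  if (nrow(pk) > maxPeaks) pk <- pk[seq_len(maxPeaks), , drop = FALSE]

  # greedy non-maximum suppression within minSeparation
  sepPx <- minSeparation / pxSize
  keep <- logical(nrow(pk))
  ki <- kj <- numeric(0)
  for (r in seq_len(nrow(pk))) {
    if (length(ki) == 0L ||
        min((ki - pk$i[r])^2 + (kj - pk$j[r])^2) >= sepPx^2) {
      keep[r] <- TRUE
      ki <- c(ki, pk$i[r]); kj <- c(kj, pk$j[r])
    }
  }
  pk <- pk[keep, , drop = FALSE]

  h <- (as.integer(window) - 1L) %/% 2L
  out <- lapply(seq_len(nrow(pk)), function(r) {
    i0 <- max(1L, pk$i[r] - h); i1 <- min(nz, pk$i[r] + h)
    j0 <- max(1L, pk$j[r] - h); j1 <- min(nx, pk$j[r] + h)
    w <- frame[i0:i1, j0:j1, drop = FALSE]
    w <- pmax(w, 0)
    tot <- sum(w)
    if (tot <= 0) return(NULL)
    ci <- sum(rowSums(w) * (i0:i1)) / tot
    cj <- sum(colSums(w) * (j0:j1)) / tot
    data.frame(frame = NA_integer_,
               x_mm = origin[1L] + (cj - 0.5) * pxSize,
               z_mm = origin[2L] + (ci - 0.5) * pxSize,
               amplitude = pk$amp[r])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

#' Detect microbubbles in every frame of a contrast stack
#'
#' @param stack a contrast [FrameStack-class].
#' @param ... passed to [detectMicrobubbles()].
#' @return data.frame of detections with the `frame` column filled.
#' @export
detectStack <- function(stack, ...) {
  px <- pixelSize(stack)
  fr <- frames(stack)
  res <- lapply(seq_len(dim(fr)[3L]), function(f) {
    d <- detectMicrobubbles(fr[, , f], px, ...)
    if (nrow(d)) d$frame <- f
    d
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
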