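# Speckle-tracking motion estimation and motion correction.

#' Estimate per-frame rigid displacement by speckle tracking
#'
#' Block-matching against a reference frame: a grid of blocks in the
#' central part of the reference is cross-correlated (normalized) with
#' each frame over integer shifts up to `searchRadius`, the integer peak
#' is refined to sub-pixel precision by separable parabolic
#' interpolation, and the per-block displacements are averaged. Blocks
#' whose correlation peak is below 0.5 are dropped from the average; if
#' every block is below 0.5 the frame's estimate is kept but flagged via
#' the confidence slot. True displacements larger than `searchRadius`
#' cannot be recovered — the estimate clips at the search boundary.
#'
#' @param bmode a B-mode [FrameStack-class].
#' @param referenceIndex 1-based reference frame (default 1).
#' @param blockSize block side in mm (default 1.0).
#' @param searchRadius maximum displacement searched, in mm (default 0.5).
#' @param blockGrid blocks per axis (default 3, i.e. a 3 x 3 grid).
#' @return A [MotionField-class]: per-frame displacement of the tissue
#'   relative to the reference frame.
#' @export
estimateMotion <- function(bmode, referenceIndex = 1L, blockSize = 1.0,
                           searchRadius = 0.5, blockGrid = 3L) {
  fr <- frames(bmode)
  px <- pixelSize(bmode)
  nz <- dim(fr)[1L]; nx <- dim(fr)[2L]; nf <- dim(fr)[3L]
  referenceIndex <- as.integer(referenceIndex)
  stopifnot(referenceIndex >= 1L, referenceIndex <= nf)
  hb <- max(4L, round(blockSize / px / 2))
  s <- max(2L, ceiling(searchRadius / px))
  if (2L * (hb + s) + 1L >= min(nz, nx))
    stop("block plus search window larger than the frame")

  # block centres on a regular grid over the central region (0-based)
  gi <- round(seq(hb + s, nz - 1L - hb - s, length.out = blockGrid + 2L))
  gj <- round(seq(hb + s, nx - 1L - hb - s, length.out = blockGrid + 2L))
  gi <- gi[2:(blockGrid + 1L)]; gj <- gj[2:(blockGrid + 1L)]
  centers <- expand.grid(i = gi, j = gj)

  ref <- fr[, , referenceIndex]
  disp <- matrix(0, nf, 2L, dimnames = list(NULL, c("dx", "dz")))
  conf <- numeric(nf)
  conf[referenceIndex] <- 1

  refine <- function(cm, pk) {
    # separable parabolic sub-pixel refinement around integer peak pk
    del <- c(0, 0)
    n <- nrow(cm)
    if (pk[1L] > 1L && pk[1L] < n) {
      a <- cm[pk[1L] - 1L, pk[2L]]; b <- cm[pk[1L], pk[2L]]
      cc <- cm[pk[1L] + 1L, pk[2L]]
      den <- a - 2 * b + cc
      if (den < 0) del[1L] <- 0.5 * (a - cc) / den
    }
    if (pk[2L] > 1L && pk[2L] < n) {
      a <- cm[pk[1L], pk[2L] - 1L]; b <- cm[pk[1L], pk[2L]]
      cc <- cm[pk[1L], pk[2L] + 1L]
      den <- a - 2 * b + cc
      if (den < 0) del[2L] <- 0.5 * (a - cc) / den
    }
    pmin(pmax(del, -0.5), 0.5)
  }

  # process frames outwards from the reference so each frame can seed
  # its search with the neighbouring frame's displacement (motion is
  # slow relative to the frame rate); a low-confidence local search
  # falls back to the full search radius
  order_f <- c(seq(referenceIndex + 1L, length.out = nf - referenceIndex),
               rev(seq_len(referenceIndex - 1L)))
  sLoc <- min(s, 3L)
  prevUp <- prevDown <- c(0, 0)  # prior (di, dj) in px
  searchFrame <- function(img, off, sr) {
    di <- dj <- pkc <- numeric(0)
    for (b in seq_len(nrow(centers))) {
      cm <- cpp_ncc_search(ref, img, centers$i[b], centers$j[b], hb, sr,
                           off[1L], off[2L])
      pk <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
      del <- refine(cm, pk)
      di <- c(di, off[1L] + pk[1L] - sr - 1L + del[1L])
      dj <- c(dj, off[2L] + pk[2L] - sr - 1L + del[2L])
      pkc <- c(pkc, max(cm))
    }
    list(di = di, dj = dj, pkc = pkc)
  }
  for (f in order_f) {
    img <- fr[, , f]
    prior <- if (f > referenceIndex) prevUp else prevDown
    off <- pmin(pmax(round(prior), -(s - sLoc)), s - sLoc)
    r <- searchFrame(img, off, sLoc)
    if (max(r$pkc) < 0.5 && sLoc < s) r <- searchFrame(img, c(0L, 0L), s)
    use <- r$pkc >= 0.5
    conf[f] <- max(r$pkc)
    if (!any(use)) use <- rep(TRUE, length(r$pkc))
    est <- c(mean(r$di[use]), mean(r$dj[use]))
    disp[f, ] <- c(est[2L], est[1L]) * px
    if (f > referenceIndex) prevUp <- est else prevDown <- est
  }
  new("MotionField", displacement = disp, referenceIndex = referenceIndex,
      confidence = conf)
}

#' Motion-correct microbubble positions
#'
#' Subtracts the frame's estimated tissue displacement from every
#' detection so all positions live in the reference frame's coordinates.
#' Row order is preserved.
#'
#' @param detections data.frame with columns `frame`, `x_mm`, `z_mm`.
#' @param motion a [MotionField-class] covering every detection frame.
#' @return the detections data.frame with shifted positions.
#' @export
correctPositions <- function(detections, motion) {
  if (nrow(detections) == 0L) return(detections)
  d <- displacement(motion)
  if (any(detections$frame < 1L | detections$frame > nrow(d)))
    stop("motion field does not cover every detection frame")
  detections$x_mm <- detections$x_mm - d[detections$frame, 1L]
  detections$z_mm <- detections$z_mm - d[detections$frame, 2L]
  detections
}
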