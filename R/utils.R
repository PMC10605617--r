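# Internal helpers: RNG scoping and polyline geometry.

# Evaluate expr with a locally-set RNG seed, restoring the caller's RNG
# state afterwards so generators are pure functions of their arguments.
withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Total arc length of a polyline (rows = points).
polylineLength <- function(p) {
  if (nrow(p) < 2L) return(0)
  sum(sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

# Distance-metric tortuosity: arc length over chord. Returns NA for a
# degenerate (zero-chord) polyline.
polylineTortuosity <- function(p) {
  chord <- sqrt(sum((p[nrow(p), ] - p[1L, ])^2))
  if (chord == 0) return(NA_real_)
  polylineLength(p) / chord
}

# Point at arc-length position s along a polyline (clamped to the ends).
pointAlongPolyline <- function(p, s) {
  seg <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  cs <- c(0, cumsum(seg))
  s <- min(max(s, 0), cs[length(cs)])
  i <- findInterval(s, cs, rightmost.closed = TRUE)
  i <- min(i, length(seg))
  f <- if (seg[i] > 0) (s - cs[i]) / seg[i] else 0
  p[i, ] + f * (p[i + 1L, ] - p[i, ])
}

# Squared EDT wrapper returning a (possibly 2D) array of Euclidean
# distances from every TRUE voxel to the nearest FALSE voxel centre.
euclideanDistance <- function(mask) {
  d <- dim(mask)
  if (length(d) == 2L) d <- c(d, 1L)
  out <- sqrt(cpp_edt_sq(as.logical(mask), as.integer(d)))
  array(out, dim = dim(mask))
}

# Binary closing with a Euclidean ball of radius r (voxel units) via two
# distance transforms (dilate then erode). The array border acts as a
# mirror: no background is assumed outside the array, so structures
# touching the border are not eroded there.
binaryClose <- function(mask, r) {
  if (r <= 0) return(mask)
  dil <- euclideanDistance(!mask) <= r
  (euclideanDistance(dil) > r) | mask
}
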