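# Independent oracles and fixture builders used across the suite.
# These deliberately avoid the package's own kernels: frames are drawn
# with plain outer(), distances with dense pairwise arithmetic, and the
# assignment oracle enumerates every gated matching.

# Render Gaussian blobs onto a frame with base-R arithmetic.
# centers: matrix with columns (i, j) in continuous pixel units
# (pixel m's center at m - 0.5).
gaussFrame <- function(nz, nx, centers, sigma, amp = 1) {
  f <- matrix(0, nz, nx)
  ii <- seq_len(nz) - 0.5
  jj <- seq_len(nx) - 0.5
  for (b in seq_len(nrow(centers))) {
    gz <- exp(-(ii - centers[b, 1L])^2 / (2 * sigma^2))
    gx <- exp(-(jj - centers[b, 2L])^2 / (2 * sigma^2))
    f <- f + amp[min(b, length(amp))] * outer(gz, gx)
  }
  f
}

# Exhaustive maximum-cardinality minimum-cost gated matching.
bruteAssign <- function(cost, gate) {
  n <- nrow(cost); m <- ncol(cost)
  best <- list(card = -1L, cost = Inf)
  rec <- function(i, used, tot, card) {
    if (i > n) {
      if (card > best$card ||
          (card == best$card && tot < best$cost - 1e-12))
        best <<- list(card = card, cost = tot)
      return(invisible())
    }
    rec(i + 1L, used, tot, card)
    for (j in seq_len(m)) {
      if (!used[j] && is.finite(cost[i, j]) && cost[i, j] <= gate) {
        used[j] <- TRUE
        rec(i + 1L, used, tot + cost[i, j], card + 1L)
        used[j] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, m), 0, 0L)
  best
}

# Brute-force Euclidean distance transform (center-to-center) and
# inscribed-sphere local thickness on a small 3D mask.
bruteLocalThickness <- function(mask) {
  d <- dim(mask)
  co <- which(mask, arr.ind = TRUE)          # foreground centers
  bg <- which(!mask, arr.ind = TRUE)
  dt <- numeric(nrow(co))
  chunk <- 2000L
  for (s in seq(1L, nrow(co), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(co))
    blk <- co[s:e, , drop = FALSE]
    d2 <- outer(blk[, 1L], bg[, 1L], "-")^2 +
      outer(blk[, 2L], bg[, 2L], "-")^2 +
      outer(blk[, 3L], bg[, 3L], "-")^2
    dt[s:e] <- sqrt(apply(d2, 1L, min))
  }
  lt <- numeric(nrow(co))
  for (s in seq(1L, nrow(co), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(co))
    blk <- co[s:e, , drop = FALSE]
    d2 <- outer(blk[, 1L], co[, 1L], "-")^2 +
      outer(blk[, 2L], co[, 2L], "-")^2 +
      outer(blk[, 3L], co[, 3L], "-")^2
    # sphere centred at u with radius dt(u) covers v iff |v - u| < dt(u)
    cover <- sweep(sqrt(d2), 2L, dt, "<")
    lt[s:e] <- apply(sweep(cover, 2L, dt, "*"), 1L, max)
  }
  out <- array(0, dim = d)
  out[mask] <- lt
  out
}

# Axis-3 cylinder mask: voxel centers within `radius` of the central axis.
cylinderMask <- function(nside, nlen, radius, center = (nside + 1) / 2) {
  ii <- seq_len(nside) - 0.5
  r2 <- outer((ii - center + 0.5)^2, (ii - center + 0.5)^2, "+")
  array(rep(r2 <= radius^2, nlen), dim = c(nside, nside, nlen))
}

# Straight two-point polyline tree (single segment).
straightTree <- function(p0, p1, radiusUm = 150, flow = 10, bbox) {
  VesselTree(list(rbind(p0, p1)), radiusUm, flow,
             regionLabel = "CO", parent = 0L, boundingBox = bbox)
}

# Long-form detection stream for a bubble moving on a straight line.
lineDetections <- function(frames, start, step) {
  data.frame(frame = frames,
             x_mm = start[1L] + (seq_along(frames) - 1L) * step[1L],
             z_mm = start[2L] + (seq_along(frames) - 1L) * step[2L])
}
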