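# Hierarchical Kalman microbubble linking.

#' Optimal gated one-to-one assignment
#'
#' Solves the per-frame linking problem: given a cost matrix (rows =
#' predicted track positions, columns = detections) and a gate, find the
#' maximum-cardinality one-to-one matching among pairs with cost <= gate
#' that minimizes total cost. Solved exactly via the Hungarian method on
#' an augmented square matrix, so the result matches brute-force
#' enumeration.
#'
#' @param cost numeric matrix of pair costs (e.g. distances in mm).
#' @param gate scalar; pairs with cost > gate cannot be linked.
#' @return integer vector of length `nrow(cost)`: for each row the
#'   matched column index, or `NA` if unmatched.
#' @export
solveAssignment <- function(cost, gate) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L) return(rep(NA_integer_, n))
  feas <- is.finite(cost) & cost <= gate
  if (!any(feas)) return(rep(NA_integer_, n))
  DUMMY <- gate + 1
  PEN <- 1e6 * DUMMY
  N <- n + m
  M <- matrix(PEN, N, N)
  M[seq_len(n), seq_len(m)] <- ifelse(feas, cost, PEN)
  # row i unmatched -> dummy column m + i; column j unmatched -> dummy row n + j
  for (i in seq_len(n)) M[i, m + i] <- DUMMY
  for (j in seq_len(m)) M[n + j, j] <- DUMMY
  M[(n + 1):N, (m + 1):N] <- 0
  sol <- as.integer(clue::solve_LSAP(M))
  out <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    j <- sol[i]
    if (j <= m && feas[i, j]) out[i] <- j
  }
  out
}

#' Link microbubble detections into trajectories
#'
#' A hierarchical Kalman tracker. Each open track carries a 2D
#' constant-velocity Kalman state (position + velocity; velocity born at
#' zero with inflated covariance). Frame by frame, predicted track
#' positions are matched one-to-one to the frame's detections by optimal
#' gated assignment ([solveAssignment()]); matched tracks are updated,
#' unmatched tracks are closed immediately (no gap tolerance — tracks
#' span strictly consecutive frames), and unmatched detections open new
#' candidate tracks. The hierarchy consists of `nHierarchyPasses` such
#' sweeps: detections consumed by an accepted track (length >=
#' `minTrackLength`) are removed, and the remaining detections are
#' re-linked with the gate widened by `passGateScale`. Only tracks
#' observed in at least `minTrackLength` consecutive frames (default 3)
#' are returned.
#'
#' @param detections data.frame with columns `frame`, `x_mm`, `z_mm`
#'   (typically motion-corrected).
#' @param params a [TrackerParams-class].
#' @param frameRate acquisition frame rate in Hz.
#' @return A [TrackSet-class].
#' @export
trackMicrobubbles <- function(detections, params = trackerParams(),
                              frameRate) {
  empty <- TrackSet(data.frame(track_id = integer(), frame = integer(),
                               x_mm = numeric(), z_mm = numeric()),
                    frameRate)
  if (nrow(detections) == 0L) return(empty)
  gate0 <- if (is.na(params@maxLinkDistance))
    params@maxSpeed / frameRate else params@maxLinkDistance
  det <- detections[order(detections$frame, detections$x_mm,
                          detections$z_mm), , drop = FALSE]
  det$.row <- seq_len(nrow(det))
  avail <- rep(TRUE, nrow(det))
  allTracks <- list()
  for (pass in seq_len(params@nHierarchyPasses)) {
    if (!any(avail)) break
    gate <- gate0 * params@passGateScale^(pass - 1L)
    res <- linkPass(det[avail, , drop = FALSE], gate, params, frameRate)
    for (tr in res) {
      if (length(tr$rows) >= params@minTrackLength) {
        allTracks[[length(allTracks) + 1L]] <- tr
        avail[tr$rows] <- FALSE
      }
    }
  }
  if (!length(allTracks)) return(empty)
  # deterministic emission order: birth frame, then x of first point
  bf <- vapply(allTracks, function(t) t$frames[1L], numeric(1))
  bx <- vapply(allTracks, function(t) t$x[1L], numeric(1))
  allTracks <- allTracks[order(bf, bx)]
  out <- do.call(rbind, lapply(seq_along(allTracks), function(k) {
    t <- allTracks[[k]]
    data.frame(track_id = k, frame = as.integer(t$frames),
               x_mm = t$x, z_mm = t$z)
  }))
  TrackSet(out, frameRate)
}

# One frame-by-frame linking sweep over a detection subset.
linkPass <- function(det, gate, params, frameRate) {
  dt <- 1 / frameRate
  Fm <- diag(4)
  Fm[1L, 3L] <- dt; Fm[2L, 4L] <- dt
  q <- params@processNoise
  Qa <- q * matrix(c(dt^4 / 4, dt^3 / 2, dt^3 / 2, dt^2), 2L, 2L)
  Qm <- matrix(0, 4L, 4L)
  Qm[c(1L, 3L), c(1L, 3L)] <- Qa
  Qm[c(2L, 4L), c(2L, 4L)] <- Qa
  Rm <- params@measurementNoise * diag(2)
  Hm <- cbind(diag(2), matrix(0, 2L, 2L))
  v0 <- (gate / dt)^2  # inflated velocity variance at birth
  P0 <- diag(c(params@measurementNoise, params@measurementNoise, v0, v0))

  open <- list()
  closed <- list()
  byFrame <- split(det, det$frame)
  frameIds <- as.integer(names(byFrame))
  for (fi in seq_along(frameIds)) {
    f <- frameIds[fi]
    dd <- byFrame[[fi]]
    # close tracks that skipped a frame (no gap tolerance)
    if (length(open)) {
      last <- vapply(open, function(t) t$frames[length(t$frames)], numeric(1))
      stale <- last < f - 1L
      closed <- c(closed, open[stale])
      open <- open[!stale]
    }
    nT <- length(open); nD <- nrow(dd)
    assigned <- rep(NA_integer_, nT)
    if (nT && nD) {
      pred <- lapply(open, function(t) {
        x <- Fm %*% t$state
        P <- Fm %*% t$cov %*% t(Fm) + Qm
        list(x = x, P = P)
      })
      px <- vapply(pred, function(p) p$x[1L], numeric(1))
      pz <- vapply(pred, function(p) p$x[2L], numeric(1))
      cost <- sqrt(outer(px, dd$x_mm, "-")^2 + outer(pz, dd$z_mm, "-")^2)
      assigned <- solveAssignment(cost, gate)
    } else if (nT) {
      pred <- NULL
    }
    usedD <- rep(FALSE, nD)
    keepOpen <- list()
    for (i in seq_len(nT)) {
      j <- assigned[i]
      if (is.na(j)) {
        closed <- c(closed, open[i])
        next
      }
      usedD[j] <- TRUE
      t <- open[[i]]
      p <- pred[[i]]
      z <- c(dd$x_mm[j], dd$z_mm[j])
      S <- Hm %*% p$P %*% t(Hm) + Rm
      K <- p$P %*% t(Hm) %*% solve(S)
      t$state <- p$x + K %*% (z - Hm %*% p$x)
      t$cov <- (diag(4) - K %*% Hm) %*% p$P
      t$frames <- c(t$frames, f)
      t$x <- c(t$x, z[1L]); t$z <- c(t$z, z[2L])
      t$rows <- c(t$rows, dd$.row[j])
      keepOpen[[length(keepOpen) + 1L]] <- t
    }
    for (j in which(!usedD)) {
      keepOpen[[length(keepOpen) + 1L]] <- list(
        state = matrix(c(dd$x_mm[j], dd$z_mm[j], 0, 0), 4L, 1L),
        cov = P0, frames = f, x = dd$x_mm[j], z = dd$z_mm[j],
        rows = dd$.row[j])
    }
    open <- keepOpen
  }
  c(closed, open)
}
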