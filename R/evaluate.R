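# Scoring recovered tracks against simulation ground truth.

#' Track-level recall and precision against ground truth
#'
#' An emitted track is *correct* if at least `coverage` of its points
#' have a same-frame ground-truth bubble position of one single bubble
#' within `tolPx` pixels; a true track (bubble observed in at least
#' `minTrackLength` frames) is *recovered* if at least one correct
#' emitted track points to it. Fragmented trajectories therefore count
#' towards recall, while identity switches and noise tracks lower
#' precision.
#'
#' @param trackset a [TrackSet-class] in reference-frame coordinates.
#' @param groundTruth a [GroundTruth-class].
#' @param pixelSizeMm acquisition pixel size in mm.
#' @param tolPx matching tolerance in pixels (default 1).
#' @param coverage fraction of an emitted track's points that must match
#'   (default 0.8).
#' @param minTrackLength true tracks shorter than this are not expected
#'   to be recovered (default 3).
#' @return list: `recall`, `precision`, `nTrue`, `nEmitted`,
#'   `assignment` (data.frame `track_id`, `bubble_id`, `matchFrac`).
#' @export
trackRecallPrecision <- function(trackset, groundTruth, pixelSizeMm,
                                 tolPx = 1, coverage = 0.8,
                                 minTrackLength = 3L) {
  tol <- tolPx * pixelSizeMm
  gt <- trueTracks(groundTruth)
  lens <- table(gt$bubble_id)
  trueIds <- as.numeric(names(lens)[lens >= minTrackLength])
  df <- tracks(trackset)
  ids <- unique(df$track_id)
  rows <- lapply(ids, function(id) {
    e <- df[df$track_id == id, ]
    cand <- gt[gt$frame %in% e$frame, ]
    if (!nrow(cand))
      return(data.frame(track_id = id, bubble_id = NA_real_, matchFrac = 0))
    frac <- vapply(unique(cand$bubble_id), function(b) {
      g <- cand[cand$bubble_id == b, ]
      m <- merge(e, g, by = "frame", suffixes = c("", ".g"))
      if (!nrow(m)) return(0)
      ok <- sqrt((m$x_mm - m$x_mm.g)^2 + (m$z_mm - m$z_mm.g)^2) <= tol
      sum(ok) / nrow(e)
    }, numeric(1))
    b <- unique(cand$bubble_id)[which.max(frac)]
    data.frame(track_id = id, bubble_id = b, matchFrac = max(frac))
  })
  asg <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track_id = numeric(), bubble_id = numeric(),
               matchFrac = numeric())
  correct <- asg[asg$matchFrac >= coverage & !is.na(asg$bubble_id), ]
  recall <- if (length(trueIds))
    mean(trueIds %in% correct$bubble_id) else NA_real_
  precision <- if (nrow(asg)) nrow(correct) / nrow(asg) else NA_real_
  list(recall = recall, precision = precision, nTrue = length(trueIds),
       nEmitted = nrow(asg), assignment = asg)
}
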