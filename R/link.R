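# Frame-to-frame linking with crossing interruption.

#' Link per-frame localizations into trajectories
#'
#' Greedy mutual-nearest-neighbor linking with no gap closing. A track is
#' extended only when exactly one detection lies within `maxDisp` of its
#' last position *and* that detection has no other track end within
#' `maxDisp`. Any ambiguity — two detections reachable from one track end,
#' or one detection claimed by two track ends — terminates all tracks
#' involved and starts fresh tracks from the detections: the
#' crossing-interruption rule, which prevents identity swaps when two
#' particles cross paths. Unassigned detections always start new tracks.
#'
#' @param locs data.frame with columns `frame`, `x`, `y` (um), e.g. from
#'   [detectStack()].
#' @param maxDisp maximum linking displacement per frame, um. A practical
#'   default is `3 * sqrt(4 * Dmax * dt)`, bounding the missed-link
#'   probability for the fastest expected state.
#' @param frameInterval seconds/frame.
#' @param pixelSize um/pixel (metadata only).
#' @param burst burst index stored in the output.
#' @return a [TrackSet-class]; frames within each track are contiguous.
#' @export
linkTracks <- function(locs, maxDisp, frameInterval = 1 / 33,
                       pixelSize = NA_real_, burst = 1L) {
  stopifnot(all(c("frame", "x", "y") %in% names(locs)))
  locs <- locs[order(locs$frame), , drop = FALSE]
  frames <- sort(unique(locs$frame))

  nextId <- 1L
  # active tracks: id, last x, y, last frame
  act <- data.frame(id = integer(), x = numeric(), y = numeric(),
                    frame = integer())
  rows <- vector("list", length(frames))

  for (fi in seq_along(frames)) {
    f <- frames[fi]
    det <- locs[locs$frame == f, c("x", "y"), drop = FALSE]
    nd <- nrow(det)
    live <- act[act$frame == f - 1L, , drop = FALSE]
    assigned <- rep(NA_integer_, nd)           # track id per detection

    if (nrow(live) && nd) {
      d2 <- outer(live$x, det$x, "-")^2 + outer(live$y, det$y, "-")^2
      adj <- d2 <= maxDisp^2
      tdeg <- rowSums(adj)
      ddeg <- colSums(adj)
      for (ti in seq_len(nrow(live))) {
        if (tdeg[ti] != 1L) next
        di <- which(adj[ti, ])
        if (ddeg[di] == 1L) assigned[di] <- live$id[ti]
      }
    }

    newIds <- integer(nd)
    for (di in seq_len(nd)) {
      if (is.na(assigned[di])) {
        assigned[di] <- nextId
        nextId <- nextId + 1L
      }
      newIds[di] <- assigned[di]
    }
    if (nd) {
      rows[[fi]] <- data.frame(particle_id = newIds, burst = burst, frame = f,
                               x = det$x, y = det$y)
      act <- data.frame(id = newIds, x = det$x, y = det$y, frame = f)
    } else {
      act <- act[0, , drop = FALSE]
    }
  }
  tr <- do.call(rbind, rows)
  if (is.null(tr))
    tr <- data.frame(particle_id = integer(), burst = integer(),
                     frame = integer(), x = numeric(), y = numeric())
  tr <- tr[order(tr$particle_id, tr$frame), , drop = FALSE]
  rownames(tr) <- NULL
  new("TrackSet", tracks = tr, frameInterval = frameInterval,
      pixelSize = pixelSize, mask = NULL)
}
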