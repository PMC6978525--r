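# Track-length filtering and fixed-length segmentation.

#' Filter tracks by length and cut them into fixed-length segments
#'
#' Tracks shorter than `minFrames` are discarded (too short to classify);
#' tracks longer than `maxFrames` are discarded to avoid over-counting
#' slow-moving molecules, which are less likely to be interrupted by path
#' crossings. Surviving tracks are cut into consecutive, non-overlapping
#' segments of `segLength` frames; a trailing remainder shorter than
#' `segLength` is dropped.
#'
#' @param x a [TrackSet-class] with contiguous frames per particle.
#' @param segLength segment length in frames (default 15).
#' @param minFrames,maxFrames inclusive track-length bounds (defaults 15 and
#'   105 frames).
#' @return a [SegmentSet-class]. Segment count equals
#'   `sum(floor(L / segLength))` over surviving track lengths `L`.
#' @examples
#' ts <- simulateTracks(simConfig(nTracks = 20, seed = 2))
#' segmentTracks(ts)
#' @export
segmentTracks <- function(x, segLength = 15L, minFrames = 15L,
                          maxFrames = 105L) {
  stopifnot(is(x, "TrackSet"))
  segLength <- as.integer(segLength)
  tr <- x@tracks
  if (!nrow(tr)) return(emptySegmentSet(segLength, x@frameInterval))
  tr <- tr[order(tr$particle_id, tr$burst, tr$frame), , drop = FALSE]
  key <- paste(tr$particle_id, tr$burst, sep = "\r")
  lens <- table(key)[unique(key)]
  keep <- names(lens)[lens >= minFrames & lens <= maxFrames]
  tr <- tr[key %in% keep, , drop = FALSE]
  if (!nrow(tr)) return(emptySegmentSet(segLength, x@frameInterval))
  key <- paste(tr$particle_id, tr$burst, sep = "\r")
  L <- as.integer(lens[key])              # parent track length, per row
  posInTrack <- sequence(as.integer(lens[keep]))
  segIdx <- (posInTrack - 1L) %/% segLength + 1L
  nFull <- L %/% segLength
  inSeg <- segIdx <= nFull
  tr <- tr[inSeg, , drop = FALSE]
  segKey <- paste(key[inSeg], segIdx[inSeg], sep = "\r")
  segId <- match(segKey, unique(segKey))
  out <- data.frame(segment_id = segId,
                    particle_id = tr$particle_id,
                    burst = tr$burst,
                    frame = tr$frame,
                    x = tr$x, y = tr$y,
                    seg_index = segIdx[inSeg],
                    parent_length = L[inSeg])
  if ("true_state" %in% names(tr)) out$true_state <- tr$true_state
  rownames(out) <- NULL
  new("SegmentSet", segments = out, segLength = segLength,
      frameInterval = x@frameInterval)
}

emptySegmentSet <- function(segLength, dt) {
  new("SegmentSet",
      segments = data.frame(segment_id = integer(), particle_id = integer(),
                            burst = integer(), frame = integer(),
                            x = numeric(), y = numeric(),
                            seg_index = integer(), parent_length = integer()),
      segLength = as.integer(segLength), frameInterval = dt)
}

# Coordinates of every segment as nseg x segLength matrices, plus per-segment
# metadata, in segment_id order.
segmentMatrices <- function(segset) {
  seg <- segset@segments
  if (!nrow(seg)) {
    meta <- seg[, c("segment_id", "particle_id", "burst", "frame",
                    "seg_index", "parent_length")]
    if ("true_state" %in% names(seg)) meta$true_state <- integer(0)
    return(list(x = matrix(numeric(), 0, segset@segLength),
                y = matrix(numeric(), 0, segset@segLength), meta = meta))
  }
  seg <- seg[order(seg$segment_id, seg$frame), , drop = FALSE]
  n <- nSegments(segset)
  L <- segset@segLength
  X <- matrix(seg$x, nrow = n, ncol = L, byrow = TRUE)
  Y <- matrix(seg$y, nrow = n, ncol = L, byrow = TRUE)
  first <- seg[seq(1, nrow(seg), by = L), , drop = FALSE]
  meta <- data.frame(segment_id = first$segment_id,
                     particle_id = first$particle_id,
                     burst = first$burst, frame = first$frame,
                     seg_index = first$seg_index,
                     parent_length = first$parent_length)
  if ("true_state" %in% names(seg)) {
    st <- matrix(seg$true_state, nrow = n, ncol = L, byrow = TRUE)
    meta$true_state <- apply(st, 1L, majorityLabel)
  }
  list(x = X, y = Y, meta = meta)
}

majorityLabel <- function(v) {
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_integer_)
  tab <- table(v)
  as.integer(names(tab)[which.max(tab)])   # ties -> smallest label
}
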