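# Plain-text I/O for tracks and segments (CSV with documented headers),
# chosen for interoperability with existing single-particle-tracking tools.

#' Read/write track tables as CSV
#'
#' The on-disk format is a CSV with header
#' `particle_id,burst,frame,x_um,y_um[,true_state]`.
#'
#' @param x a [TrackSet-class].
#' @param path file path.
#' @param frameInterval,pixelSize acquisition metadata attached on read.
#' @return `writeTracksCsv`: `path` invisibly; `readTracksCsv`: a
#'   [TrackSet-class].
#' @export
writeTracksCsv <- function(x, path) {
  tr <- x@tracks
  out <- data.frame(particle_id = tr$particle_id, burst = tr$burst,
                    frame = tr$frame, x_um = tr$x, y_um = tr$y)
  if ("true_state" %in% names(tr)) out$true_state <- tr$true_state
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTracksCsv
#' @export
readTracksCsv <- function(path, frameInterval = 1 / 33,
                          pixelSize = NA_real_) {
  d <- read.csv(path)
  tr <- data.frame(particle_id = as.integer(d$particle_id),
                   burst = as.integer(d$burst), frame = as.integer(d$frame),
                   x = d$x_um, y = d$y_um)
  if ("true_state" %in% names(d)) tr$true_state <- as.integer(d$true_state)
  new("TrackSet", tracks = tr, frameInterval = frameInterval,
      pixelSize = pixelSize, mask = NULL)
}

#' Write a segment table as CSV
#'
#' Header: `segment_id,particle_id,burst,frame,x_um,y_um,seg_index,`
#' `parent_length[,true_state]`.
#'
#' @param x a [SegmentSet-class].
#' @param path file path.
#' @export
writeSegmentsCsv <- function(x, path) {
  s <- x@segments
  out <- data.frame(segment_id = s$segment_id, particle_id = s$particle_id,
                    burst = s$burst, frame = s$frame, x_um = s$x, y_um = s$y,
                    seg_index = s$seg_index, parent_length = s$parent_length)
  if ("true_state" %in% names(s)) out$true_state <- s$true_state
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
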