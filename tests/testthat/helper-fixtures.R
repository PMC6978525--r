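# Shared fixtures: tiny in-code track sets and simulation shortcuts.

# TrackSet from a bare data.frame (adds burst when missing).
makeTrackSet <- function(df, dt = 1 / 33, pixelSize = 0.1, mask = NULL) {
  if (is.null(df$burst)) df$burst <- 1L
  new("TrackSet",
      tracks = df[, c("particle_id", "burst", "frame", "x", "y",
                      intersect("true_state", names(df)))],
      frameInterval = dt, pixelSize = pixelSize, mask = mask)
}

# One contiguous track of a given length at rest positions.
restTrack <- function(id, len, x = 1, y = 1, start = 1L) {
  data.frame(particle_id = id, burst = 1L, frame = start + seq_len(len) - 1L,
             x = x, y = y)
}

# Segment set of n non-switching 15-frame segments per state.
quickSegments <- function(nPerState, D, locSigma, seed = 1L)
  simulateSegments(nPerState, D = D, locSigma = locSigma, seed = seed)

# Hand-rolled dense log-density of a zero-mean MVN (test oracle).
denseMvnLogLik <- function(d, S) {
  -0.5 * (length(d) * log(2 * pi) +
            as.numeric(determinant(S, logarithm = TRUE)$modulus) +
            drop(t(d) %*% solve(S) %*% d))
}
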