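# S4 classes for the tracking / state-classification pipeline.

#' Planar region masks (cell contours)
#'
#' A `RegionMask` describes the planar region inside which molecules live:
#' either a disk (`shape = "disk"`, `center`, `radius`) or an axis-aligned
#' rectangle (`shape = "rect"`, `xlim`, `ylim`). All coordinates are in
#' micrometers. Masks are used for simulation boundaries (reflecting),
#' discarding detections outside the cell contour, and the Monte-Carlo
#' normalization of the pair correlation function.
#'
#' @slot shape `"disk"` or `"rect"`.
#' @slot center numeric length 2, disk center (um).
#' @slot radius disk radius (um).
#' @slot xlim,ylim numeric length 2, rectangle extent (um).
#' @seealso [diskMask()], [rectMask()], [maskContains()], [maskSample()]
#' @exportClass RegionMask
setClass("RegionMask",
  representation(shape = "character", center = "numeric", radius = "numeric",
                 xlim = "numeric", ylim = "numeric"),
  validity = function(object) {
    if (!object@shape %in% c("disk", "rect")) return("shape must be 'disk' or 'rect'")
    if (object@shape == "disk") {
      if (length(object@center) != 2L) return("disk mask needs center of length 2")
      if (length(object@radius) != 1L || object@radius <= 0) return("disk radius must be > 0")
    } else {
      if (length(object@xlim) != 2L || diff(object@xlim) <= 0) return("invalid xlim")
      if (length(object@ylim) != 2L || diff(object@ylim) <= 0) return("invalid ylim")
    }
    TRUE
  })

#' Simulation configuration for synthetic trajectories
#'
#' Parameters of the Markov-switching Brownian-motion generator. Defaults
#' mirror a typical high-frame-rate single-molecule acquisition: bursts of
#' 1000 frames at 33 Hz, geometric track lengths with mean 40 frames, full
#' frame exposure (motion-blur coefficient R = 1/6), and per-state Gaussian
#' localization noise.
#'
#' @slot nTracks number of particles to simulate.
#' @slot frameInterval frame interval Delta t in seconds (default 1/33).
#' @slot framesPerBurst frames per acquisition burst (default 1000).
#' @slot nBursts number of minute-indexed bursts.
#' @slot pixelSize camera pixel size, um/pixel.
#' @slot exposureFraction fraction of the frame interval the shutter is open,
#'   in \[0, 1\]; the blur coefficient of a uniform exposure is
#'   R = exposureFraction / 6.
#' @slot D per-state diffusivities, um^2/s.
#' @slot locSigma per-state localization noise standard deviations, um.
#' @slot transitionMatrix row-stochastic K x K per-step state transition
#'   matrix.
#' @slot initialFractions initial state probabilities (simplex, length K).
#' @slot transitionEvery apply the transition matrix every this many frames
#'   (1 = per frame; 15 emulates segment-level switching).
#' @slot mask [RegionMask-class] the particles are confined to (reflecting).
#' @slot clusterStates integer states whose particles are spawned inside and
#'   confined to small cluster disks.
#' @slot clusterRadius,nClusters cluster-disk radius (um) and number of
#'   cluster centers.
#' @slot trackLengthLaw `"geometric"` or `"fixed"`.
#' @slot meanTrackLength mean of the geometric track-length law (frames).
#' @slot fixedTrackLength track length when `trackLengthLaw = "fixed"`.
#' @slot nSub number of sub-frame positions averaged to emulate motion blur.
#' @slot seed integer RNG seed; identical configs give identical tracks.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(nTracks = "integer", frameInterval = "numeric",
                 framesPerBurst = "integer", nBursts = "integer",
                 pixelSize = "numeric", exposureFraction = "numeric",
                 D = "numeric", locSigma = "numeric",
                 transitionMatrix = "matrix", initialFractions = "numeric",
                 transitionEvery = "integer", mask = "RegionMask",
                 clusterStates = "integer", clusterRadius = "numeric",
                 nClusters = "integer", trackLengthLaw = "character",
                 meanTrackLength = "numeric", fixedTrackLength = "integer",
                 nSub = "integer", seed = "integer"),
  validity = function(object) {
    K <- length(object@D)
    if (length(object@locSigma) != K)
      return("state diffusivities and localization sigmas disagree in length")
    if (nrow(object@transitionMatrix) != K || ncol(object@transitionMatrix) != K)
      return("transition matrix dimension does not match the number of states")
    if (length(object@initialFractions) != K)
      return("initialFractions length does not match the number of states")
    if (any(object@D < 0)) return("diffusivities must be >= 0")
    if (any(object@locSigma < 0)) return("localization sigmas must be >= 0")
    if (object@exposureFraction < 0 || object@exposureFraction > 1)
      return("exposureFraction must lie in [0, 1]")
    if (max(abs(rowSums(object@transitionMatrix) - 1)) > 1e-12)
      return("transition matrix rows must sum to 1 (within 1e-12)")
    if (any(object@transitionMatrix < 0)) return("transition matrix must be non-negative")
    if (abs(sum(object@initialFractions) - 1) > 1e-9 || any(object@initialFractions < 0))
      return("initialFractions must be a probability vector")
    if (length(object@clusterStates) &&
        (any(object@clusterStates < 1) || any(object@clusterStates > K)))
      return("clusterStates out of range")
    if (!object@trackLengthLaw %in% c("geometric", "fixed"))
      return("trackLengthLaw must be 'geometric' or 'fixed'")
    if (object@nTracks < 1L) return("nTracks must be >= 1")
    TRUE
  })

#' Set of single-particle trajectories
#'
#' The pipeline's central record: per-particle, time-ordered planar positions
#' in physical units. The `tracks` slot is a data.frame with columns
#' `particle_id`, `burst`, `frame`, `x`, `y` and (for synthetic data)
#' `true_state`. Frames within a particle are contiguous; positions are in
#' micrometers.
#'
#' @slot tracks data.frame of localizations as described above.
#' @slot frameInterval frame interval in seconds.
#' @slot pixelSize camera pixel size in um/pixel (NA when unknown).
#' @slot mask the [RegionMask-class] the data live in, or `NULL`.
#' @exportClass TrackSet
setClass("TrackSet",
  representation(tracks = "data.frame", frameInterval = "numeric",
                 pixelSize = "numeric", mask = "ANY"),
  validity = function(object) {
    need <- c("particle_id", "burst", "frame", "x", "y")
    if (!all(need %in% names(object@tracks)))
      return(paste("tracks must have columns", paste(need, collapse = ", ")))
    tr <- object@tracks
    if (nrow(tr)) {
      key <- paste(tr$particle_id, tr$burst)
      ok <- tapply(tr$frame, key, function(f) all(diff(f) == 1L))
      if (!all(ok)) return("frames within a particle must be contiguous and increasing")
    }
    if (object@frameInterval <= 0) return("frameInterval must be > 0")
    TRUE
  })

#' Fixed-length trajectory segments
#'
#' Tracks cut into consecutive, non-overlapping fixed-length pieces (15
#' frames by default), the unit of diffusive-state classification. The
#' `segments` data.frame has columns `segment_id`, `particle_id`, `burst`,
#' `frame`, `x`, `y`, `seg_index` (position of the segment within its parent
#' track), `parent_length` (parent track length in frames) and optionally
#' `true_state`.
#'
#' @slot segments data.frame as described above.
#' @slot segLength segment length in frames.
#' @slot frameInterval frame interval in seconds.
#' @exportClass SegmentSet
setClass("SegmentSet",
  representation(segments = "data.frame", segLength = "integer",
                 frameInterval = "numeric"),
  validity = function(object) {
    need <- c("segment_id", "particle_id", "burst", "frame", "x", "y",
              "seg_index", "parent_length")
    if (!all(need %in% names(object@segments)))
      return(paste("segments must have columns", paste(need, collapse = ", ")))
    if (nrow(object@segments)) {
      n <- table(object@segments$segment_id)
      if (any(n != object@segLength))
        return("every segment must have exactly segLength rows")
    }
    TRUE
  })

#' Mixture model of diffusive states
#'
#' K diffusive states, each a zero-mean Gaussian model of segment
#' displacements with diffusivity `D[k]`, localization variance
#' `sigma2[k]` and population weight `weights[k]`. States are sorted by
#' increasing diffusivity (state 1 = slowest). Carries the total
#' log-likelihood, the Bayesian information criterion and the per-iteration
#' log-likelihood trace of the EM run that produced it.
#'
#' @slot K number of states.
#' @slot D per-state diffusivity, um^2/s.
#' @slot sigma2 per-state localization variance, um^2.
#' @slot weights mixture weights (simplex).
#' @slot logLik total log-likelihood.
#' @slot bic BIC = -2 logLik + p log N with p = 3K - 1.
#' @slot converged logical, EM convergence flag.
#' @slot dt frame interval used, seconds.
#' @slot blurR motion-blur coefficient used.
#' @slot logLikTrace per-iteration log-likelihood.
#' @exportClass StateModel
setClass("StateModel",
  representation(K = "integer", D = "numeric", sigma2 = "numeric",
                 weights = "numeric", logLik = "numeric", bic = "numeric",
                 converged = "logical", dt = "numeric", blurR = "numeric",
                 logLikTrace = "numeric"),
  validity = function(object) {
    if (length(object@D) != object@K || length(object@sigma2) != object@K ||
        length(object@weights) != object@K)
      return("D, sigma2 and weights must all have length K")
    if (abs(sum(object@weights) - 1) > 1e-9)
      return("weights must sum to 1 (within 1e-9)")
    if (is.unsorted(object@D)) return("states must be sorted by increasing D")
    if (any(object@sigma2 < 0)) return("sigma2 must be >= 0")
    TRUE
  })

#' Fitted segment classification
#'
#' Result of [emFit()]: the fitted [StateModel-class] plus the posterior
#' state probabilities of every segment and the hard (maximum-posterior)
#' labels. Rows of `posterior` sum to 1.
#'
#' @slot model the fitted [StateModel-class].
#' @slot posterior numeric matrix, segments x states.
#' @slot labels integer maximum-posterior state per segment.
#' @slot segmentIds segment ids, aligned with rows of `posterior`.
#' @exportClass PemFit
setClass("PemFit",
  representation(model = "StateModel", posterior = "matrix",
                 labels = "integer", segmentIds = "integer"),
  validity = function(object) {
    if (nrow(object@posterior) != length(object@labels)) return("labels/posterior mismatch")
    if (ncol(object@posterior) != object@model@K) return("posterior has wrong number of columns")
    if (nrow(object@posterior) &&
        max(abs(rowSums(object@posterior) - 1)) > 1e-9)
      return("posterior rows must sum to 1 (within 1e-9)")
    TRUE
  })

#' pEM model scan across state counts
#'
#' Result of [pemSearch()]: the best fit for each explored number of states
#' K, their BIC values, and the BIC-selected K.
#'
#' @slot fits list of [PemFit-class], one per explored K (named by K).
#' @slot bic numeric BIC per explored K.
#' @slot bestK BIC-selected number of states.
#' @exportClass PemScan
setClass("PemScan",
  representation(fits = "list", bic = "numeric", bestK = "integer"))

#' Ensemble mean-square displacement curve
#'
#' @slot lag lag in frames.
#' @slot msd mean-square displacement, um^2.
#' @slot nPairs number of displacement pairs per lag.
#' @slot group label of the trajectory group (state or condition).
#' @exportClass MsdCurve
setClass("MsdCurve",
  representation(lag = "integer", msd = "numeric", nPairs = "numeric",
                 group = "character"),
  validity = function(object) {
    if (length(object@msd) != length(object@lag)) return("lag/msd mismatch")
    if (any(object@msd < 0)) return("msd must be >= 0")
    TRUE
  })

#' Pair correlation curve
#'
#' Binned estimate of the pair correlation function g(r) of a planar point
#' pattern inside a mask, normalized by a Monte-Carlo sample of complete
#' spatial randomness (CSR) in the same mask so that mask geometry cancels.
#' g = 1 for CSR; g > 1 at short r indicates clustering.
#'
#' @slot r annulus bin centers, um.
#' @slot g pair correlation estimate per bin.
#' @slot nPairs observed pair count per bin.
#' @slot valid FALSE for bins with no CSR reference pairs.
#' @slot group label of the point group (e.g. pooled states).
#' @exportClass GrCurve
setClass("GrCurve",
  representation(r = "numeric", g = "numeric", nPairs = "numeric",
                 valid = "logical", group = "character"),
  validity = function(object) {
    n <- length(object@r)
    if (length(object@g) != n || length(object@nPairs) != n ||
        length(object@valid) != n) return("slot lengths disagree")
    if (any(object@g[object@valid] < 0)) return("g must be >= 0")
    TRUE
  })

#' STICS velocity field
#'
#' Grid of local flow vectors, one per (subregion, time window). The
#' `vectors` data.frame has columns `x`, `y` (subregion center, um),
#' `window` (time-of-interest index), `tmid` (window mid-time, s), `vx`,
#' `vy`, `speed` (um/min) and `valid` (quality-control flag). Invalid
#' vectors carry NA speeds.
#'
#' @slot vectors data.frame as described above.
#' @slot pixelSize um/pixel.
#' @slot frameInterval seconds/frame.
#' @slot sub subregion size, pixels.
#' @slot toi time-of-interest length, frames.
#' @exportClass VelocityField
setClass("VelocityField",
  representation(vectors = "data.frame", pixelSize = "numeric",
                 frameInterval = "numeric", sub = "integer", toi = "integer"),
  validity = function(object) {
    need <- c("x", "y", "window", "vx", "vy", "speed", "valid")
    if (!all(need %in% names(object@vectors)))
      return(paste("vectors must have columns", paste(need, collapse = ", ")))
    v <- object@vectors[object@vectors$valid, , drop = FALSE]
    if (nrow(v) && max(abs(v$speed - sqrt(v$vx^2 + v$vy^2)), na.rm = TRUE) > 1e-8)
      return("speed must equal hypot(vx, vy) for valid vectors")
    TRUE
  })

#' Directional coherence of a velocity field
#'
#' Per-vector cosine of the angle between the local flow vector and the
#' direction from the vector's position to the cell centroid: +1 for flow
#' straight towards the centroid (inward), -1 for flow straight away
#' (outward). Carries the inward (c > threshold) and outward
#' (c < -threshold) fractions.
#'
#' @slot values coherence values in \[-1, 1\], one per valid vector.
#' @slot inwardFraction share of vectors with c > threshold.
#' @slot outwardFraction share of vectors with c < -threshold.
#' @slot threshold the cutoff used for the fractions (default 0.9).
#' @slot n number of vectors entering the fractions.
#' @exportClass CoherenceResult
setClass("CoherenceResult",
  representation(values = "numeric", inwardFraction = "numeric",
                 outwardFraction = "numeric", threshold = "numeric",
                 n = "integer"),
  validity = function(object) {
    if (length(object@values) &&
        (min(object@values) < -1 - 1e-9 || max(object@values) > 1 + 1e-9))
      return("coherence values must lie in [-1, 1]")
    f <- c(object@inwardFraction, object@outwardFraction)
    if (any(f < 0 | f > 1)) return("fractions must lie in [0, 1]")
    if (sum(f) > 1 + 1e-9) return("inward + outward fractions cannot exceed 1")
    TRUE
  })
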