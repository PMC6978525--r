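# Synthetic trajectory generator: Markov-switching Brownian motion with
# camera exposure (motion blur) and Gaussian localization noise.

#' Build a simulation configuration
#'
#' Constructs a validated [SimConfig-class]. Defaults describe a burst
#' acquisition of 1000 frames at 33 Hz, geometric track lengths of mean 40
#' frames, full-frame exposure (blur coefficient R = 1/6) and a 10 um
#' disk-shaped cell mask.
#'
#' @param nTracks number of particles.
#' @param D per-state diffusivities, um^2/s.
#' @param locSigma per-state localization noise SD, um (recycled to
#'   `length(D)`).
#' @param transitionMatrix row-stochastic K x K per-step transition matrix
#'   (default: identity, i.e. no switching).
#' @param initialFractions initial state probabilities (default: uniform).
#' @param transitionEvery apply the transition matrix every this many frames.
#' @param frameInterval,framesPerBurst,nBursts acquisition timing.
#' @param pixelSize camera pixel size, um/pixel.
#' @param exposureFraction shutter-open fraction of the frame interval; the
#'   blur coefficient is `exposureFraction / 6` for uniform exposure.
#' @param mask a [RegionMask-class] (reflecting boundary).
#' @param clusterStates states whose particles are spawned inside and
#'   confined to small cluster disks (clustered slow states).
#' @param clusterRadius,nClusters cluster-disk radius (um) and count.
#' @param trackLengthLaw `"geometric"` (mean `meanTrackLength`) or
#'   `"fixed"` (`fixedTrackLength` frames).
#' @param meanTrackLength,fixedTrackLength track-length law parameters.
#' @param nSub sub-frame positions averaged over the exposure window.
#' @param seed RNG seed.
#' @return a [SimConfig-class].
#' @seealso [simulateTracks()]
#' @export
simConfig <- function(nTracks = 100L, D = 0.1, locSigma = 0.03,
                      transitionMatrix = NULL, initialFractions = NULL,
                      transitionEvery = 1L, frameInterval = 1 / 33,
                      framesPerBurst = 1000L, nBursts = 1L, pixelSize = 0.1,
                      exposureFraction = 1, mask = diskMask(c(5, 5), 5),
                      clusterStates = integer(0), clusterRadius = 0.2,
                      nClusters = 10L, trackLengthLaw = c("geometric", "fixed"),
                      meanTrackLength = 40, fixedTrackLength = 15L,
                      nSub = 10L, seed = 1L) {
  K <- length(D)
  locSigma <- rep_len(locSigma, K)
  if (is.null(transitionMatrix)) transitionMatrix <- diag(K)
  if (is.null(initialFractions)) initialFractions <- rep(1 / K, K)
  if (!is.matrix(transitionMatrix))
    transitionMatrix <- matrix(transitionMatrix, K, K)
  if (nrow(transitionMatrix) != K || ncol(transitionMatrix) != K ||
      length(initialFractions) != K)
    stop("state count mismatch between D, locSigma, transitionMatrix and initialFractions")
  new("SimConfig", nTracks = as.integer(nTracks),
      frameInterval = frameInterval, framesPerBurst = as.integer(framesPerBurst),
      nBursts = as.integer(nBursts), pixelSize = pixelSize,
      exposureFraction = exposureFraction, D = D, locSigma = locSigma,
      transitionMatrix = transitionMatrix,
      initialFractions = initialFractions,
      transitionEvery = as.integer(transitionEvery), mask = mask,
      clusterStates = as.integer(clusterStates), clusterRadius = clusterRadius,
      nClusters = as.integer(nClusters),
      trackLengthLaw = match.arg(trackLengthLaw),
      meanTrackLength = meanTrackLength,
      fixedTrackLength = as.integer(fixedTrackLength), nSub = as.integer(nSub),
      seed = as.integer(seed))
}

#' Simulate a set of single-particle trajectories
#'
#' Each particle performs Brownian motion with the diffusivity of its current
#' state, switching states by a Markov chain applied every
#' `transitionEvery` frames. The reported position of a frame is the average
#' of `nSub` sub-frame positions taken over the exposure window (motion
#' blur), plus isotropic Gaussian localization noise with the current
#' state's sigma. Particles reflect off the mask boundary; particles whose
#' initial state is a cluster state are spawned inside a randomly chosen
#' cluster disk and reflect off its edge while they remain in a cluster
#' state. Fully reproducible from the config seed.
#'
#' @param config a [SimConfig-class].
#' @return a [TrackSet-class] whose `true_state` column records the
#'   generating state of every frame.
#' @examples
#' ts <- simulateTracks(simConfig(nTracks = 5, D = 0.05, locSigma = 0,
#'                                trackLengthLaw = "fixed", seed = 7))
#' nTracks(ts)
#' @export
simulateTracks <- function(config) {
  validObject(config)
  withSeed(config@seed, {
    K <- length(config@D)
    n <- config@nTracks
    dt <- config@frameInterval
    eps <- config@exposureFraction
    m <- config@nSub
    mask <- config@mask

    lens <- switch(config@trackLengthLaw,
      geometric = 1L + stats::rgeom(n, 1 / config@meanTrackLength),
      fixed = rep(config@fixedTrackLength, n))
    lens <- pmin(pmax(lens, 1L), config@framesPerBurst)
    bursts <- if (config@nBursts > 1L)
      sample.int(config@nBursts, n, replace = TRUE) else rep(1L, n)
    starts <- vapply(lens, function(L)
      sample.int(config@framesPerBurst - L + 1L, 1L), integer(1))

    state <- sample.int(K, n, replace = TRUE, prob = config@initialFractions)

    # Cluster geometry: centers inset so that cluster disks fit in the mask.
    clustered0 <- state %in% config@clusterStates
    clusterId <- rep(NA_integer_, n)
    centers <- NULL
    if (length(config@clusterStates) && any(clustered0)) {
      centers <- maskSample(mask, config@nClusters, margin = config@clusterRadius)
      clusterId[clustered0] <- sample.int(config@nClusters, sum(clustered0),
                                          replace = TRUE)
    }

    pos <- maskSample(mask, n)
    if (any(clustered0)) {
      idx <- which(clustered0)
      rr <- config@clusterRadius * sqrt(runif(length(idx)))
      th <- runif(length(idx), 0, 2 * pi)
      pos[idx, 1] <- centers[clusterId[idx], 1] + rr * cos(th)
      pos[idx, 2] <- centers[clusterId[idx], 2] + rr * sin(th)
    }

    reflectAll <- function(p, act) {
      cid <- clusterId[act]
      conf <- !is.na(cid) & (state[act] %in% config@clusterStates)
      if (any(conf)) {
        i <- which(conf)
        cc <- centers[cid[i], , drop = FALSE]
        rel <- reflectDisk(cbind(p[i, 1] - cc[, 1] + 0, p[i, 2] - cc[, 2] + 0),
                           c(0, 0), config@clusterRadius)
        p[i, 1] <- cc[, 1] + rel[, 1]
        p[i, 2] <- cc[, 2] + rel[, 2]
        if (any(!conf)) {
          j <- which(!conf)
          p[j, ] <- maskReflect(mask, p[j, , drop = FALSE])
        }
        p
      } else maskReflect(mask, p)
    }

    cumP <- t(apply(config@transitionMatrix, 1L, cumsum))
    maxL <- max(lens)
    X <- matrix(NA_real_, n, maxL)
    Y <- matrix(NA_real_, n, maxL)
    S <- matrix(NA_integer_, n, maxL)

    for (f in seq_len(maxL)) {
      act <- which(lens >= f)
      if (!length(act)) break
      Dst <- config@D[state[act]]
      sg <- config@locSigma[state[act]]
      na <- length(act)
      if (eps > 0 && m > 0) {
        dtSub <- eps * dt / m
        sx <- numeric(na); sy <- numeric(na)
        sdSub <- sqrt(2 * Dst * dtSub)
        for (i in seq_len(m)) {
          pos[act, 1] <- pos[act, 1] + rnorm(na) * sdSub
          pos[act, 2] <- pos[act, 2] + rnorm(na) * sdSub
          pos[act, ] <- reflectAll(pos[act, , drop = FALSE], act)
          sx <- sx + pos[act, 1]
          sy <- sy + pos[act, 2]
        }
        mx <- sx / m
        my <- sy / m
      } else {
        mx <- pos[act, 1]
        my <- pos[act, 2]
      }
      X[cbind(act, f)] <- mx + rnorm(na) * sg
      Y[cbind(act, f)] <- my + rnorm(na) * sg
      S[cbind(act, f)] <- state[act]

      dtTail <- (1 - eps) * dt
      if (dtTail > 0) {
        sdTail <- sqrt(2 * Dst * dtTail)
        pos[act, 1] <- pos[act, 1] + rnorm(na) * sdTail
        pos[act, 2] <- pos[act, 2] + rnorm(na) * sdTail
        pos[act, ] <- reflectAll(pos[act, , drop = FALSE], act)
      }

      # State switch between frame f and f + 1, every `transitionEvery` steps.
      if (f %% config@transitionEvery == 0L && K > 1L) {
        u <- runif(na)
        rows <- cumP[state[act], , drop = FALSE]
        state[act] <- rowSums(u > rows) + 1L
      }
    }

    ids <- rep.int(seq_len(n), lens)
    off <- sequence(lens)
    df <- data.frame(
      particle_id = ids,
      burst = bursts[ids],
      frame = starts[ids] + off - 1L,
      x = X[cbind(ids, off)],
      y = Y[cbind(ids, off)],
      true_state = S[cbind(ids, off)])
    df <- df[order(df$particle_id, df$frame), , drop = FALSE]
    rownames(df) <- NULL
    new("TrackSet", tracks = df, frameInterval = dt,
        pixelSize = config@pixelSize, mask = mask)
  })
}

#' Simulate fixed-length segments of known state
#'
#' Convenience wrapper around [simulateTracks()] + [segmentTracks()]:
#' generates `nPerState` non-switching tracks of exactly `segLength` frames
#' for every state, so each resulting segment carries a known ground-truth
#' state.
#'
#' @param nPerState segments per state.
#' @param D,locSigma per-state diffusivities (um^2/s) and noise SDs (um).
#' @param segLength segment length in frames.
#' @param mask simulation mask; the default 40 um disk keeps boundary
#'   reflections negligible for the diffusivities used in practice.
#' @param seed RNG seed.
#' @inheritParams simConfig
#' @return a [SegmentSet-class] with a `true_state` column.
#' @export
simulateSegments <- function(nPerState, D, locSigma, segLength = 15L,
                             frameInterval = 1 / 33, exposureFraction = 1,
                             mask = diskMask(c(20, 20), 20), seed = 1L) {
  sets <- lapply(seq_along(D), function(k) {
    cfg <- simConfig(nTracks = nPerState, D = D[k], locSigma = locSigma[k],
                     trackLengthLaw = "fixed", fixedTrackLength = segLength,
                     frameInterval = frameInterval,
                     exposureFraction = exposureFraction, mask = mask,
                     framesPerBurst = max(1000L, segLength),
                     seed = seed + k - 1L)
    tr <- trackData(simulateTracks(cfg))
    tr$true_state <- k
    tr$particle_id <- tr$particle_id + (k - 1L) * nPerState
    tr
  })
  all <- do.call(rbind, sets)
  ts <- new("TrackSet", tracks = all, frameInterval = frameInterval,
            pixelSize = 0.1, mask = mask)
  segmentTracks(ts, segLength = segLength, minFrames = segLength,
                maxFrames = .Machine$integer.max)
}
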