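# Spatial pair-correlation analysis of state-sorted molecules.

#' First position of each distinct particle, with its state label
#'
#' For pair-correlation analysis, each distinct particle contributes a
#' single point (its first localization) so that long tracks do not
#' dominate the point pattern. A particle classified segment-by-segment
#' gets the majority label over its segments (ties towards the slower
#' state).
#'
#' @param segset the classified [SegmentSet-class].
#' @param labels per-segment state labels ([PemFit-class] accepted).
#' @return data.frame with `particle_id`, `burst`, `x`, `y`, `state`; one
#'   row per distinct (particle, burst).
#' @export
firstPositions <- function(segset, labels) {
  if (is(labels, "PemFit")) labels <- stateLabels(labels)
  sm <- segmentMatrices(segset)
  meta <- sm$meta
  lab <- labels[match(meta$segment_id, as.integer(names(labels)))]
  if (anyNA(lab)) lab <- unname(labels)[meta$segment_id]
  if (!nrow(meta))
    return(data.frame(particle_id = integer(), burst = integer(),
                      x = numeric(), y = numeric(), state = integer()))
  key <- paste(meta$particle_id, meta$burst, sep = "\r")
  out <- lapply(split(seq_len(nrow(meta)), key), function(i) {
    i1 <- i[which.min(meta$seg_index[i])]
    data.frame(particle_id = meta$particle_id[i1], burst = meta$burst[i1],
               x = sm$x[i1, 1], y = sm$y[i1, 1],
               state = majorityLabel(lab[i]))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$particle_id, out$burst), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pool states pairwise for pair-correlation analysis
#'
#' Trajectory counts per state are often too small for a stable g(r), so
#' states adjacent in diffusivity are pooled: {1,2}, {3,4}, {5,6}, {7,8};
#' an odd K leaves the last state alone. Point counts are conserved.
#'
#' @param points data.frame with a `state` column (from
#'   [firstPositions()]).
#' @param K number of states (default `max(points$state)`).
#' @return the input with a `group` factor column (labels like `"1+2"`).
#' @export
poolStatePairs <- function(points, K = NULL) {
  if (is.null(K)) K <- max(points$state, 1L)
  gidx <- (seq_len(K) + 1L) %/% 2L
  lab <- vapply(seq_len(max(gidx)), function(g) {
    s <- which(gidx == g)
    paste(s, collapse = "+")
  }, character(1))
  points$group <- factor(lab[gidx[points$state]], levels = lab)
  points
}

#' Pair correlation function with Monte-Carlo CSR normalization
#'
#' Estimates g(r) of a planar point pattern inside a mask as the ratio of
#' the observed pair-count histogram to the pair-count histogram of a
#' complete-spatial-randomness (CSR) sample in the same mask, each
#' normalized by its own number of point pairs:
#' \deqn{g(r) = \frac{OO(r) / \binom{n_o}{2}}{RR(r) / \binom{n_r}{2}}.}
#' Because the CSR reference is measured with the same estimator in the
#' same mask, edge effects and mask geometry cancel; g = 1 for CSR, g > 1
#' at short r indicates clustering. Bins with no reference pairs are marked
#' invalid.
#'
#' @param points data.frame (or two-column matrix) of coordinates, um.
#' @param mask the [RegionMask-class] containing the points.
#' @param rEdges increasing annulus edges, um (default 0 to 5 um in 50 nm
#'   bins).
#' @param refFactor CSR reference sample size as a multiple of the number
#'   of points (default 20).
#' @param group label stored on the curve.
#' @param seed RNG seed of the CSR reference.
#' @return a [GrCurve-class].
#' @export
pairCorrelation <- function(points, mask, rEdges = seq(0, 5, by = 0.05),
                            refFactor = 20, group = "all", seed = 1L) {
  xy <- asXY(points)
  assertThat(nrow(xy) >= 2L, "need at least 2 points")
  assertThat(all(diff(rEdges) > 0), "rEdges must be increasing")
  inside <- maskContains(mask, xy)
  xy <- xy[inside, , drop = FALSE]
  assertThat(nrow(xy) >= 2L, "need at least 2 points inside the mask")
  nO <- nrow(xy)
  oo <- pairCountHist(xy[, 1], xy[, 2], rEdges)

  nR <- ceiling(refFactor * nO)
  ref <- withSeed(seed, maskSample(mask, nR))
  rr <- pairCountHist(ref[, 1], ref[, 2], rEdges)

  pairsO <- nO * (nO - 1) / 2
  pairsR <- nR * (nR - 1) / 2
  valid <- rr > 0
  g <- rep(NA_real_, length(oo))
  g[valid] <- (oo[valid] / pairsO) / (rr[valid] / pairsR)
  centers <- (rEdges[-1] + rEdges[-length(rEdges)]) / 2
  new("GrCurve", r = centers, g = g, nPairs = as.numeric(oo), valid = valid,
      group = group)
}

#' Pair correlation per pooled state group
#'
#' Convenience wrapper: [firstPositions()] + [poolStatePairs()] +
#' [pairCorrelation()] per group.
#'
#' @inheritParams firstPositions
#' @inheritParams pairCorrelation
#' @param minPoints groups with fewer points are skipped.
#' @return named list of [GrCurve-class], one per state group.
#' @export
statePairCorrelation <- function(segset, labels, mask,
                                 rEdges = seq(0, 5, by = 0.05),
                                 refFactor = 20, minPoints = 10L, seed = 1L) {
  pts <- poolStatePairs(firstPositions(segset, labels))
  out <- list()
  for (g in levels(pts$group)) {
    sub <- pts[pts$group == g, , drop = FALSE]
    if (nrow(sub) < minPoints) next
    out[[g]] <- pairCorrelation(sub[, c("x", "y")], mask, rEdges = rEdges,
                                refFactor = refFactor, group = g, seed = seed)
  }
  out
}
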