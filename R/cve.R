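# Covariance-based diffusivity estimation (CVE), ensemble MSD, and
# distribution comparisons.

#' Covariance-based diffusivity estimate per segment
#'
#' For each trajectory (segment) with displacements `d_n` along one axis,
#' the unbiased covariance-based estimator is
#' \deqn{\hat D = \mathrm{mean}(d_n^2)/(2\Delta t) +
#'       \mathrm{mean}(d_n d_{n+1})/\Delta t}
#' \deqn{\hat\sigma^2 = R\,\mathrm{mean}(d_n^2) +
#'       (2R - 1)\,\mathrm{mean}(d_n d_{n+1})}
#' with frame interval `dt` and motion-blur coefficient `R` (1/6 for
#' full-frame uniform exposure). The reported values average the x and y
#' axes. The estimator is unbiased under localization noise and motion blur
#' and needs no regression, which makes it suitable for short tracks;
#' unbiasedness requires that negative estimates be returned, not clipped.
#'
#' @param x a [SegmentSet-class] (one estimate per segment) or a
#'   [TrackSet-class] (one estimate per track; every track needs at least 3
#'   positions).
#' @param dt frame interval, s; defaults to the object's.
#' @param R motion-blur coefficient (default 1/6).
#' @return data.frame with columns `segment_id` (or `particle_id`),
#'   `burst`, `D` (um^2/s, possibly negative) and `sigma2` (um^2).
#' @export
cveDiffusivity <- function(x, dt = NULL, R = 1 / 6) {
  if (is(x, "SegmentSet")) {
    if (is.null(dt)) dt <- x@frameInterval
    assertThat(x@segLength >= 3L, "segments need at least 3 positions")
    sm <- segmentMatrices(x)
    dx <- t(diff(t(sm$x)))
    dy <- t(diff(t(sm$y)))
    est <- cveFromDisp(dx, dy, dt, R)
    data.frame(segment_id = sm$meta$segment_id, burst = sm$meta$burst,
               D = est$D, sigma2 = est$sigma2)
  } else if (is(x, "TrackSet")) {
    if (is.null(dt)) dt <- x@frameInterval
    tr <- x@tracks[order(x@tracks$particle_id, x@tracks$frame), , drop = FALSE]
    sp <- split(tr, tr$particle_id)
    bad <- vapply(sp, nrow, integer(1)) < 3L
    if (any(bad)) stop("track(s) with fewer than 3 positions: ",
                       paste(names(sp)[bad], collapse = ", "))
    out <- lapply(sp, function(d) {
      est <- cveFromDisp(matrix(diff(d$x), 1), matrix(diff(d$y), 1), dt, R)
      data.frame(particle_id = d$particle_id[1], burst = d$burst[1],
                 D = est$D, sigma2 = est$sigma2)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  } else stop("x must be a SegmentSet or TrackSet")
}

# Row-wise CVE from displacement matrices (rows = segments).
cveFromDisp <- function(dx, dy, dt, R) {
  m2 <- (rowMeans(dx^2) + rowMeans(dy^2)) / 2
  nc <- ncol(dx)
  m1 <- (rowMeans(dx[, -1, drop = FALSE] * dx[, -nc, drop = FALSE]) +
         rowMeans(dy[, -1, drop = FALSE] * dy[, -nc, drop = FALSE])) / 2
  list(D = m2 / (2 * dt) + m1 / dt,
       sigma2 = R * m2 + (2 * R - 1) * m1)
}

#' Ensemble mean-square displacement
#'
#' MSD(n) averaged over all particles and all start frames:
#' `MSD(n) = mean over (i, t) of |r_i(t + n) - r_i(t)|^2`. For a single
#' diffusive state with diffusivity D, localization noise sigma and blur
#' coefficient R the expectation is `4 D n dt + 4 sigma^2 - 8 R D dt`.
#'
#' @param x a [TrackSet-class] or [SegmentSet-class].
#' @param maxLag largest lag in frames; truncated with a warning if it
#'   reaches the longest track.
#' @param group label stored on the curve.
#' @return an [MsdCurve-class]; pair counts per lag are reported and
#'   decrease with lag.
#' @export
ensembleMSD <- function(x, maxLag = 10L, group = "all") {
  if (is(x, "SegmentSet")) {
    sm <- segmentMatrices(x)
    coords <- lapply(seq_len(nrow(sm$x)),
                     function(i) cbind(sm$x[i, ], sm$y[i, ]))
  } else {
    tr <- x@tracks[order(x@tracks$particle_id, x@tracks$frame), , drop = FALSE]
    coords <- lapply(split(seq_len(nrow(tr)), tr$particle_id),
                     function(i) cbind(tr$x[i], tr$y[i]))
  }
  maxAvail <- max(vapply(coords, nrow, integer(1))) - 1L
  if (maxLag > maxAvail) {
    warning("maxLag truncated to ", maxAvail, " (longest track)")
    maxLag <- maxAvail
  }
  lags <- seq_len(maxLag)
  msd <- numeric(maxLag)
  np <- numeric(maxLag)
  for (n in lags) {
    acc <- 0; cnt <- 0
    for (p in coords) {
      L <- nrow(p)
      if (L <= n) next
      d <- (p[(n + 1):L, 1] - p[1:(L - n), 1])^2 +
           (p[(n + 1):L, 2] - p[1:(L - n), 2])^2
      acc <- acc + sum(d)
      cnt <- cnt + length(d)
    }
    msd[n] <- if (cnt) acc / cnt else NA_real_
    np[n] <- cnt
  }
  new("MsdCurve", lag = lags, msd = msd, nPairs = np, group = group)
}

#' Compare diffusivity distributions by subsampled Kruskal-Wallis tests
#'
#' The Kruskal-Wallis test applied to large track ensembles yields
#' vanishingly small p-values for irrelevant differences, so the test is
#' performed on seeded random subsets of each group and the median p over
#' the draws is reported together with the draw-wise spread. Subsets are
#' drawn with a per-draw seed shared across groups, so comparing a group
#' against an identical copy of itself gives p = 1 for every draw.
#'
#' @param groups named list of numeric vectors (e.g. per-condition `D`
#'   estimates), each of length >= `subsetSize`.
#' @param subsetSize subset size per group and draw (default 200).
#' @param nDraws number of seeded draws.
#' @param seed RNG seed.
#' @return list with `p` (median p), `draws` (p per draw) and `spread`
#'   (IQR of the draws).
#' @export
compareDiffusivities <- function(groups, subsetSize = 200L, nDraws = 50L,
                                 seed = 1L) {
  assertThat(length(groups) >= 2L, "need at least two groups")
  ns <- vapply(groups, length, integer(1))
  assertThat(all(ns >= subsetSize),
             "every group must have at least subsetSize values")
  ps <- vapply(seq_len(nDraws), function(d) {
    sub <- lapply(groups, function(g) {
      withSeed(seed + d, g[sample.int(length(g), subsetSize)])
    })
    vals <- unlist(sub, use.names = FALSE)
    fac <- factor(rep(seq_along(sub), each = subsetSize))
    if (length(unique(vals)) == 1L) {
      warning("degenerate draw: all values tied; p = 1")
      return(1)
    }
    kw <- kruskal.test(vals, fac)
    p <- kw$p.value
    if (is.nan(p)) 1 else p
  }, numeric(1))
  list(p = median(ps), draws = ps, spread = stats::IQR(ps))
}
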