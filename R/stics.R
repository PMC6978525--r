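# STICS velocimetry and directional-coherence statistics.

#' Remove the immobile image component
#'
#' Subtracts from every pixel its moving average over a `window`-frame
#' temporal neighborhood (default 20 frames), suppressing static structure
#' before correlation analysis; output interior frames of a static stack
#' are exactly zero, and adding a constant offset to the input leaves the
#' output unchanged. `method = "fourier"` instead removes the temporal DC
#' component (the per-pixel mean over the whole stack).
#'
#' @param stack an image stack (see [imageStack()]).
#' @param window moving-average length, frames.
#' @param method `"moving"` or `"fourier"`.
#' @return the filtered stack (same dimensions and metadata).
#' @export
immobileFilter <- function(stack, window = 20L, method = c("moving", "fourier")) {
  method <- match.arg(method)
  nt <- dim(stack)[3]
  assertThat(window <= nt, "immobile-filter window exceeds the stack length")
  out <- stack
  if (method == "fourier") {
    mu <- apply(stack, c(1, 2), mean)
    for (t in seq_len(nt)) out[, , t] <- stack[, , t] - mu
  } else {
    half <- window %/% 2L
    # cumulative sum along time for O(1) window means
    cs <- array(0, dim = dim(stack) + c(0, 0, 1))
    for (t in seq_len(nt)) cs[, , t + 1] <- cs[, , t] + stack[, , t]
    for (t in seq_len(nt)) {
      lo <- max(1L, t - half)
      hi <- min(nt, lo + window - 1L)
      lo <- max(1L, hi - window + 1L)
      mu <- (cs[, , hi + 1] - cs[, , lo]) / (hi - lo + 1)
      out[, , t] <- stack[, , t] - mu
    }
  }
  attributes(out) <- attributes(stack)
  out
}

#' STICS velocity field
#'
#' Spatio-temporal image correlation spectroscopy: the stack is tiled into
#' `sub` x `sub` pixel subregions shifted by `subShift` pixels, and time
#' into windows of `toi` frames shifted by `toiShift` frames. Within each
#' (subregion, window), the spatial cross-correlation of frame pairs
#' `tau` frames apart is averaged for `tau = 0..maxLag`; the correlation
#' peak of each lag is localized to sub-pixel precision by a least-squares
#' Gaussian fit around the discrete maximum, and the local velocity is the
#' slope of a least-squares line through peak displacement versus lag time.
#'
#' Vectors are marked invalid when the peak displacement exceeds half the
#' subregion, the peak fit fails, or the lag-1 correlation amplitude is
#' below `ampFactor` times the median-absolute-deviation floor of the
#' correlation plane.
#'
#' @param stack an (immobile-filtered) image stack.
#' @param sub subregion size in pixels (default 8).
#' @param subShift shift between subregions in pixels (default 2).
#' @param toi time-of-interest length in frames (default 5).
#' @param toiShift shift between TOIs in frames (default 3).
#' @param maxLag largest correlation lag in frames (default `toi - 1`).
#' @param mask optional [RegionMask-class]; subregions whose center falls
#'   outside are skipped.
#' @param ampFactor quality-control amplitude factor (default 2).
#' @param maxStep largest expected flow displacement per frame, pixels
#'   (default 2 = a quarter subregion); bounds the lag-1 peak search and
#'   the per-lag tracking radius.
#' @return a [VelocityField-class] with speeds in um/min.
#' @export
sticsVelocity <- function(stack, sub = 8L, subShift = 2L, toi = 5L,
                          toiShift = 3L, maxLag = NULL, mask = NULL,
                          ampFactor = 2, maxStep = 2) {
  ps <- stackPixelSize(stack)
  dt <- stackFrameInterval(stack)
  ny <- dim(stack)[1]; nx <- dim(stack)[2]; nt <- dim(stack)[3]
  if (is.null(maxLag)) maxLag <- max(1L, toi - 1L)
  assertThat(maxLag < toi, "maxLag must be smaller than the TOI length")
  if (toi > nt) {
    warning("TOI exceeds the stack length; no windows")
    return(emptyVelocityField(ps, dt, sub, toi))
  }
  i0s <- seq(1L, ny - sub + 1L, by = subShift)
  j0s <- seq(1L, nx - sub + 1L, by = subShift)
  t0s <- seq(1L, nt - toi + 1L, by = toiShift)
  taus <- 0:maxLag

  rows <- list()
  ri <- 0L
  for (wi in seq_along(t0s)) {
    t0 <- t0s[wi]
    for (i0 in i0s) {
      for (j0 in j0s) {
        cx <- (j0 - 1 + sub / 2) * ps
        cy <- (i0 - 1 + sub / 2) * ps
        if (!is.null(mask) && !maskContains(mask, cbind(cx, cy))) next
        # per-frame windowed FFTs, zero-padded to 2*sub so the correlation
        # is linear (no wrap-around); overlap-normalized below.
        pad <- 2L * sub
        W <- lapply(0:(toi - 1L), function(dtau) {
          w <- stack[i0:(i0 + sub - 1L), j0:(j0 + sub - 1L), t0 + dtau]
          wp <- matrix(0, pad, pad)
          wp[seq_len(sub), seq_len(sub)] <- w - mean(w)
          fft(wp)
        })
        lagCoord <- ifelse(seq_len(pad) - 1 > pad / 2,
                           seq_len(pad) - 1 - pad, seq_len(pad) - 1)
        overlap <- outer(pmax(sub - abs(lagCoord), 1),
                         pmax(sub - abs(lagCoord), 1))
        shifts <- matrix(NA_real_, length(taus), 2)
        ampOK <- TRUE; fitOK <- TRUE
        for (ti in seq_along(taus)) {
          tau <- taus[ti]
          planeF <- 0
          npair <- 0L
          for (a in seq_len(toi - tau)) {
            planeF <- planeF + Conj(W[[a]]) * W[[a + tau]]
            npair <- npair + 1L
          }
          plane <- Re(fft(planeF, inverse = TRUE)) /
            (length(planeF) * npair) / overlap
          # track the peak: for tau >= 2, search near the position
          # extrapolated from the previous lag, else the full half-window
          centre <- if (tau >= 2L && !anyNA(shifts[ti - 1L, ]))
            shifts[ti - 1L, ] * tau / (tau - 1) else c(0, 0)
          radius <- if (tau >= 2L) 2 else if (tau == 1L) maxStep else sub / 2
          pk <- corrPeak(plane, maxShift = sub / 2, centre = centre,
                         radius = radius)
          if (is.null(pk)) { fitOK <- FALSE; break }
          shifts[ti, ] <- c(pk$dx, pk$dy)
          if (tau == 1L &&
              pk$value < ampFactor * mad(plane, center = median(plane)))
            ampOK <- FALSE
        }
        valid <- fitOK && ampOK &&
          all(abs(shifts) <= sub / 2, na.rm = TRUE) &&
          !anyNA(shifts)
        if (valid) {
          tt <- taus * dt
          sl <- function(d) sum((tt - mean(tt)) * (d - mean(d))) /
            sum((tt - mean(tt))^2)
          vx <- sl(shifts[, 1]) * ps * 60   # um/min
          vy <- sl(shifts[, 2]) * ps * 60
          speed <- sqrt(vx^2 + vy^2)
        } else vx <- vy <- speed <- NA_real_
        ri <- ri + 1L
        rows[[ri]] <- data.frame(x = cx, y = cy, window = wi,
                                 tmid = (t0 - 1 + (toi - 1) / 2) * dt,
                                 vx = vx, vy = vy, speed = speed,
                                 valid = valid)
      }
    }
  }
  vecs <- if (length(rows)) do.call(rbind, rows) else
    emptyVelocityField(ps, dt, sub, toi)@vectors
  new("VelocityField", vectors = vecs, pixelSize = ps, frameInterval = dt,
      sub = as.integer(sub), toi = as.integer(toi))
}

emptyVelocityField <- function(ps, dt, sub, toi)
  new("VelocityField",
      vectors = data.frame(x = numeric(), y = numeric(), window = integer(),
                           tmid = numeric(), vx = numeric(), vy = numeric(),
                           speed = numeric(), valid = logical()),
      pixelSize = ps, frameInterval = dt, sub = as.integer(sub),
      toi = as.integer(toi))

# Sub-pixel peak of a correlation plane (FFT layout, index 1 = lag 0):
# discrete maximum within |lag| <= maxShift, refined by a least-squares
# Gaussian fit (quadratic in log-correlation) over a 5x5 neighborhood,
# falling back to three-point Gaussian interpolation per axis. Returns the
# displacement (dx, dy) in pixels (x = columns, y = rows) and the peak
# value, or NULL on failure.
corrPeak <- function(plane, maxShift = nrow(plane) / 2, centre = c(0, 0),
                     radius = maxShift) {
  n <- nrow(plane)
  # lag coordinates: index 1 -> 0, index k -> k-1 wrapped to [-n/2, n/2)
  coord <- function(idx) ifelse(idx - 1 > n / 2, idx - 1 - n, idx - 1)
  lagc <- coord(seq_len(n))
  search <- plane
  farx <- abs(lagc) > maxShift | abs(lagc - centre[1]) > radius
  fary <- abs(lagc) > maxShift | abs(lagc - centre[2]) > radius
  search[fary, ] <- -Inf
  search[, farx] <- -Inf
  if (all(!is.finite(search))) return(NULL)
  pk <- which(search == max(search), arr.ind = TRUE)[1, ]
  peakVal <- plane[pk[1], pk[2]]
  if (!is.finite(peakVal)) return(NULL)

  # Gaussian apex interpolation per axis (the exact least-squares Gaussian
  # through the peak and its two axis neighbors); a 5x5 least-squares
  # Gaussian surface fit is the fallback when a neighbor is non-positive.
  gx <- gauss3(plane[pk[1], ((pk[2] - 2) %% n) + 1],
               peakVal, plane[pk[1], (pk[2] %% n) + 1])
  gy <- gauss3(plane[((pk[1] - 2) %% n) + 1, pk[2]],
               peakVal, plane[(pk[1] %% n) + 1, pk[2]])
  if (is.na(gx) || is.na(gy)) {
    idx5 <- -2:2
    rows5 <- ((pk[1] - 1 + idx5) %% n) + 1
    cols5 <- ((pk[2] - 1 + idx5) %% n) + 1
    fit <- gaussPeak2d(plane[rows5, cols5])
    if (is.null(fit))
      fit <- list(dx = if (is.na(gx)) 0 else gx,
                  dy = if (is.na(gy)) 0 else gy)
  } else fit <- list(dx = gx, dy = gy)
  if (abs(fit$dx) > 2.5 || abs(fit$dy) > 2.5) return(NULL)
  list(dx = coord(pk[2]) + fit$dx, dy = coord(pk[1]) + fit$dy,
       value = peakVal)
}

# Least-squares Gaussian fit on a 5x5 neighborhood: weighted quadratic fit
# to log-correlation (weights = correlation^2 so bright pixels dominate).
# Returns the sub-pixel offset of the apex from the center pixel, or NULL
# when the surface is not concave.
gaussPeak2d <- function(nb) {
  xs <- rep(-2:2, each = 5)   # column offset
  ys <- rep(-2:2, times = 5)  # row offset
  v <- as.vector(nb)
  ok <- v > 0
  if (sum(ok) < 6) return(NULL)
  w <- v[ok]^2
  X <- cbind(1, xs[ok], ys[ok], xs[ok]^2, ys[ok]^2, xs[ok] * ys[ok])
  fit <- try(stats::lm.wfit(X, log(v[ok]), w), silent = TRUE)
  if (inherits(fit, "try-error") || anyNA(fit$coefficients)) return(NULL)
  cf <- fit$coefficients
  H <- matrix(c(2 * cf[4], cf[6], cf[6], 2 * cf[5]), 2)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev >= 0)) return(NULL)            # not a concave apex
  apex <- -solve(H, c(cf[2], cf[3]))
  list(dx = apex[1], dy = apex[2])
}

gauss3 <- function(cm, c0, cp) {
  if (cm <= 0 || c0 <= 0 || cp <= 0) return(NA_real_)
  den <- 2 * (log(cm) - 2 * log(c0) + log(cp))
  if (den >= 0) return(NA_real_)
  (log(cm) - log(cp)) / den
}

#' Directional coherence of a velocity field
#'
#' For every valid vector, the cosine of the angle between the flow vector
#' and the direction from the vector's position to the cell centroid:
#' +1 = flow straight towards the centroid (inward), -1 = straight away
#' (outward). Zero-length vectors are excluded. The inward and outward
#' fractions use `threshold` (default 0.9).
#'
#' @param field a [VelocityField-class].
#' @param centroid cell centroid, um.
#' @param threshold coherence cutoff for the inward/outward fractions.
#' @return a [CoherenceResult-class].
#' @export
directionalCoherence <- function(field, centroid, threshold = 0.9) {
  v <- field@vectors
  v <- v[v$valid & is.finite(v$speed) & v$speed > 0, , drop = FALSE]
  tox <- centroid[1] - v$x
  toy <- centroid[2] - v$y
  nv <- sqrt(v$vx^2 + v$vy^2)
  nt <- sqrt(tox^2 + toy^2)
  keep <- nv > 0 & nt > 0
  cval <- ((v$vx * tox + v$vy * toy) / (nv * nt))[keep]
  cval <- pmin(1, pmax(-1, cval))
  n <- length(cval)
  new("CoherenceResult", values = cval,
      inwardFraction = if (n) mean(cval > threshold) else 0,
      outwardFraction = if (n) mean(cval < -threshold) else 0,
      threshold = threshold, n = as.integer(n))
}

#' Two-proportion z-test for flow fractions
#'
#' Pooled two-proportion z-test of the null hypothesis that two flow
#' fractions (e.g. inward-flow fractions of two conditions) are equal;
#' two-sided p. When the pooled variance is zero (both fractions 0 or
#' both 1), p = 1 is returned with `degenerate = TRUE`.
#'
#' @param fractionA,nA fraction and number of vectors in condition A.
#' @param fractionB,nB same for condition B.
#' @return list with `z`, `p`, and `degenerate`.
#' @export
compareFlowFractions <- function(fractionA, nA, fractionB, nB) {
  assertThat(nA >= 1 && nB >= 1, "counts must be >= 1")
  xA <- fractionA * nA
  xB <- fractionB * nB
  pool <- (xA + xB) / (nA + nB)
  se <- sqrt(pool * (1 - pool) * (1 / nA + 1 / nB))
  if (se == 0) return(list(z = 0, p = 1, degenerate = TRUE))
  z <- (fractionA - fractionB) / se
  list(z = z, p = 2 * pnorm(-abs(z)), degenerate = FALSE)
}
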