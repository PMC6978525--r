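# Single-molecule spot detection: local maxima + least-squares 2-D Gaussian
# refinement, yielding sub-pixel positions in physical units.

#' Detect single-molecule spots in one frame
#'
#' Candidate spots are local maxima whose background-subtracted intensity
#' exceeds `threshold`; each candidate is refined by a least-squares fit of
#' a 2-D Gaussian plus constant offset on a small window around the maximum.
#' Detections outside the supplied cell mask are discarded.
#'
#' @param frame numeric matrix (one image frame).
#' @param threshold minimum peak height above the median background, counts.
#' @param psfSigma PSF sigma guess, um (sets the fit window and initializes
#'   the fit).
#' @param pixelSize um/pixel.
#' @param mask optional [RegionMask-class]; detections outside it are
#'   dropped.
#' @return data.frame with columns `x`, `y` (um), `amplitude`, `fit_sigma`
#'   (um) and `fit_ok`. A flat or saturated frame yields zero rows with a
#'   warning.
#' @export
detectSpots <- function(frame, threshold, psfSigma = 0.15, pixelSize = 0.1,
                        mask = NULL) {
  stopifnot(is.matrix(frame))
  if (diff(range(frame)) == 0) {
    warning("flat frame: no detections")
    return(emptyLocs())
  }
  bg <- median(frame)
  ny <- nrow(frame); nx <- ncol(frame)
  half <- max(3L, ceiling(2.5 * psfSigma / pixelSize))

  # strict local maxima over the 8-neighborhood, above threshold
  pk <- frame >= bg + threshold
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    shifted <- matrix(-Inf, ny, nx)
    ri <- max(1, 1 + di):min(ny, ny + di)
    rj <- max(1, 1 + dj):min(nx, nx + dj)
    shifted[ri, rj] <- frame[ri - di, rj - dj]
    pk <- pk & (frame > shifted | (frame == shifted & (di > 0 | (di == 0 & dj > 0))))
  }
  idx <- which(pk, arr.ind = TRUE)
  if (!nrow(idx)) return(emptyLocs())
  idx <- idx[idx[, 1] > half & idx[, 1] <= ny - half &
             idx[, 2] > half & idx[, 2] <= nx - half, , drop = FALSE]
  if (!nrow(idx)) return(emptyLocs())

  res <- lapply(seq_len(nrow(idx)), function(i) {
    ic <- idx[i, 1]; jc <- idx[i, 2]
    win <- frame[(ic - half):(ic + half), (jc - half):(jc + half)]
    fit <- fitGaussian2d(win, sigmaPx = psfSigma / pixelSize)
    # window (row 1, col 1) corresponds to pixel (ic - half, jc - half)
    data.frame(x = (jc - half - 1 + fit$x0) * pixelSize,
               y = (ic - half - 1 + fit$y0) * pixelSize,
               amplitude = fit$A, fit_sigma = fit$sigma * pixelSize,
               fit_ok = fit$ok)
  })
  out <- do.call(rbind, res)
  if (!is.null(mask)) out <- out[maskContains(mask, out), , drop = FALSE]
  # noise can split one molecule into two nearby maxima: keep only the
  # brighter of any pair of detections closer than 2 * psfSigma
  if (nrow(out) > 1L) {
    o <- order(-out$amplitude)
    out <- out[o, , drop = FALSE]
    keep <- rep(TRUE, nrow(out))
    minSep2 <- (2 * psfSigma)^2
    for (i in seq_len(nrow(out))[-1]) {
      d2 <- (out$x[seq_len(i - 1)] - out$x[i])^2 +
            (out$y[seq_len(i - 1)] - out$y[i])^2
      if (any(d2[keep[seq_len(i - 1)]] < minSep2)) keep[i] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
    out <- out[order(out$y, out$x), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

emptyLocs <- function()
  data.frame(x = numeric(), y = numeric(), amplitude = numeric(),
             fit_sigma = numeric(), fit_ok = logical())

# Least-squares fit of A * G(x0, y0, sigma) + B on a square window.
# Positions are in pixel units relative to the window: the center of
# window pixel (row i, col j) is (j - 0.5, i - 0.5).
fitGaussian2d <- function(win, sigmaPx) {
  n <- nrow(win)
  # the candidate maximum sits at the window center by construction, which
  # anchors the start; amplitude from the peak height over the central-pixel
  # mass of a Gaussian with the guessed sigma
  x0 <- n / 2
  y0 <- n / 2
  B0 <- median(win)
  centralMass <- (pnorm(0.5 / sigmaPx) - pnorm(-0.5 / sigmaPx))^2
  A0 <- max(win[ceiling(n / 2), ceiling(n / 2)] - B0, 1e-3) / centralMass
  edges <- seq_len(n)   # pixel j spans [j - 1, j]
  obj <- function(p) {
    s <- exp(p[4])
    ex <- pnorm((edges - p[1]) / s) - pnorm((edges - 1 - p[1]) / s)
    ey <- pnorm((edges - p[2]) / s) - pnorm((edges - 1 - p[2]) / s)
    model <- p[3] * outer(ey, ex) + p[5]
    sum((model - win)^2)
  }
  obj0 <- obj(c(x0, y0, A0, log(sigmaPx), B0))
  fit <- try(optim(c(x0, y0, A0, log(sigmaPx), B0), obj,
                   method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-10)),
             silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(x0 = x0, y0 = y0, A = A0, sigma = sigmaPx, ok = FALSE))
  p <- fit$par
  s <- exp(p[4])
  # sub-quarter-pixel or window-wide "PSFs" are noise artifacts, not
  # molecules; a maxed-out iteration count is accepted if the fit improved
  ok <- p[1] > 0 && p[1] < n && p[2] > 0 && p[2] < n &&
    p[3] > 0 && is.finite(s) && s > 0.25 && s < n && fit$value < obj0
  list(x0 = p[1], y0 = p[2], A = p[3], sigma = s, ok = ok)
}

#' Detect spots in every frame of a stack
#'
#' @param stack an image stack (see [imageStack()]).
#' @inheritParams detectSpots
#' @return data.frame of localizations with a `frame` column.
#' @export
detectStack <- function(stack, threshold, psfSigma = 0.15, mask = NULL) {
  ps <- stackPixelSize(stack)
  out <- lapply(seq_len(dim(stack)[3]), function(f) {
    d <- suppressWarnings(detectSpots(stack[, , f], threshold, psfSigma,
                                      pixelSize = ps, mask = mask))
    if (nrow(d)) cbind(frame = f, d) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- cbind(frame = integer(), emptyLocs())
  out
}
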