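# Image stacks: in-memory representation, TIFF I/O, spot-movie rendering and
# advected speckle (flow) movies.
#
# A stack is a numeric array [ny, nx, nframes] with attributes `pixelSize`
# (um/pixel) and `frameInterval` (s). Pixel (row i, col j) covers the square
# centered at x = (j - 0.5) * pixelSize, y = (i - 0.5) * pixelSize.

#' Create an image stack
#'
#' @param data numeric array `[ny, nx, nframes]` (a matrix is treated as a
#'   single frame).
#' @param pixelSize um/pixel.
#' @param frameInterval seconds/frame.
#' @return the array with `pixelSize` / `frameInterval` attributes set.
#' @export
imageStack <- function(data, pixelSize, frameInterval) {
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 3L, pixelSize > 0, frameInterval > 0)
  attr(data, "pixelSize") <- pixelSize
  attr(data, "frameInterval") <- frameInterval
  data
}

#' @rdname imageStack
#' @param stack an image stack.
#' @export
stackPixelSize <- function(stack) attr(stack, "pixelSize")

#' @rdname imageStack
#' @export
stackFrameInterval <- function(stack) attr(stack, "frameInterval")

#' Read/write image stacks as multi-page TIFF
#'
#' Stacks are stored as 32-bit float multi-page TIFF, rescaled to \[0, 1\];
#' the scale factor, pixel size and frame interval travel in a JSON sidecar
#' (`<path>.meta.json`) so that `readImageStack(writeImageStack(x))` is an
#' identity up to float precision.
#'
#' @param stack an image stack (see [imageStack()]).
#' @param path TIFF file path.
#' @return `readImageStack`: the stack; `writeImageStack`: `path`,
#'   invisibly.
#' @export
writeImageStack <- function(stack, path) {
  rng <- range(stack)
  scale <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
  frames <- lapply(seq_len(dim(stack)[3]), function(i)
    (stack[, , i] - rng[1]) / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  meta <- list(pixel_size_um = stackPixelSize(stack),
               frame_interval_s = stackFrameInterval(stack),
               offset = rng[1], scale = scale)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeImageStack
#' @export
readImageStack <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  a <- array(unlist(frames), dim = c(dim(frames[[1]]), length(frames)))
  metaPath <- paste0(path, ".meta.json")
  if (file.exists(metaPath)) {
    meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
    a <- a * meta$scale + meta$offset
    imageStack(a, meta$pixel_size_um, meta$frame_interval_s)
  } else imageStack(a, 1, 1)
}

#' Render a single-molecule movie from trajectories
#'
#' Each localization is drawn as an integrated 2-D Gaussian (the PSF
#' integrated over each pixel), scaled by `photonScale`, on a constant
#' `background`. Optional shot noise (Poisson on the expected counts) plus
#' Gaussian read noise.
#'
#' @param tracks a [TrackSet-class] (single burst).
#' @param psfSigma PSF standard deviation, um.
#' @param photonScale expected photons per molecule per frame.
#' @param background expected background counts per pixel.
#' @param noiseModel `"none"` or `"poisson+gaussian"`.
#' @param readSd Gaussian read-noise SD (counts), for
#'   `noiseModel = "poisson+gaussian"`.
#' @param imageSize `c(ny, nx)` in pixels; default covers the mask bounding
#'   box.
#' @param seed RNG seed for the noise.
#' @return an image stack; frame `t` of the stack corresponds to the `t`-th
#'   distinct frame index present in `tracks` (gaps carry pure background).
#' @export
renderSpotMovie <- function(tracks, psfSigma = 0.15, photonScale = 200,
                            background = 10,
                            noiseModel = c("none", "poisson+gaussian"),
                            readSd = 2, imageSize = NULL, seed = 1L) {
  stopifnot(is(tracks, "TrackSet"))
  noiseModel <- match.arg(noiseModel)
  ps <- tracks@pixelSize
  stopifnot(is.finite(ps), ps > 0, psfSigma > 0)
  tr <- tracks@tracks
  if (is.null(imageSize)) {
    bb <- if (!is.null(tracks@mask)) maskBBox(tracks@mask)
          else list(xlim = c(0, max(tr$x, 1)), ylim = c(0, max(tr$y, 1)))
    imageSize <- c(ceiling(bb$ylim[2] / ps), ceiling(bb$xlim[2] / ps))
  }
  ny <- imageSize[1]; nx <- imageSize[2]
  nFrames <- if (nrow(tr)) max(tr$frame) - min(tr$frame) + 1L else 1L
  f0 <- if (nrow(tr)) min(tr$frame) else 1L
  stack <- array(background, dim = c(ny, nx, nFrames))

  if (nrow(tr)) {
    bad <- tr$x < 0 | tr$x > nx * ps | tr$y < 0 | tr$y > ny * ps
    if (any(bad))
      stop("particle(s) ", paste(unique(tr$particle_id[bad]), collapse = ", "),
           " fall outside the image extent")
    half <- ceiling(4 * psfSigma / ps)
    for (i in seq_len(nrow(tr))) {
      cx <- tr$x[i] / ps          # in pixel units, pixel j spans [j-1, j]
      cy <- tr$y[i] / ps
      jc <- floor(cx) + 1L; ic <- floor(cy) + 1L
      js <- max(1L, jc - half):min(nx, jc + half)
      is <- max(1L, ic - half):min(ny, ic + half)
      ex <- pnorm((js - cx) / (psfSigma / ps)) -
            pnorm((js - 1 - cx) / (psfSigma / ps))
      ey <- pnorm((is - cy) / (psfSigma / ps)) -
            pnorm((is - 1 - cy) / (psfSigma / ps))
      f <- tr$frame[i] - f0 + 1L
      stack[is, js, f] <- stack[is, js, f] + photonScale * outer(ey, ex)
    }
  }
  if (noiseModel == "poisson+gaussian") {
    stack <- withSeed(seed, {
      noisy <- rpois(length(stack), lambda = pmax(stack, 0)) +
        rnorm(length(stack), sd = readSd)
      array(noisy, dim = dim(stack))
    })
  }
  imageStack(stack, ps, tracks@frameInterval)
}

#' Simulate an advected speckle movie with a known velocity field
#'
#' A static random speckle texture (Gaussian-filtered white noise with
#' correlation length `textureGrain`) is advected by a prescribed velocity
#' field using periodic sub-pixel interpolation, plus optional additive
#' Gaussian noise. Ground truth for STICS velocimetry.
#'
#' @param fieldSpec one of `list(type = "uniform", v = c(vx, vy))` (um/s),
#'   `list(type = "radial", speed = s, center = c(x, y))` (speed in um/s;
#'   positive = inward, negative = outward), or `list(type = "zero")`.
#' @param imageSize `c(ny, nx)` pixels.
#' @param nFrames number of frames.
#' @param pixelSize um/pixel.
#' @param frameInterval seconds/frame.
#' @param textureGrain speckle correlation length (Gaussian sigma), um.
#'   The default 0.06 um is the Gaussian sigma of a ~145 nm FWHM point
#'   spread function, i.e. speckles at the resolution limit of deconvolved
#'   live-cell super-resolution imaging.
#' @param amplitude texture contrast (counts).
#' @param noiseSd additive Gaussian noise SD (counts).
#' @param seed RNG seed.
#' @return `list(stack = <image stack>, field = <data.frame>)`; the field
#'   gives the true `vx`, `vy` (um/s) at every pixel center.
#' @export
simulateFlowStack <- function(fieldSpec = list(type = "zero"),
                              imageSize = c(64, 64), nFrames = 20L,
                              pixelSize = 0.1, frameInterval = 2,
                              textureGrain = 0.06, amplitude = 100,
                              noiseSd = 0, seed = 1L) {
  ny <- imageSize[1]; nx <- imageSize[2]
  withSeed(seed, {
    texture <- speckleTexture(ny, nx, textureGrain / pixelSize) * amplitude

    xs <- ((seq_len(nx)) - 0.5) * pixelSize
    ys <- ((seq_len(ny)) - 0.5) * pixelSize
    gx <- matrix(xs, ny, nx, byrow = TRUE)
    gy <- matrix(ys, ny, nx)
    type <- fieldSpec$type
    if (type == "uniform") {
      vx <- matrix(fieldSpec$v[1], ny, nx)
      vy <- matrix(fieldSpec$v[2], ny, nx)
    } else if (type == "radial") {
      ctr <- if (!is.null(fieldSpec$center)) fieldSpec$center
             else c(nx * pixelSize / 2, ny * pixelSize / 2)
      dx <- ctr[1] - gx; dy <- ctr[2] - gy
      r <- pmax(sqrt(dx^2 + dy^2), 1e-12)
      vx <- fieldSpec$speed * dx / r
      vy <- fieldSpec$speed * dy / r
    } else if (type == "zero") {
      vx <- matrix(0, ny, nx); vy <- matrix(0, ny, nx)
    } else stop("unknown field type: ", type)

    maxShift <- max(sqrt(vx^2 + vy^2)) * frameInterval / pixelSize
    if (maxShift > 4) # half of the default 8-px STICS subregion
      warning("flow exceeds half a subregion per frame; STICS will alias")

    stack <- array(0, dim = c(ny, nx, nFrames))
    for (t in seq_len(nFrames)) {
      shiftT <- (t - 1) * frameInterval / pixelSize   # px per (um/s)
      # Semi-Lagrangian backtrace with the frozen local velocity.
      sx <- gx / pixelSize - 0.5 - vx * shiftT        # 0-based px coords
      sy <- gy / pixelSize - 0.5 - vy * shiftT
      stack[, , t] <- bilinearPeriodic(texture, sy, sx)
    }
    if (noiseSd > 0)
      stack <- stack + array(rnorm(length(stack), sd = noiseSd), dim(stack))
    list(stack = imageStack(stack, pixelSize, frameInterval),
         field = data.frame(x = as.vector(gx), y = as.vector(gy),
                            vx = as.vector(vx), vy = as.vector(vy)))
  })
}

# Gaussian-smoothed periodic white noise, unit variance.
speckleTexture <- function(ny, nx, grainPx) {
  w <- matrix(rnorm(ny * nx), ny, nx)
  if (grainPx > 0) {
    fy <- c(0:(ny %/% 2), -((ceiling(ny / 2) - 1):1)) / ny
    fx <- c(0:(nx %/% 2), -((ceiling(nx / 2) - 1):1)) / nx
    H <- exp(-2 * pi^2 * grainPx^2 * outer(fy^2, fx^2, "+"))
    w <- Re(fft(fft(w) * H, inverse = TRUE)) / length(w)
  }
  (w - mean(w)) / sd(w)
}

# Periodic bilinear interpolation at 0-based (row, col) coordinates.
bilinearPeriodic <- function(img, ri, ci) {
  ny <- nrow(img); nx <- ncol(img)
  r0 <- floor(ri); c0 <- floor(ci)
  fr <- ri - r0; fc <- ci - c0
  i0 <- (as.integer(r0) %% ny) + 1L
  i1 <- (as.integer(r0 + 1) %% ny) + 1L
  j0 <- (as.integer(c0) %% nx) + 1L
  j1 <- (as.integer(c0 + 1) %% nx) + 1L
  v <- img[cbind(as.vector(i0), as.vector(j0))] * (1 - fr) * (1 - fc) +
       img[cbind(as.vector(i1), as.vector(j0))] * fr * (1 - fc) +
       img[cbind(as.vector(i0), as.vector(j1))] * (1 - fr) * fc +
       img[cbind(as.vector(i1), as.vector(j1))] * fr * fc
  matrix(v, ny, nx)
}
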