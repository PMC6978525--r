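# Planar region masks: construction, membership, sampling, reflection.

#' Create a disk or rectangle mask
#'
#' Masks stand in for the cell contour: trajectories are confined to them
#' (reflecting boundary), detections outside them are discarded, and the
#' pair-correlation normalization samples uniform points inside them.
#'
#' @param center numeric length 2, disk center in um.
#' @param radius disk radius in um.
#' @return a [RegionMask-class].
#' @examples
#' m <- diskMask(c(5, 5), 5)
#' maskContains(m, cbind(5, 5))
#' @export
diskMask <- function(center = c(5, 5), radius = 5)
  new("RegionMask", shape = "disk", center = as.numeric(center),
      radius = as.numeric(radius), xlim = numeric(), ylim = numeric())

#' @rdname diskMask
#' @param xlim,ylim rectangle extent in um.
#' @export
rectMask <- function(xlim = c(0, 10), ylim = c(0, 10))
  new("RegionMask", shape = "rect", center = numeric(), radius = numeric(),
      xlim = as.numeric(xlim), ylim = as.numeric(ylim))

#' Mask geometry helpers
#'
#' `maskContains` tests points for membership, `maskArea` returns the mask
#' area (um^2), `maskBBox` its bounding box, `maskSample` draws uniform
#' points inside the mask (optionally inset by `margin`), and
#' `maskReflect` folds points back into the (margin-inset) mask, the
#' reflecting-boundary rule used by the simulator.
#'
#' @param mask a [RegionMask-class].
#' @param xy two-column matrix of coordinates (um).
#' @return `maskContains`: logical vector; `maskSample`, `maskReflect`:
#'   two-column matrices; `maskArea`: scalar; `maskBBox`: list with
#'   `xlim`, `ylim`.
#' @export
maskContains <- function(mask, xy) {
  xy <- asXY(xy)
  if (mask@shape == "disk") {
    (xy[, 1] - mask@center[1])^2 + (xy[, 2] - mask@center[2])^2 <= mask@radius^2
  } else {
    xy[, 1] >= mask@xlim[1] & xy[, 1] <= mask@xlim[2] &
      xy[, 2] >= mask@ylim[1] & xy[, 2] <= mask@ylim[2]
  }
}

#' @rdname maskContains
#' @export
maskArea <- function(mask) {
  if (mask@shape == "disk") pi * mask@radius^2
  else diff(mask@xlim) * diff(mask@ylim)
}

#' @rdname maskContains
#' @export
maskBBox <- function(mask) {
  if (mask@shape == "disk")
    list(xlim = mask@center[1] + c(-1, 1) * mask@radius,
         ylim = mask@center[2] + c(-1, 1) * mask@radius)
  else list(xlim = mask@xlim, ylim = mask@ylim)
}

#' @rdname maskContains
#' @param n number of points to draw.
#' @param margin inset from the boundary (um).
#' @export
maskSample <- function(mask, n, margin = 0) {
  if (mask@shape == "disk") {
    r <- (mask@radius - margin) * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    cbind(x = mask@center[1] + r * cos(th), y = mask@center[2] + r * sin(th))
  } else {
    cbind(x = runif(n, mask@xlim[1] + margin, mask@xlim[2] - margin),
          y = runif(n, mask@ylim[1] + margin, mask@ylim[2] - margin))
  }
}

#' @rdname maskContains
#' @export
maskReflect <- function(mask, xy, margin = 0) {
  xy <- asXY(xy)
  if (mask@shape == "disk") {
    reflectDisk(xy, mask@center, mask@radius - margin)
  } else {
    cbind(x = reflectInterval(xy[, 1], mask@xlim[1] + margin, mask@xlim[2] - margin),
          y = reflectInterval(xy[, 2], mask@ylim[1] + margin, mask@ylim[2] - margin))
  }
}

# Radial fold into a disk: r -> 2R - r, iterated for extreme excursions.
reflectDisk <- function(xy, center, radius) {
  dx <- xy[, 1] - center[1]
  dy <- xy[, 2] - center[2]
  r <- sqrt(dx^2 + dy^2)
  out <- which(r > radius)
  while (length(out)) {
    rn <- pmax(2 * radius - r[out], 0)
    scl <- ifelse(r[out] > 0, rn / r[out], 0)
    dx[out] <- dx[out] * scl
    dy[out] <- dy[out] * scl
    r[out] <- rn
    out <- out[rn > radius]
  }
  cbind(x = center[1] + dx, y = center[2] + dy)
}

# Fold a coordinate into [lo, hi] by repeated specular reflection.
reflectInterval <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  y <- ifelse(y > w, 2 * w - y, y)
  lo + y
}

asXY <- function(xy) {
  if (is.data.frame(xy)) xy <- as.matrix(xy[, c("x", "y")])
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  xy
}

setMethod("show", "RegionMask", function(object) {
  if (object@shape == "disk")
    cat(sprintf("RegionMask: disk, center (%.3g, %.3g) um, radius %.3g um\n",
                object@center[1], object@center[2], object@radius))
  else
    cat(sprintf("RegionMask: rectangle, x [%.3g, %.3g] um, y [%.3g, %.3g] um\n",
                object@xlim[1], object@xlim[2], object@ylim[1], object@ylim[2]))
})
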