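# Perturbation-expectation-maximization over diffusive states.
#
# Each 15-frame segment contributes 14 displacements per axis. Under a
# single diffusive state with diffusivity D, localization variance sigma2
# and blur coefficient R, the displacement vector of one axis is zero-mean
# multivariate normal with symmetric tridiagonal-Toeplitz covariance:
#   diagonal       a = 2 D dt - 4 R D dt + 2 sigma2
#   off-diagonal   b = 2 R D dt - sigma2
# Its eigenvalues are lambda_j = a + 2 b cos(j pi / (n+1)) with the discrete
# sine basis as eigenvectors, independent of (a, b) - so each segment is
# sine-transformed once and any state's log-likelihood is a 14-term sum.

#' Model displacement covariance of a diffusive state
#'
#' Returns the n x n covariance matrix of successive one-axis displacements
#' of a Brownian trajectory with diffusivity `D`, localization variance
#' `sigma2`, frame interval `dt` and motion-blur coefficient `R`:
#' tridiagonal Toeplitz with diagonal `2*D*dt - 4*R*D*dt + 2*sigma2` and
#' first off-diagonal `2*R*D*dt - sigma2`.
#'
#' @param D diffusivity, um^2/s.
#' @param sigma2 localization variance, um^2.
#' @param dt frame interval, s.
#' @param R motion-blur coefficient.
#' @param nDisp number of displacements (14 for 15-frame segments).
#' @return the covariance matrix (um^2).
#' @export
displacementCovariance <- function(D, sigma2, dt, R = 1 / 6, nDisp = 14L) {
  ab <- covParams(D, sigma2, dt, R)
  m <- diag(ab$a, nDisp)
  if (nDisp > 1L) {
    ix <- cbind(seq_len(nDisp - 1L), seq_len(nDisp - 1L) + 1L)
    m[ix] <- ab$b
    m[ix[, 2:1, drop = FALSE]] <- ab$b
  }
  m
}

covParams <- function(D, sigma2, dt, R)
  list(a = 2 * D * dt - 4 * R * D * dt + 2 * sigma2,
       b = 2 * R * D * dt - sigma2)

covEigenvalues <- function(D, sigma2, dt, R, nDisp) {
  ab <- covParams(D, sigma2, dt, R)
  ab$a + 2 * ab$b * cos(seq_len(nDisp) * pi / (nDisp + 1))
}

# Orthonormal discrete sine basis; columns are eigenvectors of any
# tridiagonal-Toeplitz matrix of size n.
sineBasis <- function(n) {
  j <- seq_len(n)
  sqrt(2 / (n + 1)) * sin(outer(j, j) * pi / (n + 1))
}

#' Log-likelihood of one segment under a diffusive state
#'
#' Sum over the x and y axes of the zero-mean multivariate normal
#' log-density of the displacement vectors, with the covariance of
#' [displacementCovariance()]. Returns `-Inf` (with a diagnostic attribute)
#' when the covariance is not positive-definite.
#'
#' @param dx,dy displacement vectors of the two axes (equal length).
#' @inheritParams displacementCovariance
#' @return scalar log-likelihood.
#' @export
segmentLogLik <- function(dx, dy, D, sigma2, dt, R = 1 / 6) {
  n <- length(dx)
  stopifnot(length(dy) == n)
  lam <- covEigenvalues(D, sigma2, dt, R, n)
  if (any(lam <= 0)) {
    out <- -Inf
    attr(out, "reason") <- "covariance not positive-definite"
    return(out)
  }
  U <- sineBasis(n)
  zx <- drop(crossprod(U, dx))
  zy <- drop(crossprod(U, dy))
  -sum(log(2 * pi * lam)) - 0.5 * sum((zx^2 + zy^2) / lam)
}

# Sufficient statistics of a segment set for the EM:
#  S     nseg x nDisp matrix of sine-transformed squared displacements
#        (x and y summed),
#  m2/m1 per-segment mean squared displacement and mean lag-1 product
#        (axes averaged), used for moment-based M-step starts.
pemStats <- function(segset, dt = NULL) {
  sm <- segmentMatrices(segset)
  dx <- t(diff(t(sm$x)))
  dy <- t(diff(t(sm$y)))
  n <- ncol(dx)
  U <- sineBasis(n)
  Zx <- dx %*% U
  Zy <- dy %*% U
  m2 <- (rowMeans(dx^2) + rowMeans(dy^2)) / 2
  m1 <- (rowMeans(dx[, -1, drop = FALSE] * dx[, -n, drop = FALSE]) +
         rowMeans(dy[, -1, drop = FALSE] * dy[, -n, drop = FALSE])) / 2
  list(S = Zx^2 + Zy^2, m2 = m2, m1 = m1, nDisp = n, meta = sm$meta,
       dt = if (is.null(dt)) segset@frameInterval else dt)
}

# Log-likelihood matrix (segments x states) from sufficient statistics.
pemLogLikMatrix <- function(S, D, sigma2, dt, R) {
  K <- length(D)
  n <- ncol(S)
  cosj <- cos(seq_len(n) * pi / (n + 1))
  out <- matrix(-Inf, nrow(S), K)
  for (k in seq_len(K)) {
    ab <- covParams(D[k], sigma2[k], dt, R)
    lam <- ab$a + 2 * ab$b * cosj
    if (any(lam <= 0)) next
    out[, k] <- -sum(log(2 * pi * lam)) - 0.5 * drop(S %*% (1 / lam))
  }
  out
}

# gamma-weighted expected log-likelihood of one state (the M-step objective)
# from the weighted stats W = sum(gamma), Tj = colSums(gamma * S).
stateQ <- function(D, sigma2, dt, R, W, Tj, cosj) {
  ab <- covParams(D, sigma2, dt, R)
  lam <- ab$a + 2 * ab$b * cosj
  if (any(lam <= 0)) return(-Inf)
  -W * sum(log(2 * pi * lam)) - 0.5 * sum(Tj / lam)
}

DFLOOR <- 1e-9
S2FLOOR <- 1e-12

# M-step for one state: start from the current parameters and the inverted
# gamma-weighted moments, polish by bounded quasi-Newton, and keep whichever
# candidate has the largest Q. Never returns parameters with a lower Q than
# the current ones, so the EM log-likelihood is non-decreasing.
mStepState <- function(cur, dt, R, W, Tj, cosj, m2bar, m1bar) {
  cand <- list(cur)
  Dm <- (m2bar + 2 * m1bar) / (2 * dt)            # a + 2b = 2 D dt
  s2m <- 2 * R * Dm * dt - m1bar                  # b = 2 R D dt - sigma2
  cand[[2]] <- c(max(Dm, DFLOOR), max(s2m, S2FLOOR))
  qv <- vapply(cand, function(p) stateQ(p[1], p[2], dt, R, W, Tj, cosj),
               numeric(1))
  best <- cand[[which.max(qv)]]
  opt <- try(optim(best, function(p)
    -stateQ(p[1], p[2], dt, R, W, Tj, cosj),
    method = "L-BFGS-B", lower = c(DFLOOR, S2FLOOR),
    control = list(maxit = 25)), silent = TRUE)
  if (!inherits(opt, "try-error") &&
      -opt$value > stateQ(best[1], best[2], dt, R, W, Tj, cosj))
    best <- opt$par
  best
}

#' Fit a K-state mixture to trajectory segments by EM
#'
#' Expectation-maximization on the displacement-covariance likelihood:
#' the E-step computes posterior state probabilities
#' `gamma ~ pi_k * L_k(segment)`; the M-step re-estimates the weights as
#' mean posteriors and each state's (D, sigma2) by maximizing the
#' gamma-weighted likelihood (moment inversion with projection to the
#' feasible cone, polished numerically). The total log-likelihood is
#' non-decreasing across iterations. States whose weight falls below `1/N`
#' are dropped (with a message) and K reduced. The returned states are
#' sorted by increasing D and renumbered.
#'
#' @param segset a [SegmentSet-class] with at least K segments.
#' @param K number of states.
#' @param dt frame interval, s (default: the segment set's).
#' @param R motion-blur coefficient (default 1/6, full-frame exposure).
#' @param init optional list with `D`, `sigma2`, `weights` initial values.
#' @param maxIter,tol EM stopping rule: stop when the log-likelihood gain
#'   drops below `tol`.
#' @param seed RNG seed for the random initialization (ignored when `init`
#'   is given).
#' @return a [PemFit-class].
#' @export
emFit <- function(segset, K, dt = NULL, R = 1 / 6, init = NULL,
                  maxIter = 300L, tol = 1e-6, seed = 1L) {
  st <- if (is(segset, "SegmentSet")) pemStats(segset, dt) else segset
  N <- nrow(st$S)
  assertThat(N >= K, "need at least K segments")
  dt <- st$dt
  cosj <- cos(seq_len(st$nDisp) * pi / (st$nDisp + 1))

  if (is.null(init)) init <- randomInit(st, K, R, seed)
  D <- init$D; sigma2 <- init$sigma2; w <- init$weights
  ord <- order(D)
  D <- D[ord]; sigma2 <- sigma2[ord]; w <- w[ord]

  trace <- numeric(0)
  converged <- FALSE
  gamma <- NULL
  for (it in seq_len(maxIter)) {
    ll <- pemLogLikMatrix(st$S, D, sigma2, dt, R)
    lw <- sweep(ll, 2L, log(w), "+")
    lse <- rowLogSumExp(lw)
    total <- sum(lse)
    gamma <- exp(lw - lse)
    trace <- c(trace, total)
    if (it > 1L && abs(total - trace[it - 1L]) < tol) {
      converged <- TRUE
      break
    }
    # M-step
    w <- colMeans(gamma)
    keep <- w >= 1 / N
    if (!all(keep)) {
      message("dropping ", sum(!keep), " empty state(s); K reduced to ",
              sum(keep))
      D <- D[keep]; sigma2 <- sigma2[keep]
      gamma <- gamma[, keep, drop = FALSE]
      w <- w[keep] / sum(w[keep])
    }
    for (k in seq_along(D)) {
      gk <- gamma[, k]
      W <- sum(gk)
      if (W <= 0) next
      Tj <- drop(crossprod(gk, st$S))
      m2bar <- sum(gk * st$m2) / W
      m1bar <- sum(gk * st$m1) / W
      p <- mStepState(c(D[k], sigma2[k]), dt, R, W, Tj, cosj, m2bar, m1bar)
      D[k] <- p[1]; sigma2[k] <- p[2]
    }
  }

  ord <- order(D)
  D <- D[ord]; sigma2 <- sigma2[ord]; w <- w[ord]
  gamma <- gamma[, ord, drop = FALSE]
  Kfin <- length(D)
  bic <- -2 * trace[length(trace)] + (3 * Kfin - 1) * log(N)
  model <- new("StateModel", K = Kfin, D = D, sigma2 = sigma2,
               weights = w / sum(w), logLik = trace[length(trace)], bic = bic,
               converged = converged, dt = dt, blurR = R, logLikTrace = trace)
  new("PemFit", model = model, posterior = gamma,
      labels = as.integer(max.col(gamma, ties.method = "first")),
      segmentIds = as.integer(st$meta$segment_id))
}

# Random EM start: diffusivities drawn log-uniformly over the range spanned
# by the per-segment CVE estimates, noise variances log-uniform over a
# localization-noise scale, weights uniform.
randomInit <- function(st, K, R, seed) {
  withSeed(seed, {
    Dcve <- st$m2 / (2 * st$dt) + st$m1 / st$dt
    pos <- Dcve[Dcve > 0]
    rng <- if (length(pos) >= 2) range(quantile(pos, c(0.02, 0.98)))
           else c(1e-4, 1)
    rng[1] <- max(rng[1], 1e-6)
    D <- sort(exp(runif(K, log(rng[1]), log(rng[2]))))
    s2ref <- pmax(median(pmax(R * st$m2 + (2 * R - 1) * st$m1, 0)), 1e-6)
    sigma2 <- exp(runif(K, log(s2ref / 30), log(s2ref * 3)))
    list(D = D, sigma2 = sigma2, weights = rep(1 / K, K))
  })
}

#' pEM: EM with random reinitializations and perturbation escapes,
#' BIC selection of the number of states
#'
#' For each K up to `Kmax`, the EM is run from `nReinit` random starts;
#' from the best of these, `nPerturb` random perturbations (log-normal
#' jitter of D and sigma2, Dirichlet jitter of the weights) are each
#' polished by EM and the best log-likelihood kept. The number of states is
#' selected by the Bayesian information criterion
#' `BIC = -2 logLik + (3K - 1) log N`, ties resolved towards smaller K.
#'
#' @inheritParams emFit
#' @param Kmax largest number of states to explore (default 15).
#' @param nReinit random reinitializations per K (default 20).
#' @param nPerturb perturbations of the best fit per K (default 150).
#' @param perturbScale SD of the log-normal jitter applied to D and sigma2.
#' @param dirichletAlpha concentration of the Dirichlet weight jitter.
#' @param polishIter EM iterations allowed when polishing a perturbation.
#' @param stopAfter stop exploring larger K after this many consecutive K
#'   with BIC above the running minimum (`Inf` = explore all).
#' @param verbose print per-K progress.
#' @return a [PemScan-class]; all candidate models are retained in `fits`.
#' @export
pemSearch <- function(segset, Kmax = 15L, nReinit = 20L, nPerturb = 150L,
                      dt = NULL, R = 1 / 6, maxIter = 300L, tol = 1e-4,
                      perturbScale = 0.5, dirichletAlpha = 10,
                      polishIter = 100L, stopAfter = 3L, seed = 1L,
                      verbose = FALSE) {
  st <- pemStats(segset, dt)
  N <- nrow(st$S)
  fits <- list()
  bics <- numeric(0)
  worse <- 0L
  for (K in seq_len(min(Kmax, N))) {
    best <- NULL
    for (r in seq_len(nReinit)) {
      f <- emFit(st, K, R = R, maxIter = maxIter, tol = tol,
                 seed = seed * 1000L + K * 100L + r)
      if (is.null(best) || f@model@logLik > best@model@logLik) best <- f
    }
    if (nPerturb > 0 && best@model@K == K) {
      for (p in seq_len(nPerturb)) {
        m <- best@model       # may have collapsed below K in a prior polish
        Kc <- m@K
        ini <- withSeed(seed * 100000L + K * 1000L + p, {
          list(D = m@D * exp(rnorm(Kc, sd = perturbScale)),
               sigma2 = pmax(m@sigma2, S2FLOOR) *
                 exp(rnorm(Kc, sd = perturbScale)),
               weights = rdirichlet1(dirichletAlpha * Kc * m@weights + 1e-3))
        })
        f <- emFit(st, Kc, R = R, init = ini, maxIter = polishIter, tol = tol)
        if (f@model@logLik > best@model@logLik) best <- f
      }
      # re-polish the winner to full convergence
      m <- best@model
      best <- emFit(st, m@K, R = R,
                    init = list(D = m@D, sigma2 = m@sigma2,
                                weights = m@weights),
                    maxIter = maxIter, tol = tol)
    }
    eff <- best@model@K
    if (eff < K) {
      # states collapsed during EM: this candidate belongs to a smaller K
      prev <- fits[[as.character(eff)]]
      if (!is.null(prev) && best@model@logLik > prev@model@logLik) {
        fits[[as.character(eff)]] <- best
        bics[as.character(eff)] <- best@model@bic
      }
      bics[as.character(K)] <- NA_real_
      fits[[as.character(K)]] <- best
    } else {
      fits[[as.character(K)]] <- best
      bics[as.character(K)] <- best@model@bic
    }
    if (verbose)
      message(sprintf("K = %d: logLik = %.2f, BIC = %.2f", K,
                      best@model@logLik, best@model@bic))
    if (is.na(bics[as.character(K)]) ||
        bics[as.character(K)] > min(bics, na.rm = TRUE))
      worse <- worse + 1L
    else worse <- 0L
    if (worse >= stopAfter) break
  }
  bestK <- as.integer(names(bics)[which.min(bics)])  # ties -> smaller K
  new("PemScan", fits = fits, bic = bics, bestK = bestK)
}

#' Population fractions per burst with Wilson confidence intervals
#'
#' Fraction of segments assigned to each state at each time point (burst),
#' with a Wilson score interval at the requested confidence level. Bursts
#' with no segments are omitted with a warning. Fractions across states sum
#' to 1 within each burst.
#'
#' @param labels integer state labels (e.g. from [stateLabels()]).
#' @param bursts burst (time-point) index per label.
#' @param K number of states (default `max(labels)`).
#' @param conf confidence level (default 0.95).
#' @return data.frame with `burst`, `state`, `n`, `total`, `fraction`,
#'   `lower`, `upper`.
#' @export
populationFractions <- function(labels, bursts = rep(1L, length(labels)),
                                K = max(labels), conf = 0.95) {
  assertThat(length(labels) == length(bursts), "labels/bursts length mismatch")
  ub <- sort(unique(bursts))
  out <- lapply(ub, function(b) {
    lb <- labels[bursts == b]
    total <- length(lb)
    counts <- tabulate(lb, nbins = K)
    ci <- t(vapply(counts, wilsonInterval, numeric(2), n = total, conf = conf))
    data.frame(burst = b, state = seq_len(K), n = counts, total = total,
               fraction = counts / total, lower = ci[, 1], upper = ci[, 2])
  })
  do.call(rbind, out)
}

#' State-transition counts between consecutive segments
#'
#' Within each parent track longer than `minTrackFrames - 1` frames (i.e.
#' tracks of more than 30 frames by default), consecutive 15-frame segments
#' give one observed transition from the state of segment i to the state of
#' segment i + 1. Counts are row-normalized into frequencies; rows with no
#' observations are flagged.
#'
#' @param segset the [SegmentSet-class] that was classified.
#' @param labels state label per segment, aligned with the segment ids of
#'   `segset` (a [PemFit-class] is also accepted).
#' @param K number of states.
#' @param minTrackFrames minimum parent-track length in frames (default 31,
#'   i.e. tracks > 30 frames).
#' @return list with `counts` (K x K), `freq` (row-normalized; NA rows where
#'   no transitions were observed) and `emptyRows`.
#' @export
stateTransitions <- function(segset, labels, K = NULL, minTrackFrames = 31L) {
  if (is(labels, "PemFit")) {
    if (is.null(K)) K <- labels@model@K
    labels <- stateLabels(labels)
  }
  sm <- segmentMatrices(segset)
  meta <- sm$meta
  lab <- labels[match(meta$segment_id, as.integer(names(labels)))]
  if (anyNA(lab)) {
    # labels given as a bare vector in segment-id order
    lab <- unname(labels)[meta$segment_id]
  }
  if (is.null(K)) K <- max(lab)
  eligible <- meta$parent_length >= minTrackFrames
  counts <- matrix(0L, K, K)
  if (any(eligible)) {
    m <- meta[eligible, , drop = FALSE]
    l <- lab[eligible]
    o <- order(m$particle_id, m$burst, m$seg_index)
    m <- m[o, , drop = FALSE]; l <- l[o]
    same <- m$particle_id[-1] == m$particle_id[-nrow(m)] &
      m$burst[-1] == m$burst[-nrow(m)] &
      m$seg_index[-1] == m$seg_index[-nrow(m)] + 1L
    from <- l[-length(l)][same]
    to <- l[-1][same]
    for (i in seq_along(from))
      counts[from[i], to[i]] <- counts[from[i], to[i]] + 1L
  }
  if (sum(counts) == 0L) warning("no eligible transitions")
  rs <- rowSums(counts)
  freq <- counts / ifelse(rs > 0, rs, NA_real_)
  list(counts = counts, freq = freq, emptyRows = which(rs == 0))
}
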