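# pEM: displacement-covariance likelihood, EM fitting, BIC search,
# population fractions, transitions.

test_that("displacement covariance is tridiagonal Toeplitz with the stated entries", {
  # D = 0.1 um^2/s, dt = 0.03 s, R = 1/6, sigma2 = 9e-4 um^2:
  # a = 2 D dt - 4 R D dt + 2 sigma2 = 0.0058, b = 2 R D dt - sigma2 = 1e-4
  m <- displacementCovariance(0.1, 9e-4, 0.03, 1 / 6, 4)
  expect_equal(unique(diag(m)), 0.0058)
  expect_equal(m[1, 2], 1e-4)
  expect_equal(m[2, 1], 1e-4)
  expect_equal(m[1, 3], 0)

  expect_equal(displacementCovariance(0, 0, 0.03, 1 / 6, 3),
               matrix(0, 3, 3))
  pure <- displacementCovariance(0.2, 0, 0.05, 0, 3)
  expect_equal(pure, diag(2 * 0.2 * 0.05, 3))
})

test_that("segment log-likelihood matches a dense multivariate-normal oracle", {
  # hand-checkable 2-displacement case
  dx <- c(0.05, -0.02); dy <- c(0.01, 0.03)
  S2 <- displacementCovariance(0.08, 4e-4, 1 / 33, 1 / 6, 2)
  expect_equal(segmentLogLik(dx, dy, 0.08, 4e-4, 1 / 33, 1 / 6),
               denseMvnLogLik(dx, S2) + denseMvnLogLik(dy, S2))
  # full 14-displacement case
  set.seed(2)
  dx <- rnorm(14, sd = 0.05); dy <- rnorm(14, sd = 0.05)
  S <- displacementCovariance(0.05, 6e-4, 1 / 33, 1 / 6, 14)
  expect_equal(segmentLogLik(dx, dy, 0.05, 6e-4, 1 / 33, 1 / 6),
               denseMvnLogLik(dx, S) + denseMvnLogLik(dy, S))
})

test_that("non-positive-definite parameters give -Inf with a diagnostic", {
  ll <- segmentLogLik(c(0.1, 0.1), c(0, 0), D = 0, sigma2 = 0, dt = 1 / 33)
  expect_identical(as.numeric(ll), -Inf)
  expect_match(attr(ll, "reason"), "positive-definite")
})

test_that("the generating state out-scores a 10x wrong diffusivity", {
  segs <- quickSegments(300, D = 0.05, locSigma = 0.03, seed = 21)
  sm <- trackStates:::segmentMatrices(segs)
  wins <- vapply(seq_len(nrow(sm$x)), function(i) {
    dx <- diff(sm$x[i, ]); dy <- diff(sm$y[i, ])
    segmentLogLik(dx, dy, 0.05, 9e-4, 1 / 33) >
      segmentLogLik(dx, dy, 0.5, 9e-4, 1 / 33)
  }, logical(1))
  expect_gte(mean(wins), 0.99)
})

test_that("single-component EM agrees with the pooled CVE ensemble", {
  segs <- quickSegments(1500, D = 0.08, locSigma = 0.03, seed = 22)
  fit <- emFit(segs, K = 1, seed = 1)
  cve <- cveDiffusivity(segs)
  expect_equal(stateWeights(fit), 1)
  expect_lt(abs(stateD(fit) / mean(cve$D) - 1), 0.05)
  expect_lt(abs(stateD(fit) / 0.08 - 1), 0.1)
})

test_that("two well-separated states are recovered with correct fractions", {
  segs <- quickSegments(1000, D = c(0.01, 0.3), locSigma = c(0.02, 0.06),
                        seed = 23)
  fit <- emFit(segs, K = 2, seed = 2)
  expect_lt(max(abs(stateD(fit) / c(0.01, 0.3) - 1)), 0.15)
  expect_lt(max(abs(stateWeights(fit) - 0.5)), 0.05)
  truth <- trackStates:::segmentMatrices(segs)$meta$true_state
  expect_gte(mean(fit@labels == truth), 0.95)
  expect_equal(unname(rowSums(statePosterior(fit))),
               rep(1, nSegments(segs)), tolerance = 1e-9)
})

test_that("EM log-likelihood is non-decreasing in every seeded run", {
  segs <- quickSegments(400, D = c(0.02, 0.2), locSigma = c(0.02, 0.05),
                        seed = 24)
  for (s in 1:5) {
    fit <- emFit(segs, K = 2, seed = s)
    tr <- fit@model@logLikTrace
    expect_true(all(diff(tr) >= -1e-6 * (1 + abs(tr[-length(tr)]))),
                info = paste("seed", s))
  }
})

test_that("estimated localization noise increases with state diffusivity", {
  segs <- quickSegments(800, D = c(0.003, 0.3), locSigma = c(0.02, 0.08),
                        seed = 25)
  fit <- emFit(segs, K = 2, seed = 3)
  expect_lt(stateSigma2(fit)[1], stateSigma2(fit)[2])
  expect_lt(abs(sqrt(stateSigma2(fit)[1]) - 0.02), 0.01)
  expect_lt(abs(sqrt(stateSigma2(fit)[2]) - 0.08), 0.02)
})

test_that("BIC selects one state for single-state data; loglik is nested in K", {
  segs <- quickSegments(600, D = 0.05, locSigma = 0.03, seed = 26)
  scan <- pemSearch(segs, Kmax = 3, nReinit = 3, nPerturb = 4, seed = 5)
  expect_equal(scan@bestK, 1L)
  lls <- vapply(scan@fits, logLik2, numeric(1))
  ks <- vapply(scan@fits, function(f) f@model@K, integer(1))
  # among fits that kept their nominal K, richer models fit no worse
  full <- lls[ks == as.integer(names(ks))]
  if (length(full) > 1) expect_true(all(diff(full) >= -1e-4 * abs(full[-1])))
})

test_that("population fractions carry Wilson 95% intervals", {
  labels <- rep(c(1L, 2L), each = 200)
  fr <- populationFractions(labels, K = 2)
  expect_equal(fr$fraction, c(0.5, 0.5))
  expect_equal(fr$lower, rep(0.4514, 2), tolerance = 1e-3)
  expect_equal(fr$upper, rep(0.5486, 2), tolerance = 1e-3)
  expect_equal(sum(fr$fraction), 1)
  # agreement with the score interval from prop.test (no continuity corr.)
  pt <- prop.test(200, 400, correct = FALSE)$conf.int
  expect_equal(fr$lower[1], pt[1], tolerance = 1e-9)
  expect_equal(fr$upper[1], pt[2], tolerance = 1e-9)

  one <- populationFractions(rep(1L, 50), K = 1)
  expect_equal(one$fraction, 1)
  expect_equal(one$upper, 1)

  multi <- populationFractions(c(1L, 1L, 2L, 1L, 2L, 2L),
                               bursts = c(1, 1, 1, 2, 2, 2), K = 2)
  sums <- tapply(multi$fraction, multi$burst, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("transition counting: identity labels, track-length eligibility", {
  # two tracks: 45 frames (3 segments) and 30 frames (2 segments, excluded)
  df <- rbind(restTrack(1, 45), restTrack(2, 30, x = 3))
  segs <- segmentTracks(makeTrackSet(df))
  labels <- rep(1L, nSegments(segs))
  tm <- stateTransitions(segs, labels, K = 2)
  expect_equal(tm$counts[1, 1], 2L)          # only the 45-frame track counts
  expect_equal(sum(tm$counts), 2L)
  expect_equal(tm$freq[1, 1], 1)
  expect_equal(tm$emptyRows, 2L)

  # a 31-frame track yields two full segments, hence one transition
  segs31 <- segmentTracks(makeTrackSet(restTrack(1, 31)))
  tm31 <- stateTransitions(segs31, rep(2L, 2), K = 2)
  expect_equal(sum(tm31$counts), 1L)
  expect_equal(tm31$counts[2, 2], 1L)
})

test_that("no eligible tracks gives an empty matrix with a warning", {
  segs <- segmentTracks(makeTrackSet(restTrack(1, 20)))
  expect_warning(tm <- stateTransitions(segs, rep(1L, 1), K = 1),
                 "no eligible")
  expect_equal(sum(tm$counts), 0L)
})
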