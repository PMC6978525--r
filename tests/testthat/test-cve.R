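# Covariance-based diffusivity estimation, ensemble MSD, and
# subsampled Kruskal-Wallis comparisons.

test_that("static segments give D = 0 and sigma2 = 0", {
  df <- restTrack(1, 15, x = 2, y = 3)
  segs <- segmentTracks(makeTrackSet(df))
  est <- cveDiffusivity(segs, dt = 1, R = 0)
  expect_equal(est$D, 0)
  expect_equal(est$sigma2, 0)
})

test_that("alternating 1-D positions reproduce the estimator arithmetic", {
  # positions (0,1,0,1) um on both axes, dt = 1 s, R = 0:
  # displacements (+1,-1,+1): mean(d^2)/2 + mean(d_n d_{n+1}) = 0.5 - 1
  df <- data.frame(particle_id = 1L, burst = 1L, frame = 1:4,
                   x = c(0, 1, 0, 1), y = c(0, 1, 0, 1))
  est <- cveDiffusivity(makeTrackSet(df, dt = 1), dt = 1, R = 0)
  expect_equal(est$D, -0.5)
  # sigma2 = R*m2 + (2R-1)*m1 = 0 - (-1) = 1
  expect_equal(est$sigma2, 1)
})

test_that("segments with fewer than 3 positions are rejected", {
  df <- restTrack(1, 2)
  expect_error(cveDiffusivity(makeTrackSet(df)), "3 positions")
})

test_that("ensemble CVE recovers D and sigma2 of simulated segments", {
  segs <- quickSegments(3000, D = 0.1, locSigma = 0.03, seed = 4)
  est <- cveDiffusivity(segs, R = 1 / 6)
  expect_lt(abs(mean(est$D) / 0.1 - 1), 0.05)
  expect_lt(abs(mean(est$sigma2) / 9e-4 - 1), 0.15)
  # negative estimates must be retained (unbiasedness at short tracks)
  expect_gt(sum(est$D < 0), 0)
})

test_that("ensemble MSD definition: lag-1 equals the mean squared step", {
  set.seed(6)
  df <- do.call(rbind, lapply(1:5, function(i)
    data.frame(particle_id = i, burst = 1L, frame = 1:10,
               x = cumsum(rnorm(10, sd = 0.1)),
               y = cumsum(rnorm(10, sd = 0.1)))))
  ts <- makeTrackSet(df)
  m <- ensembleMSD(ts, maxLag = 3)
  direct <- unlist(lapply(split(df, df$particle_id), function(d)
    diff(d$x)^2 + diff(d$y)^2))
  expect_equal(m@msd[1], mean(direct))
  expect_equal(m@nPairs[1], 45)
})

test_that("ensemble MSD is zero for static particles and warns on long lags", {
  ts <- makeTrackSet(rbind(restTrack(1, 6), restTrack(2, 6, x = 2)))
  expect_warning(m <- ensembleMSD(ts, maxLag = 10), "truncated")
  expect_true(all(m@msd == 0))
  expect_equal(length(m@lag), 5)
})

test_that("MSD regression on simulated tracks recovers the diffusivity", {
  cfg <- simConfig(nTracks = 3000, D = 0.05, locSigma = 0,
                   exposureFraction = 0, trackLengthLaw = "fixed",
                   fixedTrackLength = 15, mask = diskMask(c(25, 25), 25),
                   seed = 12)
  m <- ensembleMSD(simulateTracks(cfg), maxLag = 5)
  dt <- 1 / 33
  slope <- coef(lm(m@msd ~ I(m@lag * dt)))[2]
  expect_lt(abs(slope / 4 / 0.05 - 1), 0.05)
})

test_that("subsampled Kruskal-Wallis: identity, null, and power behavior", {
  set.seed(9)
  base <- rlnorm(600, meanlog = -3, sdlog = 1)
  # one group against an identical copy: every draw ties completely -> p = 1
  same <- compareDiffusivities(list(a = base, b = base), subsetSize = 100,
                               nDraws = 10, seed = 2)
  expect_true(all(same$draws == 1))

  # independent samples from one distribution: no systematic signal
  nullg <- compareDiffusivities(list(a = rlnorm(500, -3, 1),
                                     b = rlnorm(500, -3, 1)),
                                subsetSize = 200, nDraws = 20, seed = 3)
  expect_gt(nullg$p, 0.01)

  # 10x shifted diffusivities at subset size 200: decisive rejection
  shift <- compareDiffusivities(list(a = base, b = base * 10),
                                subsetSize = 200, nDraws = 20, seed = 4)
  expect_lt(shift$p, 0.001)
})

test_that("degenerate all-tied draws give p = 1 with a warning", {
  g <- list(a = rep(1, 50), b = rep(1, 50))
  ws <- capture_warnings(res <- compareDiffusivities(g, subsetSize = 20,
                                                     nDraws = 3, seed = 1))
  expect_match(ws, "degenerate", all = TRUE)
  expect_length(ws, 3)
  expect_equal(res$p, 1)
})

test_that("groups smaller than the subset size are rejected", {
  expect_error(compareDiffusivities(list(a = 1:10, b = 1:300),
                                    subsetSize = 50), "subsetSize")
})
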