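# Spot detection, Gaussian refinement, and crossing-aware linking.

test_that("flat frames yield no detections, with a warning", {
  expect_warning(d <- detectSpots(matrix(5, 32, 32), threshold = 10),
                 "flat")
  expect_equal(nrow(d), 0)
})

test_that("a noiseless rendered spot is recovered to sub-centipixel accuracy", {
  one <- makeTrackSet(data.frame(particle_id = 1L, frame = 1L,
                                 x = 0.503, y = 0.748),
                      mask = rectMask(c(0, 1.6), c(0, 1.6)))
  st <- renderSpotMovie(one, psfSigma = 0.15, photonScale = 500,
                        background = 5)
  d <- detectSpots(st[, , 1], threshold = 10, psfSigma = 0.15,
                   pixelSize = 0.1)
  expect_equal(nrow(d), 1)
  expect_lt(abs(d$x - 0.503) / 0.1, 0.02)
  expect_lt(abs(d$y - 0.748) / 0.1, 0.02)
  expect_true(d$fit_ok)
})

test_that("localization RMSE at single-molecule SNR is below 25 nm", {
  set.seed(1)
  errs <- numeric(0)
  for (i in 1:200) {
    x0 <- 0.7 + runif(1) * 0.1
    y0 <- 0.7 + runif(1) * 0.1
    tk <- makeTrackSet(data.frame(particle_id = 1L, frame = 1L,
                                  x = x0, y = y0),
                       mask = rectMask(c(0, 1.6), c(0, 1.6)))
    st <- renderSpotMovie(tk, psfSigma = 0.15, photonScale = 500,
                          background = 10, noiseModel = "poisson+gaussian",
                          readSd = 2, seed = i)
    d <- detectSpots(st[, , 1], threshold = 15, psfSigma = 0.15,
                     pixelSize = 0.1)
    d <- d[d$fit_ok & d$amplitude > 100, , drop = FALSE]
    if (!nrow(d)) next
    j <- which.min((d$x - x0)^2 + (d$y - y0)^2)
    errs <- c(errs, sqrt((d$x[j] - x0)^2 + (d$y[j] - y0)^2))
  }
  expect_gt(length(errs), 180)                 # near-complete detection
  expect_lt(sqrt(mean(errs^2)) * 1000, 25)     # nm
})

test_that("detections outside the mask are discarded", {
  two <- makeTrackSet(data.frame(particle_id = 1:2, frame = 1L,
                                 x = c(0.5, 1.2), y = c(0.5, 1.2)),
                      mask = rectMask(c(0, 1.7), c(0, 1.7)))
  st <- renderSpotMovie(two, psfSigma = 0.15, photonScale = 500,
                        background = 5)
  d <- detectSpots(st[, , 1], threshold = 10, psfSigma = 0.15,
                   pixelSize = 0.1, mask = diskMask(c(0.5, 0.5), 0.3))
  expect_equal(nrow(d), 1)
  expect_lt(abs(d$x - 0.5), 0.05)
})

test_that("a drifting particle below maxDisp links into one track", {
  locs <- data.frame(frame = 1:6, x = 0.1 * (1:6), y = 0.5)
  lt <- linkTracks(locs, maxDisp = 0.15)
  expect_equal(nTracks(lt), 1)
  expect_equal(unname(trackLengths(lt)), 6L)
})

test_that("crossing paths interrupt both trajectories", {
  locs <- data.frame(frame = rep(1:5, 2),
                     x = c(1:5, 5:1), y = c(rep(1, 5), rep(1.05, 5)))
  lt <- linkTracks(locs, maxDisp = 1.5)
  tr <- trackData(lt)
  lens <- table(tr$particle_id)
  # both pre-crossing tracks stop at frame 2; >= 2 new tracks appear after
  pre <- unique(tr$particle_id[tr$frame <= 2])
  expect_true(all(tapply(tr$frame, tr$particle_id, max)[as.character(pre)] == 2))
  expect_gte(length(unique(tr$particle_id[tr$frame >= 3])), 2)
})

test_that("a jump beyond maxDisp splits the track", {
  locs <- data.frame(frame = 1:6, x = c(1, 1.1, 1.2, 3, 3.1, 3.2), y = 0)
  lt <- linkTracks(locs, maxDisp = 0.5)
  expect_equal(nTracks(lt), 2)
  expect_equal(sort(unname(trackLengths(lt))), c(3L, 3L))
})

test_that("simulate -> render -> detect -> link recovers sparse slow tracks", {
  cfg <- simConfig(nTracks = 8, D = 0.02, locSigma = 0,
                   trackLengthLaw = "fixed", fixedTrackLength = 20,
                   mask = rectMask(c(1, 11), c(1, 11)),
                   framesPerBurst = 20, seed = 42)
  ts <- simulateTracks(cfg)
  st <- renderSpotMovie(ts, psfSigma = 0.15, photonScale = 800,
                        background = 10, noiseModel = "poisson+gaussian",
                        readSd = 2, imageSize = c(120, 120), seed = 9)
  locs <- detectStack(st, threshold = 20, psfSigma = 0.15)
  lt <- linkTracks(locs[locs$fit_ok, ], maxDisp = 3 * sqrt(4 * 0.02 / 33))
  expect_gte(sum(trackLengths(lt) == 20), ceiling(0.9 * 8))
})
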