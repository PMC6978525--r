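# Synthetic-data generator: motion statistics, switching, determinism,
# rendering and flow movies.

test_that("zero diffusivity and zero noise give constant positions", {
  ts <- simulateTracks(simConfig(nTracks = 5, D = 0, locSigma = 0,
                                 trackLengthLaw = "fixed",
                                 fixedTrackLength = 8, seed = 1))
  tr <- trackData(ts)
  spread <- tapply(tr$x, tr$particle_id, function(v) diff(range(v))) +
    tapply(tr$y, tr$particle_id, function(v) diff(range(v)))
  expect_equal(unname(max(spread)), 0)
})

test_that("ensemble MSD matches 4 D n dt (no blur, no noise)", {
  cfg <- simConfig(nTracks = 5000, D = 0.1, locSigma = 0,
                   exposureFraction = 0, trackLengthLaw = "fixed",
                   fixedTrackLength = 15, mask = diskMask(c(25, 25), 25),
                   seed = 2)
  m <- ensembleMSD(simulateTracks(cfg), maxLag = 3)
  dt <- 1 / 33
  expect_lt(max(abs(m@msd / (4 * 0.1 * m@lag * dt) - 1)), 0.02)
  expect_true(all(diff(m@nPairs) < 0))
})

test_that("ensemble MSD matches the blur/noise form 4Dndt + 4s2 - 8RDdt", {
  D <- 0.1; s <- 0.03; dt <- 1 / 33
  cfg <- simConfig(nTracks = 6000, D = D, locSigma = s,
                   exposureFraction = 1, trackLengthLaw = "fixed",
                   fixedTrackLength = 15, mask = diskMask(c(25, 25), 25),
                   seed = 3)
  m <- ensembleMSD(simulateTracks(cfg), maxLag = 8)
  pred <- 4 * D * m@lag * dt + 4 * s^2 - 8 * (1 / 6) * D * dt
  expect_lt(max(abs(m@msd / pred - 1)), 0.03)
})

test_that("symmetric 2-state switching converges to 50/50 occupancy", {
  P <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
  cfg <- simConfig(nTracks = 800, D = c(0.01, 0.1), locSigma = 0,
                   transitionMatrix = P, initialFractions = c(0.9, 0.1),
                   trackLengthLaw = "fixed", fixedTrackLength = 400,
                   framesPerBurst = 400, seed = 5)
  occ <- mean(trackData(simulateTracks(cfg))$true_state == 1)
  expect_lt(abs(occ - 0.5), 0.02)
})

test_that("identical config and seed give bit-identical tracks", {
  cfg <- simConfig(nTracks = 30, D = c(0.01, 0.2), locSigma = c(0.02, 0.05),
                   transitionMatrix = matrix(c(.95, .05, .05, .95), 2,
                                             byrow = TRUE),
                   seed = 7)
  expect_identical(trackData(simulateTracks(cfg)),
                   trackData(simulateTracks(cfg)))
})

test_that("tracks have contiguous frames and stay inside the mask", {
  mask <- diskMask(c(5, 5), 5)
  cfg <- simConfig(nTracks = 100, D = 0.5, locSigma = 0, mask = mask,
                   seed = 8)
  tr <- trackData(simulateTracks(cfg))
  gaps <- tapply(tr$frame, tr$particle_id, function(f) all(diff(f) == 1))
  expect_true(all(gaps))
  expect_true(all(maskContains(mask, tr)))
})

test_that("state-count mismatches in the config are rejected", {
  expect_error(simConfig(D = c(0.1, 0.2), locSigma = 0.02,
                         transitionMatrix = diag(3)),
               "state count mismatch")
  expect_error(simConfig(D = 0.1, exposureFraction = 1.2), "exposureFraction")
})

test_that("cluster states produce spatial clustering of first positions", {
  cfg <- simConfig(nTracks = 400, D = c(0.002, 0.2),
                   locSigma = c(0.02, 0.05), clusterStates = 1L,
                   clusterRadius = 0.2, nClusters = 15,
                   trackLengthLaw = "fixed", fixedTrackLength = 15, seed = 3)
  ts <- simulateTracks(cfg)
  tr <- trackData(ts)
  first <- tr[!duplicated(tr$particle_id) & tr$true_state == 1,
              c("x", "y")]
  gr <- grTable(pairCorrelation(first, cfg@mask,
                                rEdges = seq(0, 1, by = 0.05), seed = 2))
  expect_gt(gr$g[2], 3)   # strong short-range clustering
})

test_that("spot rendering: background-only cases and centroid accuracy", {
  empty <- makeTrackSet(data.frame(particle_id = integer(), burst = integer(),
                                   frame = integer(), x = numeric(),
                                   y = numeric()),
                        mask = rectMask(c(0, 1), c(0, 1)))
  st <- renderSpotMovie(empty, background = 7)
  expect_true(all(st == 7))

  one <- makeTrackSet(data.frame(particle_id = 1L, frame = 1L,
                                 x = 1.103, y = 1.148),
                      mask = rectMask(c(0, 2.2), c(0, 2.2)))
  dark <- renderSpotMovie(one, photonScale = 0, background = 3)
  expect_true(all(dark == 3))

  st1 <- renderSpotMovie(one, psfSigma = 0.15, photonScale = 500,
                         background = 5)
  img <- st1[, , 1] - 5
  xs <- (seq_len(ncol(img)) - 0.5) * 0.1
  cx <- sum(colSums(img) * xs) / sum(img)
  cy <- sum(rowSums(img) * xs) / sum(img)
  expect_lt(abs(cx - 1.103) / 0.1, 1e-3)
  expect_lt(abs(cy - 1.148) / 0.1, 1e-3)
})

test_that("rendering rejects tracks outside the image extent", {
  bad <- makeTrackSet(data.frame(particle_id = 9L, frame = 1L, x = 5, y = 5),
                      mask = rectMask(c(0, 1), c(0, 1)))
  expect_error(renderSpotMovie(bad), "9")
})

test_that("flow stacks: zero field static, unit shift translates, radial truth", {
  z <- simulateFlowStack(list(type = "zero"), imageSize = c(16, 16),
                         nFrames = 4, seed = 1)
  expect_equal(z$stack[, , 2], z$stack[, , 1])
  expect_equal(z$stack[, , 4], z$stack[, , 1])

  ps <- 0.1; dt <- 2
  u <- simulateFlowStack(list(type = "uniform", v = c(ps / dt, 0)),
                         imageSize = c(16, 16), nFrames = 3, pixelSize = ps,
                         frameInterval = dt, seed = 2)
  s <- u$stack
  expect_equal(s[, , 2], cbind(s[, 16, 1], s[, 1:15, 1]),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(s[, , 3], cbind(s[, 15:16, 1], s[, 1:14, 1]),
               tolerance = 1e-10, ignore_attr = TRUE)

  r <- simulateFlowStack(list(type = "radial", speed = 0.02),
                         imageSize = c(32, 32), nFrames = 2, seed = 3)
  f <- r$field
  ctr <- c(1.6, 1.6)
  cosang <- ((ctr[1] - f$x) * f$vx + (ctr[2] - f$y) * f$vy) /
    sqrt(f$vx^2 + f$vy^2) / sqrt((ctr[1] - f$x)^2 + (ctr[2] - f$y)^2)
  expect_true(all(abs(cosang - 1) < 1e-9))
})

test_that("image stacks survive a TIFF round trip with metadata", {
  st <- imageStack(array(runif(16 * 16 * 3) * 50, c(16, 16, 3)),
                   pixelSize = 0.1, frameInterval = 2)
  path <- file.path(tempdir(), "stack-roundtrip.tif")
  writeImageStack(st, path)
  back <- readImageStack(path)
  expect_equal(stackPixelSize(back), 0.1)
  expect_equal(stackFrameInterval(back), 2)
  expect_equal(as.vector(back), as.vector(st), tolerance = 1e-6)
  unlink(c(path, paste0(path, ".meta.json")))
})
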