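# Immobile filtering, STICS velocimetry, directional coherence, and the
# two-proportion flow test.

test_that("immobile filter zeroes a static stack and ignores DC offsets", {
  base <- matrix(runif(256, 10, 50), 16, 16)
  st <- imageStack(array(rep(base, 25), c(16, 16, 25)), 0.1, 2)
  f <- immobileFilter(st, window = 20)
  expect_lt(max(abs(f)), 1e-9)

  set.seed(1)
  dyn <- imageStack(array(rnorm(16 * 16 * 25), c(16, 16, 25)), 0.1, 2)
  shifted <- imageStack(dyn + 100, 0.1, 2)
  expect_equal(as.vector(immobileFilter(shifted, 20)),
               as.vector(immobileFilter(dyn, 20)), tolerance = 1e-9)

  expect_error(immobileFilter(dyn, window = 30), "exceeds")
})

test_that("immobile filter removes background but preserves a moving spot", {
  set.seed(2)
  bgimg <- matrix(runif(32 * 32, 20, 60), 32, 32)
  st <- array(rep(bgimg, 30), c(32, 32, 30))
  for (t in 1:30) st[8, 1 + t %% 32, t] <- st[8, 1 + t %% 32, t] + 100
  st <- imageStack(st, 0.1, 2)
  f <- immobileFilter(st, 20)
  spotRows <- 7:9
  bgEnergy0 <- sum(st[-spotRows, , ]^2)
  bgEnergyF <- sum(f[-spotRows, , ]^2)
  expect_lt(bgEnergyF, 0.05 * bgEnergy0)
  expect_gt(max(f[spotRows, , ]), 50)
})

test_that("uniform flow is recovered within 10% for >= 90% of valid vectors", {
  ps <- 0.1; dt <- 2
  v <- c(0.5 * ps / dt, 0)                       # 0.5 px/frame
  sim <- simulateFlowStack(list(type = "uniform", v = v),
                           imageSize = c(48, 48), nFrames = 16,
                           pixelSize = ps, frameInterval = dt,
                           noiseSd = 2, seed = 2)
  vf <- sticsVelocity(sim$stack)
  vv <- velocityVectors(vf)
  ok <- vv$valid
  truth <- sqrt(sum(v^2)) * 60                   # um/min
  expect_gt(sum(ok), 0.5 * nrow(vv))
  expect_gte(mean(abs(vv$speed[ok] - truth) / truth < 0.1), 0.9)
  # direction bias < 5 degrees for the median vector
  ang <- atan2(median(vv$vy[ok]), median(vv$vx[ok])) * 180 / pi
  expect_lt(abs(ang), 5)
})

test_that("a zero-flow stack yields near-zero speeds", {
  sim <- simulateFlowStack(list(type = "zero"), imageSize = c(48, 48),
                           nFrames = 16, pixelSize = 0.1, frameInterval = 2,
                           noiseSd = 2, seed = 3)
  vf <- sticsVelocity(sim$stack)
  vv <- velocityVectors(vf)
  expect_lt(median(vv$speed[vv$valid]), 0.15)    # 10% of 1.5 um/min
})

test_that("radial inward flow gives small angular errors", {
  sim <- simulateFlowStack(list(type = "radial", speed = 0.025),
                           imageSize = c(64, 64), nFrames = 16,
                           pixelSize = 0.1, frameInterval = 2,
                           noiseSd = 2, seed = 4)
  vf <- sticsVelocity(sim$stack)
  vv <- velocityVectors(vf)
  vv <- vv[vv$valid & vv$speed > 0, ]
  ctr <- c(3.2, 3.2)
  cosang <- ((ctr[1] - vv$x) * vv$vx + (ctr[2] - vv$y) * vv$vy) /
    sqrt(vv$vx^2 + vv$vy^2) / sqrt((ctr[1] - vv$x)^2 + (ctr[2] - vv$y)^2)
  err <- acos(pmin(1, pmax(-1, cosang[is.finite(cosang)]))) * 180 / pi
  expect_lt(median(err), 15)
})

test_that("directional coherence is the cosine towards the centroid", {
  mk <- function(x, y, vx, vy)
    new("VelocityField",
        vectors = data.frame(x = x, y = y, window = 1L, tmid = 0,
                             vx = vx, vy = vy,
                             speed = sqrt(vx^2 + vy^2), valid = TRUE),
        pixelSize = 0.1, frameInterval = 2, sub = 8L, toi = 5L)
  ctr <- c(5, 5)
  expect_equal(directionalCoherence(mk(1, 5, 1, 0), ctr)@values, 1)
  expect_equal(directionalCoherence(mk(1, 5, -1, 0), ctr)@values, -1)
  expect_equal(directionalCoherence(mk(1, 5, 0, 1), ctr)@values, 0)
  # zero-length vectors are excluded
  res <- directionalCoherence(mk(c(1, 2), c(5, 5), c(1, 0), c(0, 0)), ctr)
  expect_equal(res@n, 1L)
  expect_equal(res@inwardFraction, 1)
})

test_that("coherence distribution is stable under a 90-degree rotation", {
  sim <- simulateFlowStack(list(type = "radial", speed = 0.025),
                           imageSize = c(48, 48), nFrames = 10,
                           pixelSize = 0.1, frameInterval = 2,
                           noiseSd = 1, seed = 6)
  st <- sim$stack
  rot <- imageStack(array(apply(st, 3, function(fr) t(fr[nrow(fr):1, ])),
                          dim(st)), 0.1, 2)
  c1 <- directionalCoherence(sticsVelocity(st), c(2.4, 2.4))
  c2 <- directionalCoherence(sticsVelocity(rot), c(2.4, 2.4))
  expect_lt(abs(c1@inwardFraction - c2@inwardFraction), 0.05)
})

test_that("two-proportion z-test matches the pooled-formula oracle", {
  eq <- compareFlowFractions(0.2, 100, 0.2, 100)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)

  r <- compareFlowFractions(143 / 1000, 1000, 450 / 1000, 1000)
  pool <- (143 + 450) / 2000
  zHand <- (0.143 - 0.45) / sqrt(pool * (1 - pool) * (2 / 1000))
  expect_equal(r$z, zHand, tolerance = 1e-12)
  expect_equal(r$p, 2 * pnorm(-abs(zHand)), tolerance = 1e-12)
  # prop.test's chi-squared statistic is z^2
  pt <- prop.test(c(143, 450), c(1000, 1000), correct = FALSE)
  expect_equal(unname(pt$statistic), r$z^2, tolerance = 1e-9)

  sw <- compareFlowFractions(450 / 1000, 1000, 143 / 1000, 1000)
  expect_equal(sw$z, -r$z)
  expect_equal(sw$p, r$p)

  deg <- compareFlowFractions(0, 50, 0, 70)
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
})
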