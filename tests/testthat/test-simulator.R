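test_that("grid enumeration follows the lattice in row-major order", {
  g <- makeGrid(8, nx = 2L, ny = 1L, layerElevations = 0)
  expect_equal(unname(as.matrix(gridNodes(g)[, c("x", "y", "z")])),
               rbind(c(0, 0, 0), c(8, 0, 0)))
  g3 <- makeGrid(8, 5L, 4L, c(0, 9.6, 19.2))
  expect_identical(nrow(gridNodes(g3)), 60L)
  expect_identical(trueDistances(g3, 1L, 2L), 8)
  expect_error(makeGrid(0), "pitch")
  expect_error(makeGrid(8, 1L, 1L, 0), "at least 2 nodes")
})

test_that("closed-form node distances match coordinate geometry", {
  g <- makeGrid(8, 5L, 4L, c(0, 9.6, 19.2))
  n <- gridNodes(g)
  set.seed(5)
  i <- sample(n$node_id, 30, replace = TRUE)
  j <- sample(n$node_id, 30, replace = TRUE)
  keep <- i != j
  ref <- sqrt((n$x[i] - n$x[j])^2 + (n$y[i] - n$y[j])^2 + (n$z[i] - n$z[j])^2)
  expect_equal(trueDistances(g, i[keep], j[keep]), ref[keep])
})

test_that("a zero-amplitude field is the exact identity on positions", {
  g <- makeGrid()
  spec <- distortionField(amplitudeMm = 0, angleNoiseDeg = 0, carmDistanceCm = 10)
  out <- applyDistortion(g, spec)
  expect_identical(out$x, gridNodes(g)$x)
  expect_identical(out$z, gridNodes(g)$z)
  expect_true(all(out$phi_x == 0))
  expect_equal(out$q, rep(spec@qualityBase, 60) +
                 out$q - spec@qualityBase)  # q finite, baseline-only
})

test_that("distortion is deterministic for a fixed spec and seed", {
  g <- makeGrid()
  spec <- distortionField(carmDistanceCm = 8, seed = 11L)
  expect_identical(applyDistortion(g, spec), applyDistortion(g, spec))
})

test_that("field magnitude decreases with C-arm distance and displaces z most", {
  g <- makeGrid()
  near <- distortionField(carmDistanceCm = 8, seed = 4L)
  far <- distortionField(carmDistanceCm = 50, seed = 4L)
  expect_gt(effectiveAmplitude(near), effectiveAmplitude(far))

  acq0 <- acquisitionSpec(samplesPerPoint = 1L, noiseSdMm = 0,
                          qualityNoiseSd = 0, angleNoiseSdDeg = 0, seed = 1L)
  rmseOf <- function(spec) {
    d <- simulateAcquisition(applyDistortion(g, spec), acq0, "e", "C",
                             carmDistance = spec@carmDistanceCm)
    errorRmse(displacementError(buildDisplacementPairs(d, g)))
  }
  expect_gt(rmseOf(near), rmseOf(far))

  ev <- evaluateField(realizeField(near, g),
                      as.matrix(gridNodes(g)[, c("x", "y", "z")]))
  rmsAxis <- sqrt(colMeans(ev$displacement^2))
  expect_gt(rmsAxis[3], rmsAxis[1])
  expect_gt(rmsAxis[3], rmsAxis[2])
})

test_that("quality grows with local displacement magnitude", {
  g <- makeGrid()
  spec <- distortionField(carmDistanceCm = 8, seed = 9L, qualityBaselineSd = 0)
  ev <- evaluateField(realizeField(spec, g),
                      as.matrix(gridNodes(g)[, c("x", "y", "z")]))
  mag <- sqrt(rowSums(ev$displacement^2))
  expect_equal(ev$q, spec@qualityBase + spec@qualityCoupling * mag)
})

test_that("field evaluation is smooth: nearby points move almost identically", {
  g <- makeGrid()
  f <- realizeField(distortionField(carmDistanceCm = 8, seed = 2L), g)
  set.seed(3)
  base <- cbind(runif(40, 0, 32), runif(40, 0, 24), runif(40, 0, 19))
  d1 <- evaluateField(f, base)$displacement
  near <- evaluateField(f, base + 0.5)$displacement   # well below length scale
  farr <- evaluateField(f, base + 12)$displacement    # beyond length scale
  nearDiff <- sqrt(rowSums((near - d1)^2))
  farDiff <- sqrt(rowSums((farr - d1)^2))
  expect_lt(mean(nearDiff), 0.25 * mean(farDiff))
  expect_lt(max(nearDiff), max(farDiff))
})

test_that("averaged acquisition reproduces the distorted truth as noise vanishes", {
  g <- makeGrid()
  distorted <- applyDistortion(g, distortionField(carmDistanceCm = 11, seed = 3L))
  acq0 <- acquisitionSpec(samplesPerPoint = 5L, noiseSdMm = 0,
                          qualityNoiseSd = 0, angleNoiseSdDeg = 0, seed = 1L)
  d <- simulateAcquisition(distorted, acq0, "e", "C", carmDistance = 11)
  expect_equal(measurements(d)$z, distorted$z)
  expect_equal(measurements(d)$x, distorted$x)
})

test_that("averaging suppresses noise like 1/sqrt(n)", {
  g <- makeGrid(8, 10L, 10L, c(0, 9.6))   # 200 nodes for a stable estimate
  distorted <- applyDistortion(g, distortionField(amplitudeMm = 0, angleNoiseDeg = 0,
                                                  carmDistanceCm = 10, seed = 1L))
  one <- simulateAcquisition(distorted, acquisitionSpec(1L, noiseSdMm = 1, seed = 7L),
                             "a", "C", carmDistance = 10)
  resid1 <- measurements(one)$x - distorted$x
  expect_equal(stats::sd(resid1), 1, tolerance = 0.15)

  many <- simulateAcquisition(distorted, acquisitionSpec(500L, noiseSdMm = 1, seed = 8L),
                              "b", "C", carmDistance = 10)
  few <- simulateAcquisition(distorted, acquisitionSpec(5L, noiseSdMm = 1, seed = 9L),
                             "c", "C", carmDistance = 10)
  dev <- function(d) sqrt(mean((measurements(d)$x - distorted$x)^2))
  expect_lt(dev(many), dev(few))
  expect_equal(stats::sd(measurements(many)$x - distorted$x), 1 / sqrt(500),
               tolerance = 0.2)
})

test_that("environment suites are complete, layered, ordered and reproducible", {
  g <- makeGrid()
  cfg <- suiteConfig(seed = 5L, acquisition = list(samplesPerPoint = 25L))
  suite <- generateEnvironmentSuite(g, cfg)
  expect_identical(length(suite), 9L)  # 1 lab + 8 C-arm environments
  expect_identical(envDomain(suite$laboratory), "L")

  ## laboratory restricted to layers 1-2: no layer-3 nodes
  labNodes <- gridNodes(g)$layer[match(nodeIndex(suite$laboratory),
                                       gridNodes(g)$node_id)]
  expect_true(all(labNodes %in% c(1L, 2L)))
  expect_identical(nrow(measurements(suite$carm_08cm)), 60L)

  rmse <- vapply(suite, function(d)
    errorRmse(displacementError(buildDisplacementPairs(d, g))), numeric(1))
  expect_gt(rmse[["carm_08cm"]], rmse[["carm_11cm"]])
  expect_gt(rmse[["carm_11cm"]], rmse[["carm_50cm"]])
  expect_gt(rmse[["carm_50cm"]], rmse[["laboratory"]])

  again <- generateEnvironmentSuite(g, cfg)
  expect_identical(lapply(suite, measurements), lapply(again, measurements))
})

test_that("a zero-amplitude zero-noise suite has exactly zero displacement error", {
  g <- makeGrid()
  cfg <- suiteConfig(
    seed = 2L,
    field = list(amplitudeMm = 0, angleNoiseDeg = 0, qualityBaselineSd = 0),
    intrinsic = list(scaleSd = 0, translationSd = 0),
    acquisition = list(samplesPerPoint = 1L, noiseSdMm = 0,
                       qualityNoiseSd = 0, angleNoiseSdDeg = 0))
  suite <- generateEnvironmentSuite(g, cfg)
  for (d in suite)
    expect_identical(errorRmse(displacementError(buildDisplacementPairs(d, g))), 0)
})

test_that("suite config validates its inputs", {
  expect_error(suiteConfig(carm = data.frame(name = "a")), "missing column")
  expect_error(suiteConfig(labName = "carm_08cm"), "unique")
})
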