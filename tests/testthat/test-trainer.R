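## plain-loop reference forward pass, independent of the package's vectorized one
refForward <- function(net, X) {
  out <- matrix(NA_real_, nrow(X), net@dims[length(net@dims)])
  for (r in seq_len(nrow(X))) {
    h <- X[r, ]
    for (k in seq_along(net@weights)) {
      a <- as.numeric(h %*% net@weights[[k]]) + net@biases[[k]]
      if (k < length(net@weights)) {
        h <- ifelse(a > 0, a, net@hiddenSlope * a)
      } else if (net@outputActivation == "sigmoid") {
        h <- 1 / (1 + exp(-a))
      } else h <- a
    }
    out[r, ] <- h
  }
  out
}

refBce <- function(p, y) mean(-(y * log(p) + (1 - y) * log(1 - p)))

test_that("the learning rate is constant then decays linearly to zero", {
  cfg <- trainConfig()
  expect_identical(learningRate(0, cfg), 0.0005)
  expect_identical(learningRate(100, cfg), 0.0005)
  expect_identical(learningRate(150, cfg), 0.00025)
  expect_identical(learningRate(200, cfg), 0)
  expect_identical(learningRate(50, cfg), 0.0005)
})

test_that("adversarial loss equals its closed form for an uninformative discriminator", {
  pair <- randomModelPair(4L)
  ## zero the discriminator heads: sigmoid(0) = 0.5 for every input
  for (slot in c("dCL", "dLC")) {
    d <- slot(pair, slot)
    nl <- length(d@weights)
    d@weights[[nl]] <- d@weights[[nl]] * 0
    d@biases[[nl]] <- 0
    slot(pair, slot) <- d
  }
  set.seed(3)
  bC <- matrix(runif(7 * 8), 8, 7)
  bL <- matrix(runif(7 * 8), 8, 7)
  expect_equal(adversarialLoss(bC, bL, pair, labelValid = 1), 2 * -log(0.5),
               tolerance = 1e-12)
})

test_that("generator losses match independent reference computations", {
  pair <- randomModelPair(7L)
  set.seed(11)
  bC <- matrix(runif(7 * 6), 6, 7)
  bL <- matrix(runif(7 * 5), 5, 7)
  lv <- runif(1, 0.8, 1)

  fakeL <- cbind(bC[, 1:2], refForward(pair@gCL, bC))
  fakeC <- cbind(bL[, 1:2], refForward(pair@gLC, bL))
  refAdv <- refBce(refForward(pair@dCL, fakeL), lv) +
    refBce(refForward(pair@dLC, fakeC), lv)
  expect_equal(adversarialLoss(bC, bL, pair, labelValid = lv), refAdv,
               tolerance = 1e-9)

  recovC <- refForward(pair@gLC, fakeL)
  recovL <- refForward(pair@gCL, fakeC)
  refRecC <- sum(abs(recovC - bC[, 3:7])) / (6 * 7)
  refRecL <- sum(abs(recovL - bL[, 3:7])) / (5 * 7)
  cl <- cycleLoss(bC, bL, pair)
  expect_equal(unname(cl["recovC"]), refRecC, tolerance = 1e-9)
  expect_equal(unname(cl["recovL"]), refRecL, tolerance = 1e-9)
  expect_identical(unname(cl["cycle"]), unname(cl["recovL"] + cl["recovC"]))
  expect_error(cycleLoss(bC[0, , drop = FALSE], bL, pair), "empty")
})

test_that("cycle loss follows the mean-over-batch-and-7-channels convention", {
  bounds <- new("NormalizationBounds",
                lower = stats::setNames(rep(0, 7), emtChannels()),
                upper = stats::setNames(rep(1, 7), emtChannels()))
  pair <- randomModelPair(1L, bounds = bounds)
  gShift <- identityGenerator()
  gShift@biases[[4]][1] <- 0.1          # C->L offsets z by 0.1 normalized
  pair@gCL <- gShift
  pair@gLC <- identityGenerator()
  set.seed(2)
  bC <- matrix(runif(7 * 10, 0.05, 0.85), 10, 7)
  bL <- matrix(runif(7 * 10, 0.05, 0.85), 10, 7)
  cl <- cycleLoss(bC, bL, pair)
  expect_equal(unname(cl["recovC"]), 0.1 / 7, tolerance = 1e-12)
  expect_equal(unname(cl["recovL"]), 0.1 / 7, tolerance = 1e-12)

  pair@gCL <- identityGenerator()
  expect_equal(unname(cycleLoss(bC, bL, pair)["cycle"]), 0, tolerance = 1e-12)
})

test_that("compensation loss is the MSE of pair distances in millimetres", {
  grid2 <- makeGrid(8, 2L, 1L, 0)
  lo <- stats::setNames(rep(0, 7), emtChannels())
  hi <- stats::setNames(c(10, 10, 10, 1, 1, 1, 1), emtChannels())
  bounds <- new("NormalizationBounds", lower = lo, upper = hi)
  pair <- randomModelPair(1L, bounds = bounds)
  pair@gCL <- identityGenerator()
  ## two points 9 mm apart in x, same z -> true lattice distance 8 mm
  bC <- rbind(c(0.0, 0, 0.2, 0.5, 0.5, 0.5, 0.5),
              c(0.9, 0, 0.2, 0.5, 0.5, 0.5, 0.5))
  expect_equal(compensationLoss(bC, c(1L, 2L), pair, grid2), 1, tolerance = 1e-12)
  expect_error(compensationLoss(bC[1, , drop = FALSE], 1L, pair, grid2),
               "at least 2")

  ## translated points reproducing the lattice exactly -> zero loss
  grid3 <- makeGrid(8, 3L, 1L, 0)
  bT <- cbind(c(0, 0.8, 1.6), 0, 0, 0.5, 0.5, 0.5, 0.5)  # x = 0, 8, 16 mm
  expect_equal(compensationLoss(bT, 1:3, pair, grid3,
                                pairs = rbind(c(1L, 2L), c(2L, 3L))), 0,
               tolerance = 1e-12)

  ## random case against a double-loop reference
  set.seed(8)
  pairR <- randomModelPair(3L, bounds = bounds)
  bR <- matrix(runif(7 * 6), 6, 7)
  ids <- c(1L, 2L, 2L, 3L, 1L, 3L)
  gen <- refForward(pairR@gCL, bR)
  P <- cbind(bR[, 1] * 10, bR[, 2] * 10, gen[, 1] * 10)
  ref <- mean(sapply(1:3, function(k) {
    a <- 2 * k - 1; b <- 2 * k
    (sqrt(sum((P[a, ] - P[b, ])^2)) - trueDistances(grid3, ids[a], ids[b]))^2
  }))
  expect_equal(compensationLoss(bR, ids, pairR, grid3), ref, tolerance = 1e-9)
})

test_that("the total generator loss is the exact weighted sum", {
  cfg <- trainConfig()
  parts <- list(lAdv = 1, lCycle = 1, lComp = 1)
  expect_identical(totalGeneratorLoss(parts, cfg), 0.5 + 10 + 1e-5)
  expect_identical(totalGeneratorLoss(list(lAdv = 0, lCycle = 0, lComp = 0), cfg), 0)
  vcfg <- trainConfig(mode = "vanilla_gan")
  expect_identical(totalGeneratorLoss(parts, vcfg), 0.5 + 1e-5)
})

test_that("short training runs are reproducible and log exact loss identities", {
  setup <- quickTrainSetup(2L)
  cfg <- trainConfig(totalEpochs = 5L, decayStartEpoch = 2L, ensembleSize = 1L,
                     seed = 9L)
  p1 <- trainModelPair(cfg, setup$dataC, setup$dataL, setup$grid)
  p2 <- trainModelPair(cfg, setup$dataC, setup$dataL, setup$grid)
  expect_identical(p1@gCL@weights, p2@gCL@weights)
  expect_identical(p1@dLC@weights, p2@dLC@weights)
  expect_identical(trainingLog(p1), trainingLog(p2))

  log <- trainingLog(p1)
  expect_identical(log$lCycle, log$lRecovL + log$lRecovC)
  expect_identical(log$lTotal,
                   cfg@lambdaAdv * log$lAdv + cfg@lambdaCycle * log$lCycle +
                     cfg@lambdaComp * log$lComp)
  expect_equal(unique(log$lr[log$epoch < 2]), cfg@lr)
  expect_lt(max(log$lr[log$epoch == 4]), cfg@lr)
})

test_that("vanilla mode removes the cycle term from the total loss", {
  setup <- quickTrainSetup(3L)
  cfg <- trainConfig(totalEpochs = 3L, decayStartEpoch = 1L, ensembleSize = 1L,
                     mode = "vanilla_gan", seed = 4L)
  p <- trainModelPair(cfg, setup$dataC, setup$dataL, setup$grid)
  log <- trainingLog(p)
  expect_identical(log$lTotal, cfg@lambdaAdv * log$lAdv + cfg@lambdaComp * log$lComp)
  expect_true(all(log$lCycle == 0))
  expect_identical(p@mode, "vanilla_gan")
})

test_that("training rejects wrong-domain or empty inputs", {
  setup <- quickTrainSetup(1L)
  cfg <- trainConfig(totalEpochs = 2L, decayStartEpoch = 1L, seed = 1L)
  expect_error(trainModelPair(cfg, setup$dataL, setup$dataL, setup$grid),
               "domain C")
  expect_error(trainModelPair(cfg, list(), setup$dataL, setup$grid),
               "at least one dataset")
})

test_that("ensembles derive member seeds from the master seed", {
  setup <- quickTrainSetup(4L)
  cfg <- trainConfig(totalEpochs = 3L, decayStartEpoch = 1L, ensembleSize = 1L,
                     seed = 21L)
  single <- trainModelPair(cfg, setup$dataC, setup$dataL, setup$grid)
  ens1 <- trainEnsemble(cfg, setup$dataC, setup$dataL, setup$grid)
  expect_identical(length(ens1), 1L)
  expect_identical(ens1[[1]]@gCL@weights, single@gCL@weights)

  cfg2 <- cfg; cfg2@ensembleSize <- 2L
  ens2 <- trainEnsemble(cfg2, setup$dataC, setup$dataL, setup$grid)
  expect_false(identical(ens2[[1]]@gCL@weights, ens2[[2]]@gCL@weights))
})

test_that("ensemble compensation averages members and reports their spread", {
  g <- makeGrid()
  d <- environmentDataset("e", "C", randomSamples(20, g, seed = 6), carmDistance = 9)
  pair <- randomModelPair(2L)
  one <- ensembleCompensate(list(pair), d)
  expect_identical(sigmaPred(one), rep(0, 20))
  expect_equal(measurements(one), measurements(compensatePoints(pair, d)))

  same <- ensembleCompensate(list(pair, pair, pair), d)
  expect_equal(sigmaPred(same), rep(0, 20), tolerance = 1e-12)

  members <- lapply(c(2L, 31L, 77L), randomModelPair)
  res <- ensembleCompensate(members, d)
  outs <- lapply(members, function(m) measurements(compensatePoints(m, d)))
  expect_identical(measurements(res)$x, measurements(d)$x)
  expect_equal(measurements(res)$z, rowMeans(sapply(outs, `[[`, "z")),
               tolerance = 1e-12)
  expect_equal(sigmaPred(res), predictionSpread(outs)$perPoint, tolerance = 1e-12)
})

test_that("validation-based selection never returns a model worse than its best score", {
  setup <- quickTrainSetup(5L)
  dataV <- setup$suite[c("carm_10cm", "carm_30cm")]
  cfg <- trainConfig(totalEpochs = 6L, decayStartEpoch = 3L, ensembleSize = 1L,
                     seed = 2L)
  p <- trainModelPair(cfg, setup$dataC, setup$dataL, setup$grid, dataV = dataV)
  v <- attr(trainingLog(p), "validation")
  expect_true(is.data.frame(v) && nrow(v) >= 2)
  ## recompute the selected model's validation score: equals the recorded minimum
  errs <- unlist(lapply(dataV, function(d) {
    ds <- buildDisplacementPairs(environmentDataset("v", "L",
            measurements(compensatePoints(p, d))), setup$grid)
    ds@measuredDist - ds@trueDist
  }))
  expect_equal(sqrt(mean(errs^2)), min(v$valRmse), tolerance = 1e-9)
})
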