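test_that("network construction is deterministic per seed with the stated shapes", {
  g1 <- buildGenerator(42L)
  g2 <- buildGenerator(42L)
  expect_identical(g1@weights, g2@weights)
  expect_identical(g1@dims, c(7L, 16L, 16L, 16L, 5L))
  d1 <- buildDiscriminator(42L)
  expect_identical(d1@dims, c(7L, 16L, 16L, 1L))
  expect_false(identical(buildGenerator(1L)@weights, buildGenerator(2L)@weights))

  ## closed-form parameter counts for the dense stacks
  expect_identical(parameterCount(g1),
                   (7L * 16L + 16L) + 2L * (16L * 16L + 16L) + (16L * 5L + 5L))
  expect_identical(parameterCount(d1),
                   (7L * 16L + 16L) + (16L * 16L + 16L) + (16L * 1L + 1L))
})

test_that("discriminator outputs are strictly inside (0, 1) for arbitrary inputs", {
  d <- buildDiscriminator(3L)
  set.seed(1)
  X <- matrix(rnorm(700, sd = 50), 100, 7)
  p <- cycleEMT:::netForward(d, X)
  expect_true(all(p > 0 & p < 1))
  expect_error(cycleEMT:::netForward(d, matrix(0, 2, 6)), "dimensionality")
})

test_that("a fresh generator with identity initialization is a near-no-op compensator", {
  g <- buildGenerator(5L)
  set.seed(2)
  X <- matrix(runif(70), 10, 7)
  out <- cycleEMT:::netForward(g, X)
  expect_lt(max(abs(out - X[, 3:7])), 0.25)
  gid <- identityGenerator()
  expect_equal(cycleEMT:::netForward(gid, X), X[, 3:7], tolerance = 1e-12)
})

test_that("analytic gradients agree with central finite differences", {
  fc <- cycleEMT:::.forwardCache
  bw <- cycleEMT:::.backward
  set.seed(6)
  net <- buildGenerator(8L, identityInit = FALSE)
  X <- matrix(runif(42), 6, 7)
  R <- matrix(rnorm(30), 6, 5)           # loss = sum(out * R)
  bk <- bw(net, fc(net, X), R)
  eps <- 1e-6
  for (k in seq_along(net@weights)) {
    for (idx in sample(length(net@weights[[k]]), 4)) {
      np <- net; np@weights[[k]][idx] <- np@weights[[k]][idx] + eps
      nm <- net; nm@weights[[k]][idx] <- nm@weights[[k]][idx] - eps
      num <- (sum(fc(np, X)$out * R) - sum(fc(nm, X)$out * R)) / (2 * eps)
      expect_equal(bk$dW[[k]][idx], num, tolerance = 1e-5)
    }
  }
  for (i in sample(length(X), 6)) {
    Xp <- X; Xp[i] <- Xp[i] + eps
    Xm <- X; Xm[i] <- Xm[i] - eps
    num <- (sum(fc(net, Xp)$out * R) - sum(fc(net, Xm)$out * R)) / (2 * eps)
    expect_equal(bk$dX[i], num, tolerance = 1e-5)
  }

  ## BCE-through-sigmoid path on a discriminator
  d <- buildDiscriminator(9L)
  y <- runif(6, 0.8, 1)
  cache <- fc(d, X)
  bk2 <- bw(d, cache, (cache$out - y) / 6, fromPre = TRUE)
  lossAt <- function(n) mean(cycleEMT:::.bce(fc(n, X)$out, y))
  for (k in seq_along(d@weights)) {
    idx <- sample(length(d@weights[[k]]), 3)
    for (i in idx) {
      np <- d; np@weights[[k]][i] <- np@weights[[k]][i] + eps
      nm <- d; nm@weights[[k]][i] <- nm@weights[[k]][i] - eps
      expect_equal(bk2$dW[[k]][i], (lossAt(np) - lossAt(nm)) / (2 * eps),
                   tolerance = 1e-5)
    }
  }
})

test_that("compensation passes x and y through bit-exactly for any weights", {
  g <- makeGrid()
  for (seed in c(1L, 77L, 1234L)) {
    pair <- randomModelPair(seed, bounds = randomBounds(2))
    df <- randomSamples(1000, g, seed = seed)
    out <- compensatePoints(pair, df)
    expect_identical(out$x, df$x)
    expect_identical(out$y, df$y)
    expect_false(identical(out$z, df$z))
    th <- as.matrix(out[, c("phi_x", "phi_y", "phi_z")])
    expect_true(all(th >= -180 & th < 180))
  }
})

test_that("a zeroed linear head reduces compensation to the denormalized bias", {
  bounds <- randomBounds(3)
  pair <- randomModelPair(1L, bounds = bounds)
  gz <- pair@gCL
  nl <- length(gz@weights)
  gz@weights[[nl]] <- gz@weights[[nl]] * 0
  gz@biases[[nl]] <- c(0.25, 0.5, 0.5, 0.5, 0.5)
  pair@gCL <- gz
  df <- randomSamples(5, makeGrid(), seed = 1)
  out <- compensatePoints(pair, df)
  expectZ <- bounds@lower[["z"]] + 0.25 * (bounds@upper[["z"]] - bounds@lower[["z"]])
  expect_equal(out$z, rep(unname(expectZ), 5), tolerance = 1e-12)
})

test_that("model checkpoints round-trip through JSON", {
  pair <- randomModelPair(12L)
  path <- withr::local_tempfile(fileext = ".json")
  saveModelPair(pair, path)
  back <- readModelPair(path)
  df <- randomSamples(25, makeGrid(), seed = 5)
  expect_equal(measurements(compensatePoints(back,
                 environmentDataset("e", "C", df, carmDistance = 9))),
               measurements(compensatePoints(pair,
                 environmentDataset("e", "C", df, carmDistance = 9))),
               tolerance = 1e-12)
  expect_identical(back@mode, pair@mode)
  expect_error(readModelPair(withr::local_tempfile(lines = "{}", fileext = ".json")),
               "not a cycleEMT model")
})
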