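test_that("pair schemes produce the expected pair sets", {
  g2 <- makeGrid(8, 2L, 1L, 0)
  d2 <- environmentDataset("a", "L", emtSamples(1:2, x = c(0, 8.5), y = 0, z = 0, q = 1))
  ds <- buildDisplacementPairs(d2, g2)
  expect_identical(nPairs(ds), 1L)
  expect_identical(ds@trueDist, 8)
  expect_equal(ds@measuredDist, 8.5)

  g <- makeGrid()
  d <- environmentDataset("b", "C", randomSamples(60, g, seed = 2)[order(randomSamples(60, g, seed = 2)$node_id), ],
                          carmDistance = 9)
  d@samples$node_id <- gridNodes(g)$node_id  # one sample per node
  ap <- buildDisplacementPairs(d, g, "all-pairs")
  expect_identical(nPairs(ap), 1770L)  # 60 * 59 / 2

  ## lattice-neighbor count against brute-force enumeration over node indices
  ln <- buildDisplacementPairs(d, g)
  nodes <- gridNodes(g)
  cnt <- 0L
  for (i in 1:59) for (j in (i + 1):60) {
    di <- abs(nodes$ix[i] - nodes$ix[j])
    dj <- abs(nodes$iy[i] - nodes$iy[j])
    dl <- abs(nodes$layer[i] - nodes$layer[j])
    if ((dl == 0 && di + dj == 1) || (dl == 1 && di == 0 && dj == 0)) cnt <- cnt + 1L
  }
  expect_identical(nPairs(ln), cnt)
  expect_error(buildDisplacementPairs(
    environmentDataset("c", "L", emtSamples(c(1, 999), x = c(0, 1), y = 0, z = 0, q = 1)), g),
    "unknown grid node")
})

test_that("displacement error matches a double-loop reference to 1e-12", {
  mkset <- function(n, seed) {
    set.seed(seed)
    new("DisplacementSet",
        pairs = matrix(c(seq_len(n), seq_len(n) + n), ncol = 2L),
        nodePairs = matrix(1L, n, 2L),
        measuredDist = runif(n, 1, 30), trueDist = runif(n, 1, 30),
        scheme = "synthetic")
  }
  for (seed in 1:100) {
    ds <- mkset(sample(1:50, 1), seed)
    s <- displacementError(ds)
    ## independent reference
    errs <- numeric(0)
    for (k in seq_along(ds@measuredDist))
      errs <- c(errs, ds@measuredDist[k] - ds@trueDist[k])
    refR <- sqrt(sum(errs^2) / length(errs))
    refS <- if (length(errs) > 1) sqrt(sum((errs - mean(errs))^2) / (length(errs) - 1)) else 0
    expect_equal(errorRmse(s), refR, tolerance = 1e-12)
    expect_equal(errorSd(s), refS, tolerance = 1e-12)
  }
})

test_that("displacement error has the stated edge behaviour", {
  ds <- new("DisplacementSet", pairs = matrix(c(1L, 2L), 1, 2),
            nodePairs = matrix(c(1L, 2L), 1, 2),
            measuredDist = 9, trueDist = 8, scheme = "s")
  s <- displacementError(ds)
  expect_identical(errorRmse(s), 1)
  expect_identical(errorSd(s), 0)
  ds0 <- new("DisplacementSet", pairs = matrix(integer(0), 0, 2),
             nodePairs = matrix(integer(0), 0, 2),
             measuredDist = numeric(0), trueDist = numeric(0), scheme = "s")
  expect_error(displacementError(ds0), "empty")
})

test_that("displacement error is invariant to rigid motion of the point set", {
  g <- makeGrid()
  d <- quickSuite(3, g)[["carm_08cm"]]
  base <- errorRmse(displacementError(buildDisplacementPairs(d, g)))
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  p <- as.matrix(measurements(d)[, c("x", "y", "z")]) %*% t(R)
  m <- measurements(d)
  m$x <- p[, 1] + 100; m$y <- p[, 2] - 55; m$z <- p[, 3] + 7
  dRot <- environmentDataset("rot", "C", m, carmDistance = 8)
  expect_equal(errorRmse(displacementError(buildDisplacementPairs(dRot, g))), base,
               tolerance = 1e-10)
})

test_that("prediction spread is zero for identical members and matches closed forms", {
  g <- makeGrid()
  df <- randomSamples(20, g, seed = 4)
  expect_identical(predictionSpread(list(df, df, df))$perPoint, rep(0, 20))

  df2 <- df
  df2$z <- df$z + 2
  sp <- predictionSpread(list(df, df2))
  expect_equal(sp$perPoint, rep(stats::sd(c(0, 2)), 20))

  expect_error(predictionSpread(list(df)), "at least 2")
  expect_error(predictionSpread(list(df, df[-1, ])), "mismatched")
})

test_that("prediction spread matches brute force and is member-order invariant", {
  g <- makeGrid()
  set.seed(9)
  members <- lapply(1:10, function(i) {
    m <- randomSamples(15, g, seed = 1)
    m$x <- m$x + rnorm(15, 0, 0.3)
    m$y <- m$y + rnorm(15, 0, 0.3)
    m$z <- m$z + rnorm(15, 0, 0.8)
    m
  })
  sp <- predictionSpread(members)
  ref <- sapply(1:15, function(i) {
    xs <- sapply(members, function(m) m$x[i])
    ys <- sapply(members, function(m) m$y[i])
    zs <- sapply(members, function(m) m$z[i])
    sqrt(stats::var(xs) + stats::var(ys) + stats::var(zs))
  })
  expect_equal(sp$perPoint, ref, tolerance = 1e-12)
  expect_equal(sp$aggregate, mean(ref), tolerance = 1e-12)
  expect_equal(predictionSpread(rev(members))$perPoint, sp$perPoint)
})

test_that("rotational stability uses circular statistics across the wrap", {
  traj <- emtSamples(1:2, x = c(0, 8), y = 0, z = 0, q = 1,
                     phi_x = 0, phi_y = 0, phi_z = c(359, 1))
  s <- rotationalStability(traj)
  az <- s[s$role == "azimuth", ]
  expect_lt(az$circSd, 2)      # ~1 degree, never ~179
  expect_lt(abs(az$circMean), 1)
  expect_equal(az$maxDrift, 2)

  const <- emtSamples(1:5, x = 8 * (0:4), y = 0, z = 0, q = 1,
                      phi_x = 12, phi_y = -3, phi_z = 0.5)
  sc <- rotationalStability(const)
  expect_equal(sc$circSd, rep(0, 3), tolerance = 1e-5)
  expect_equal(sc$maxDrift, rep(0, 3))
  expect_error(rotationalStability(const[1, ]), "at least 2")
})
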