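## Shared fixtures, all generated in code.

tinyGrid <- function() makeGrid(8, nx = 3L, ny = 2L, layerElevations = c(0, 9.6))

## A fast low-noise suite for unit tests: few averaged samples per point.
quickSuite <- function(seed = 1L, grid = makeGrid()) {
  generateEnvironmentSuite(grid, suiteConfig(
    seed = seed, acquisition = list(samplesPerPoint = 25L)))
}

## Random 7-channel sample frame with node ids drawn from a grid.
randomSamples <- function(n, grid, seed = 1L) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    ids <- sample(gridNodes(grid)$node_id, n, replace = TRUE)
    emtSamples(ids,
               x = runif(n, -40, 40), y = runif(n, -40, 40),
               z = runif(n, -5, 25), q = runif(n, 0, 12),
               phi_x = runif(n, -180, 180), phi_y = runif(n, -180, 180),
               phi_z = runif(n, -180, 180))
  })
}

randomBounds <- function(seed = 1L) {
  set.seed(seed)
  lo <- stats::setNames(runif(7, -20, 0), emtChannels())
  new("NormalizationBounds", lower = lo, upper = lo + runif(7, 5, 40))
}

## An untrained model pair with random (non-identity) generator weights.
randomModelPair <- function(seed = 1L, bounds = randomBounds(seed)) {
  new("ModelPair",
      gCL = buildGenerator(seed, identityInit = FALSE),
      gLC = buildGenerator(seed + 1L, identityInit = FALSE),
      dCL = buildDiscriminator(seed + 2L),
      dLC = buildDiscriminator(seed + 3L),
      bounds = bounds, seed = as.integer(seed), mode = "cyclegan",
      log = data.frame())
}

## A generator that is the exact identity on the translated channels for
## inputs with nonnegative normalized values (leaky rectifier linear region).
identityGenerator <- function() {
  dims <- c(7L, 16L, 16L, 16L, 5L)
  W <- list(matrix(0, 7, 16), matrix(0, 16, 16), matrix(0, 16, 16), matrix(0, 16, 5))
  for (j in 1:5) W[[1]][2 + j, j] <- 1
  for (k in 2:3) for (j in 1:5) W[[k]][j, j] <- 1
  for (j in 1:5) W[[4]][j, j] <- 1
  new("DenseNetwork", dims = dims, weights = W,
      biases = list(rep(0, 16), rep(0, 16), rep(0, 16), rep(0, 5)),
      hiddenSlope = 0.01, outputActivation = "linear", seed = 0L)
}

## Minimal well-behaved training inputs for short trainer runs.
quickTrainSetup <- function(seed = 1L) {
  grid <- makeGrid()
  suite <- quickSuite(seed, grid)
  list(grid = grid,
       dataC = suite[c("carm_08cm", "carm_11cm", "carm_50cm")],
       dataL = suite["laboratory"],
       suite = suite)
}
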