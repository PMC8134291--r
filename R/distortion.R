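#' Describe a simulated C-arm distortion field
#'
#' Constructor for \linkS4class{DistortionFieldSpec}. Defaults emulate the
#' metallic distortion of a mobile C-arm acting on a DC electromagnetic
#' tracker: a smooth field whose magnitude grows as the source distance
#' shrinks, predominantly displacing the z component, with the device quality
#' estimate coupled to the local displacement magnitude and a smooth
#' orientation perturbation. The default inverse-distance exponent of 0.5 is
#' calibrated to the published distance-to-error trend of grid measurements
#' taken at 8, 11 and 50 cm from an X-ray source.
#'
#' @param amplitudeMm Field magnitude (mm) at the reference distance, defined
#'   as the RMS displacement difference across one lattice step (the quantity
#'   displacement error responds to).
#' @param carmDistanceCm Source-to-board distance (cm) of this environment.
#' @param referenceDistanceCm Distance at which \code{amplitudeMm} holds.
#' @param distanceExponent Exponent p of \code{(reference / distance)^p}.
#' @param lengthScaleMm Gaussian bump width controlling smoothness.
#' @param axisWeights (x, y, z) variance shares, nonnegative, summing to 1.
#' @param nBumps Radial-basis bumps per field component.
#' @param seed Seed of the shared field component.
#' @param envSeed Seed of the environment-specific component.
#' @param envPerturbFrac Fraction of the field that is environment-specific.
#' @param qualityBase Quality reading in undistorted conditions.
#' @param qualityCoupling Quality slope per mm of local displacement
#'   (positive: larger q flags more distortion).
#' @param qualityBaselineSd RMS of the smooth position-dependent baseline
#'   variation of q present even without metallic distortion (trackers report a
#'   mildly position-dependent quality estimate in clean fields too).
#' @param angleNoiseDeg RMS orientation perturbation (deg) at the reference distance.
#' @return A \linkS4class{DistortionFieldSpec}.
#' @export
#' @examples
#' distortionField(carmDistanceCm = 8)
distortionField <- function(amplitudeMm = 0.9, carmDistanceCm = 10,
                            referenceDistanceCm = 50, distanceExponent = 0.5,
                            lengthScaleMm = 10,
                            axisWeights = c(0.15, 0.15, 0.70),
                            nBumps = 60L, seed = 1L,
                            envSeed = deriveSeed(seed, 1L),
                            envPerturbFrac = 0.15,
                            qualityBase = 1, qualityCoupling = 2,
                            qualityBaselineSd = 0.5,
                            angleNoiseDeg = 2) {
  new("DistortionFieldSpec", amplitudeMm = as.numeric(amplitudeMm),
      carmDistanceCm = as.numeric(carmDistanceCm),
      referenceDistanceCm = as.numeric(referenceDistanceCm),
      distanceExponent = as.numeric(distanceExponent),
      lengthScaleMm = as.numeric(lengthScaleMm),
      axisWeights = as.numeric(axisWeights), nBumps = as.integer(nBumps),
      seed = as.integer(seed), envSeed = as.integer(envSeed),
      envPerturbFrac = as.numeric(envPerturbFrac),
      qualityBase = as.numeric(qualityBase),
      qualityCoupling = as.numeric(qualityCoupling),
      qualityBaselineSd = as.numeric(qualityBaselineSd),
      angleNoiseDeg = as.numeric(angleNoiseDeg))
}

#' Effective field magnitude at a spec's C-arm distance
#'
#' \code{amplitudeMm * (referenceDistanceCm / carmDistanceCm)^distanceExponent};
#' strictly decreasing in the C-arm distance.
#'
#' @param spec A \linkS4class{DistortionFieldSpec}.
#' @return RMS displacement magnitude in mm.
#' @export
effectiveAmplitude <- function(spec) {
  stopifnot(is(spec, "DistortionFieldSpec"))
  spec@amplitudeMm * (spec@referenceDistanceCm / spec@carmDistanceCm)^spec@distanceExponent
}

## Draw the raw RBF + linear-trend parameters of one field component set
## (3 components) under the current RNG state.
.drawFieldComponent <- function(nBumps, region, k = 3L) {
  centers <- cbind(stats::runif(nBumps, region[1, 1], region[2, 1]),
                   stats::runif(nBumps, region[1, 2], region[2, 2]),
                   stats::runif(nBumps, region[1, 3], region[2, 3]))
  ## weak linear trend: the distortion is predominantly local (eddy-current
  ## like), not a global tilt of the tracking volume
  list(centers = centers,
       coef = matrix(stats::rnorm(nBumps * k), nBumps, k),
       trend = matrix(stats::rnorm(4L * k, sd = 0.15), 4L, k))
}

## Evaluate raw (unstandardized) components at positions (n x 3).
.rawField <- function(positions, centers, coef, trend, lengthScale, region) {
  n <- nrow(positions)
  span <- pmax(region[2, ] - region[1, ], lengthScale)
  ptil <- sweep(sweep(positions, 2L, colMeans(region), "-"), 2L, span, "/")
  out <- cbind(1, ptil) %*% trend
  d2 <- outer(rowSums(positions^2), rowSums(centers^2), "+") -
    2 * positions %*% t(centers)
  phi <- exp(-pmax(d2, 0) / (2 * lengthScale^2))
  out + phi %*% coef
}

#' Realize a distortion field over a region
#'
#' Draws the seeded radial-basis parameters and per-axis standardization
#' constants of the field described by \code{spec}, over the bounding box of
#' \code{grid} (expanded by one length scale). The realized field is a
#' deterministic smooth function of position and can be evaluated anywhere,
#' e.g. along a sensor pull-out trajectory.
#'
#' @param spec A \linkS4class{DistortionFieldSpec}.
#' @param grid A \linkS4class{GroundTruthGrid} defining the probe region, or a
#'   2 x 3 matrix of region bounds (rows: min, max).
#' @return A \linkS4class{DistortionField}.
#' @export
realizeField <- function(spec, grid) {
  stopifnot(is(spec, "DistortionFieldSpec"))
  region <- if (is(grid, "GroundTruthGrid")) {
    p <- as.matrix(grid@nodes[, c("x", "y", "z")])
    rbind(apply(p, 2L, min), apply(p, 2L, max))
  } else as.matrix(grid)
  stopifnot(identical(dim(region), c(2L, 3L)))
  pad <- spec@lengthScaleMm
  regionPad <- rbind(region[1, ] - pad, region[2, ] + pad)

  shared <- withSeed(spec@seed, list(pos = .drawFieldComponent(spec@nBumps, regionPad),
                                     ang = .drawFieldComponent(spec@nBumps, regionPad),
                                     qual = .drawFieldComponent(spec@nBumps, regionPad, 1L)))
  envc <- withSeed(spec@envSeed, list(pos = .drawFieldComponent(spec@nBumps, regionPad),
                                      ang = .drawFieldComponent(spec@nBumps, regionPad),
                                      qual = .drawFieldComponent(spec@nBumps, regionPad, 1L)))
  f <- spec@envPerturbFrac
  nb <- spec@nBumps
  centers <- rbind(shared$pos$centers, envc$pos$centers,
                   shared$ang$centers, envc$ang$centers,
                   shared$qual$centers, envc$qual$centers)
  zero <- function(n, k) matrix(0, n, k)
  posCoef <- rbind((1 - f) * shared$pos$coef, f * envc$pos$coef, zero(4L * nb, 3L))
  angCoef <- rbind(zero(2L * nb, 3L),
                   (1 - f) * shared$ang$coef, f * envc$ang$coef, zero(2L * nb, 3L))
  ## the quality baseline is a room property: fully shared, never perturbed
  qualCoef <- rbind(zero(4L * nb, 1L), shared$qual$coef, zero(nb, 1L))
  posTrend <- (1 - f) * shared$pos$trend + f * envc$pos$trend
  angTrend <- (1 - f) * shared$ang$trend + f * envc$ang$trend
  qualTrend <- shared$qual$trend

  ## Standardization probes. The angular and quality components are scaled to
  ## unit RMS over a probe lattice. The positional components are scaled by the
  ## RMS of their finite differences across one lattice step along their own
  ## axis: displacement error measures exactly those differences, so this makes
  ## the raw displacement error of an environment track the amplitude law
  ## deterministically rather than depend on the realized field roughness.
  probe <- as.matrix(expand.grid(
    x = seq(region[1, 1], region[2, 1], length.out = 6L),
    y = seq(region[1, 2], region[2, 2], length.out = 6L),
    z = seq(region[1, 3], region[2, 3], length.out = 4L)))
  step <- if (is(grid, "GroundTruthGrid")) grid@pitch else mean(region[2, ] - region[1, ]) / 8
  rms <- function(v) sqrt(mean(v^2))
  evalPos <- function(p) .rawField(p, centers, posCoef, posTrend,
                                   spec@lengthScaleMm, regionPad)
  base <- evalPos(probe)
  posScale <- vapply(1:3, function(k) {
    shifted <- probe
    shifted[, k] <- shifted[, k] + step
    rms(evalPos(shifted)[, k] - base[, k])
  }, numeric(1))
  posScale <- pmax(posScale, 1e-12)
  rawA <- .rawField(probe, centers, angCoef, angTrend, spec@lengthScaleMm, regionPad)
  rawQ <- .rawField(probe, centers, qualCoef, qualTrend, spec@lengthScaleMm, regionPad)
  angScale <- pmax(apply(rawA, 2L, rms), 1e-12)
  qualScale <- pmax(apply(rawQ, 2L, rms), 1e-12)

  new("DistortionField", spec = spec, centers = centers,
      posCoef = posCoef, angCoef = angCoef, qualCoef = qualCoef,
      posTrend = posTrend, angTrend = angTrend, qualTrend = qualTrend,
      posScale = posScale, angScale = angScale, qualScale = qualScale,
      region = regionPad)
}

#' Evaluate a realized distortion field at arbitrary positions
#'
#' @param field A \linkS4class{DistortionField}.
#' @param positions Numeric matrix (n x 3) of (x, y, z) in mm.
#' @return List with \code{displacement} (n x 3, mm), \code{q} (length n) and
#'   \code{angleOffset} (n x 3, degrees).
#' @export
evaluateField <- function(field, positions) {
  stopifnot(is(field, "DistortionField"))
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) .fail("positions must be n x 3")
  spec <- field@spec
  ampPos <- effectiveAmplitude(spec)
  ampAng <- spec@angleNoiseDeg *
    (spec@referenceDistanceCm / spec@carmDistanceCm)^spec@distanceExponent
  disp <- matrix(0, nrow(positions), 3L)
  angs <- matrix(0, nrow(positions), 3L)
  if (ampPos > 0) {
    raw <- .rawField(positions, field@centers, field@posCoef, field@posTrend,
                     spec@lengthScaleMm, field@region)
    disp <- sweep(raw, 2L, ampPos * sqrt(spec@axisWeights) / field@posScale, "*")
  }
  if (ampAng > 0) {
    raw <- .rawField(positions, field@centers, field@angCoef, field@angTrend,
                     spec@lengthScaleMm, field@region)
    angs <- sweep(raw, 2L, ampAng / (sqrt(3) * field@angScale), "*")
  }
  qBase <- spec@qualityBase
  if (spec@qualityBaselineSd > 0) {
    raw <- .rawField(positions, field@centers, field@qualCoef, field@qualTrend,
                     spec@lengthScaleMm, field@region)
    qBase <- qBase + spec@qualityBaselineSd * raw[, 1L] / field@qualScale
  }
  q <- qBase + spec@qualityCoupling * sqrt(rowSums(disp^2))
  list(displacement = disp, q = q, angleOffset = angs)
}

#' Apply a distortion field to a ground-truth grid
#'
#' Displaces the grid nodes by the realized field, derives the quality channel
#' from the local displacement magnitude, and perturbs the (nominally zero)
#' orientation. Deterministic for a fixed spec (the field is a function of
#' position, not a per-call random draw).
#'
#' @param grid A \linkS4class{GroundTruthGrid}.
#' @param field A \linkS4class{DistortionFieldSpec} (realized internally over
#'   the grid) or an already realized \linkS4class{DistortionField}.
#' @param nodes Optional subset of grid nodes (a data.frame as in
#'   \code{gridNodes}); defaults to the active layers of the grid.
#' @return data.frame with columns node_id, x, y, z, q, phi_x, phi_y, phi_z.
#' @export
applyDistortion <- function(grid, field, nodes = activeNodes(grid)) {
  stopifnot(is(grid, "GroundTruthGrid"))
  if (is(field, "DistortionFieldSpec")) field <- realizeField(field, grid)
  pos <- as.matrix(nodes[, c("x", "y", "z")])
  ev <- evaluateField(field, pos)
  out <- pos + ev$displacement
  data.frame(node_id = nodes$node_id,
             x = out[, 1], y = out[, 2], z = out[, 3], q = ev$q,
             phi_x = wrapAngles(ev$angleOffset[, 1]),
             phi_y = wrapAngles(ev$angleOffset[, 2]),
             phi_z = wrapAngles(ev$angleOffset[, 3]))
}
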