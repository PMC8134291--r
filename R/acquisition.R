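#' Describe an acquisition / averaging protocol
#'
#' @param samplesPerPoint Raw samples averaged per measuring point (default 500).
#' @param noiseSdMm Per-sample positional noise sd in mm.
#' @param qualityNoiseSd Per-sample noise on the quality channel.
#' @param angleNoiseSdDeg Per-sample orientation noise in degrees.
#' @param seed RNG seed.
#' @return An \linkS4class{AcquisitionSpec}.
#' @export
acquisitionSpec <- function(samplesPerPoint = 500L, noiseSdMm = 3,
                            qualityNoiseSd = 0.1, angleNoiseSdDeg = 0.5,
                            seed = 1L) {
  new("AcquisitionSpec", samplesPerPoint = as.integer(samplesPerPoint),
      noiseSdMm = as.numeric(noiseSdMm), qualityNoiseSd = as.numeric(qualityNoiseSd),
      angleNoiseSdDeg = as.numeric(angleNoiseSdDeg), seed = as.integer(seed))
}

#' Simulate the averaged acquisition of distorted measuring points
#'
#' For every node, \code{samplesPerPoint} noisy raw samples are drawn around
#' the distorted value and averaged (circular mean on the angle channels), so
#' the residual noise of a stored point shrinks as
#' \code{1/sqrt(samplesPerPoint)}.
#'
#' @param distorted data.frame from \code{\link{applyDistortion}}.
#' @param acq An \linkS4class{AcquisitionSpec}.
#' @param name,domain,carmDistance,gantryAngle Metadata of the resulting dataset.
#' @return An \linkS4class{EnvironmentDataset}.
#' @export
simulateAcquisition <- function(distorted, acq, name, domain,
                                carmDistance = NA_real_, gantryAngle = NA_real_) {
  stopifnot(is(acq, "AcquisitionSpec"))
  checkSampleFrame(distorted)
  n <- nrow(distorted)
  k <- acq@samplesPerPoint
  out <- distorted
  withSeed(acq@seed, {
    sds <- c(x = acq@noiseSdMm, y = acq@noiseSdMm, z = acq@noiseSdMm,
             q = acq@qualityNoiseSd, phi_x = acq@angleNoiseSdDeg,
             phi_y = acq@angleNoiseSdDeg, phi_z = acq@angleNoiseSdDeg)
    for (ch in emtChannels()) {
      if (sds[[ch]] <= 0 || n == 0L) next
      draws <- matrix(stats::rnorm(n * k, sd = sds[[ch]]), n, k) + distorted[[ch]]
      if (ch %in% .ANGLE_CHANNELS) {
        out[[ch]] <- wrapAngles(apply(wrapAngles(draws), 1L, circularMean))
      } else {
        out[[ch]] <- rowMeans(draws)
      }
    }
  })
  environmentDataset(name, domain, out, carmDistance, gantryAngle)
}

#' Describe a full simulated measurement campaign
#'
#' One laboratory (bench) environment plus a set of C-arm environments at
#' stated distances, each with a role (training / validation / evaluation).
#' Default roles and distances mirror a typical campaign: training at 8, 11 and
#' 50 cm (gantry 60 degrees at 50 cm), validation at 10 and 30 cm (gantry 30
#' degrees at 30 cm), evaluation at 7, 9 and 12 cm. The laboratory dataset is
#' restricted to two of the three z layers, holding the third layer out of
#' training to probe generalization.
#'
#' In addition to the C-arm distortion, every environment (the laboratory
#' included) carries the same tracker-intrinsic miscalibration: a small affine
#' warp of the measured positions that does not depend on the C-arm and is not
#' flagged by the quality estimate. It is the error component that the
#' laboratory-domain linear fine-tuning step can learn and remove.
#'
#' @param labName Name of the laboratory environment.
#' @param labLayers Layer indices present in the laboratory dataset.
#' @param carm data.frame with columns name, distance_cm, gantry_angle_deg, role.
#' @param field Named list of \code{\link{distortionField}} argument overrides
#'   shared by all C-arm environments (amplitude, length scale, ...).
#' @param intrinsic Named list with \code{scaleSd} (sd of the random affine
#'   perturbation entries, default 0.04, i.e. about a 4 percent
#'   miscalibration) and \code{translationSd} (mm, default 2).
#' @param acquisition Named list of \code{\link{acquisitionSpec}} overrides.
#' @param seed Master suite seed; all per-environment seeds derive from it.
#' @return A list of class \code{suiteConfig}.
#' @export
suiteConfig <- function(labName = "laboratory", labLayers = c(1L, 2L),
                        carm = data.frame(
                          name = c("carm_08cm", "carm_11cm", "carm_50cm",
                                   "carm_10cm", "carm_30cm",
                                   "carm_07cm", "carm_09cm", "carm_12cm"),
                          distance_cm = c(8, 11, 50, 10, 30, 7, 9, 12),
                          gantry_angle_deg = c(NA, NA, 60, NA, 30, NA, NA, NA),
                          role = c("training", "training", "training",
                                   "validation", "validation",
                                   "evaluation", "evaluation", "evaluation")),
                        field = list(), intrinsic = list(),
                        acquisition = list(), seed = 1L) {
  need <- c("name", "distance_cm", "gantry_angle_deg", "role")
  missing <- setdiff(need, names(carm))
  if (length(missing) > 0L)
    .fail("carm table is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(carm) < 1L) .fail("need at least one C-arm environment")
  if (anyDuplicated(c(labName, carm$name))) .fail("environment names must be unique")
  structure(list(labName = labName, labLayers = as.integer(labLayers),
                 carm = carm, field = field, intrinsic = intrinsic,
                 acquisition = acquisition, seed = as.integer(seed)),
            class = "suiteConfig")
}

#' C-arm field spec of a suite environment
#'
#' Reconstructs, from a suite config, the exact distortion-field specification
#' used for a named C-arm environment. Exposed so that out-of-grid measurements
#' (e.g. a sensor pull-out trajectory) can be simulated under the same physical
#' field as the environment datasets.
#'
#' @param config A \code{\link{suiteConfig}}.
#' @param envName Name of a C-arm environment.
#' @return A \linkS4class{DistortionFieldSpec}.
#' @export
suiteFieldSpec <- function(config, envName) {
  stopifnot(inherits(config, "suiteConfig"))
  i <- match(envName, config$carm$name)
  if (is.na(i)) .fail("unknown C-arm environment '", envName, "'")
  fieldArgs <- config$field
  fieldArgs$seed <- deriveSeed(config$seed, 0L)
  do.call(distortionField, utils::modifyList(
    fieldArgs, list(carmDistanceCm = config$carm$distance_cm[i],
                    envSeed = deriveSeed(config$seed, 100L + i))))
}

#' Tracker-intrinsic miscalibration of a suite
#'
#' The seeded affine warp \code{measured = A true + t} shared by every
#' environment of the suite: the tracker's own position-dependent inaccuracy,
#' independent of the C-arm and invisible to the quality channel.
#'
#' @param config A \code{\link{suiteConfig}}.
#' @return List with the 3 x 3 matrix \code{A} and length-3 offset \code{t} (mm).
#' @export
suiteMiscalibration <- function(config) {
  stopifnot(inherits(config, "suiteConfig"))
  defaults <- list(scaleSd = 0.04, translationSd = 2)
  intr <- utils::modifyList(defaults, config$intrinsic)
  withSeed(deriveSeed(config$seed, 1L), list(
    A = diag(3) + matrix(stats::rnorm(9, sd = intr$scaleSd), 3, 3),
    t = stats::rnorm(3, sd = intr$translationSd)))
}

## Warp measured positions by the intrinsic miscalibration (quality and
## orientation channels untouched: the tracker cannot flag or rotate what it
## never knew was wrong).
.addIntrinsic <- function(distorted, miscal, truePositions) {
  warped <- truePositions %*% t(miscal$A)
  offset <- sweep(warped - truePositions, 2L, miscal$t, "+")
  distorted$x <- distorted$x + offset[, 1L]
  distorted$y <- distorted$y + offset[, 2L]
  distorted$z <- distorted$z + offset[, 3L]
  distorted
}

#' Generate a suite of simulated environment datasets
#'
#' Produces one near-undistorted laboratory dataset (restricted to the
#' configured layers) and one dataset per configured C-arm environment. All
#' C-arm environments share the common component of the distortion field
#' (same device, same room) and differ in their distance-scaled amplitude,
#' their environment-specific field component and their acquisition noise, so
#' raw displacement error is ordered inversely with C-arm distance.
#' Deterministic for a fixed config and seed.
#'
#' @param grid A \linkS4class{GroundTruthGrid}.
#' @param config A \code{\link{suiteConfig}}.
#' @return Named list of \linkS4class{EnvironmentDataset}, laboratory first.
#' @export
generateEnvironmentSuite <- function(grid, config) {
  stopifnot(is(grid, "GroundTruthGrid"), inherits(config, "suiteConfig"))
  acqArgs <- config$acquisition
  miscal <- suiteMiscalibration(config)

  labGrid <- grid
  labGrid@layerMask <- seq_along(grid@layerElevations) %in% config$labLayers
  labNodes <- activeNodes(labGrid)
  labSpec <- do.call(distortionField, utils::modifyList(
    config$field, list(amplitudeMm = 0, angleNoiseDeg = 0,
                       carmDistanceCm = 50,
                       seed = deriveSeed(config$seed, 0L),
                       envSeed = deriveSeed(config$seed, 999L))))
  labAcq <- do.call(acquisitionSpec,
                    utils::modifyList(acqArgs, list(seed = deriveSeed(config$seed, 500L))))
  labRaw <- .addIntrinsic(applyDistortion(grid, labSpec, labNodes),
                          miscal, as.matrix(labNodes[, c("x", "y", "z")]))
  lab <- simulateAcquisition(labRaw, labAcq, config$labName, "L")

  out <- list(lab)
  names(out) <- config$labName
  truePos <- as.matrix(activeNodes(grid)[, c("x", "y", "z")])
  for (i in seq_len(nrow(config$carm))) {
    row <- config$carm[i, ]
    spec <- suiteFieldSpec(config, row$name)
    acq <- do.call(acquisitionSpec,
                   utils::modifyList(acqArgs, list(seed = deriveSeed(config$seed, 200L + i))))
    raw <- .addIntrinsic(applyDistortion(grid, spec), miscal, truePos)
    out[[row$name]] <- simulateAcquisition(
      raw, acq, row$name, "C",
      carmDistance = row$distance_cm, gantryAngle = row$gantry_angle_deg)
  }
  out
}

#' Simulate a straight sensor pull-out trajectory in a suite environment
#'
#' Emulates retracting the sensor in equal steps along the tracker x-axis (as
#' in a pull-out experiment: 13 steps of 8 mm), with constant true orientation,
#' under the same C-arm and tracker-intrinsic fields as the named suite
#' environment. Useful for assessing rotational stability of raw versus
#' compensated measurements.
#'
#' @param grid The \linkS4class{GroundTruthGrid} the suite was generated on
#'   (defines the field region).
#' @param config The \code{\link{suiteConfig}} of the suite.
#' @param envName Name of the (C-arm) environment to measure in.
#' @param start Numeric (x, y, z) start position in mm.
#' @param stepMm Step length along x.
#' @param nSteps Number of measuring points.
#' @return An \linkS4class{EnvironmentDataset} (domain C) whose node ids are
#'   the 1-based step indices (not grid nodes).
#' @export
simulateTrajectory <- function(grid, config, envName,
                               start = c(-32, 12, 9.6), stepMm = 8, nSteps = 13L) {
  spec <- suiteFieldSpec(config, envName)
  pos <- cbind(start[1] + stepMm * (seq_len(nSteps) - 1L), start[2], start[3])
  carmField <- realizeField(spec, grid)
  ev <- evaluateField(carmField, pos)
  raw <- data.frame(node_id = seq_len(nSteps),
                    x = pos[, 1] + ev$displacement[, 1],
                    y = pos[, 2] + ev$displacement[, 2],
                    z = pos[, 3] + ev$displacement[, 3],
                    q = ev$q,
                    phi_x = wrapAngles(ev$angleOffset[, 1]),
                    phi_y = wrapAngles(ev$angleOffset[, 2]),
                    phi_z = wrapAngles(ev$angleOffset[, 3]))
  raw <- .addIntrinsic(raw, suiteMiscalibration(config), pos)
  acq <- do.call(acquisitionSpec, utils::modifyList(
    config$acquisition, list(seed = deriveSeed(config$seed, 300L))))
  i <- match(envName, config$carm$name)
  simulateAcquisition(raw, acq, paste0(envName, "_trajectory"), "C",
                      carmDistance = config$carm$distance_cm[i],
                      gantryAngle = config$carm$gantry_angle_deg[i])
}

#' Roles of the environments in a suite config
#'
#' @param config A \code{\link{suiteConfig}}.
#' @param role One of \code{"training"}, \code{"validation"}, \code{"evaluation"}.
#' @return Character vector of environment names with that role.
#' @export
suiteEnvironments <- function(config, role) {
  stopifnot(inherits(config, "suiteConfig"))
  role <- match.arg(role, c("training", "validation", "evaluation"))
  config$carm$name[config$carm$role == role]
}
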