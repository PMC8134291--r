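## Central S4 classes. Validity methods enforce the structural invariants that the
## rest of the package relies on; user code should go through the constructors
## and accessors, never through slots.

#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Calibrated ground-truth grid
#'
#' A regular lattice of measuring points (a calibrated pegboard measured at
#' several elevations). Node positions follow row-major order: x fastest, then
#' y, then layer. Pairwise true distances are computable in closed form from the
#' lattice, which is what makes displacement error a self-contained accuracy
#' metric: no external measurement standard is needed.
#'
#' @slot pitch Lattice spacing in mm.
#' @slot dims Integer (nx, ny): nodes per row and rows per layer.
#' @slot layerElevations Numeric z elevation of each layer in mm.
#' @slot layerMask Logical, one per layer; FALSE marks layers held out from a use
#'   (e.g. laboratory training data restricted to two of three layers).
#' @slot nodes data.frame with columns node_id, ix, iy, layer, x, y, z.
#' @export
setClass("GroundTruthGrid",
  representation(pitch = "numeric", dims = "integer",
                 layerElevations = "numeric", layerMask = "logical",
                 nodes = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (length(object@pitch) != 1L || !is.finite(object@pitch) || object@pitch <= 0)
      msg <- c(msg, "pitch must be a single positive number")
    if (length(object@dims) != 2L || any(object@dims < 1L))
      msg <- c(msg, "dims must be two positive integers")
    if (length(object@layerMask) != length(object@layerElevations))
      msg <- c(msg, "layerMask must match layerElevations in length")
    n <- object@nodes
    need <- c("node_id", "ix", "iy", "layer", "x", "y", "z")
    if (!all(need %in% names(n))) {
      msg <- c(msg, "nodes must have columns node_id, ix, iy, layer, x, y, z")
    } else if (nrow(n) > 0L) {
      ex <- (n$ix - 1) * object@pitch
      ey <- (n$iy - 1) * object@pitch
      ez <- object@layerElevations[n$layer]
      if (max(abs(n$x - ex), abs(n$y - ey), abs(n$z - ez)) > 1e-9)
        msg <- c(msg, "node positions do not lie on the lattice implied by pitch and layers")
      if (anyDuplicated(n$node_id))
        msg <- c(msg, "node_id values must be unique")
    }
    if (length(msg) == 0L) TRUE else msg
  })

#' A named set of tracked points from one environment
#'
#' Holds the averaged measurements of one acquisition session: a laboratory
#' (bench, domain \code{"L"}) session or a C-arm bedside session (domain
#' \code{"C"}) taken at a known distance from the X-ray source. Every sample is
#' mapped to exactly one ground-truth grid node through \code{node_id}.
#'
#' @slot name Environment label, e.g. \code{"carm_08cm"}.
#' @slot domain \code{"C"} (C-arm / bedside) or \code{"L"} (laboratory / bench).
#' @slot samples data.frame with columns node_id, x, y, z, q, phi_x, phi_y, phi_z.
#' @slot carmDistance Distance from X-ray source to board centre in cm
#'   (\code{NA} for laboratory data, which has no C-arm).
#' @slot gantryAngle C-arm gantry rotation in degrees (\code{NA} if not recorded).
#' @export
setClass("EnvironmentDataset",
  representation(name = "character", domain = "character",
                 samples = "data.frame", carmDistance = "numeric",
                 gantryAngle = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
      msg <- c(msg, "name must be a non-empty string")
    if (!(identical(object@domain, "C") || identical(object@domain, "L")))
      msg <- c(msg, "domain must be \"C\" or \"L\"")
    ok <- tryCatch({ checkSampleFrame(object@samples); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) msg <- c(msg, ok)
    if (identical(object@domain, "L") && isTRUE(is.finite(object@carmDistance)))
      msg <- c(msg, "laboratory (domain L) datasets must not carry a C-arm distance")
    if (identical(object@domain, "C") &&
        (length(object@carmDistance) != 1L || !is.finite(object@carmDistance) ||
         object@carmDistance <= 0))
      msg <- c(msg, "C-arm datasets need a positive carmDistance (cm)")
    if (isTRUE(ok) && nrow(object@samples) > 0L) {
      th <- as.matrix(object@samples[, .ANGLE_CHANNELS])
      if (any(th < -180 | th >= 180))
        msg <- c(msg, "orientation angles must be wrapped to [-180, 180)")
    }
    if (length(msg) == 0L) TRUE else msg
  })

#' Per-channel min-max normalization bounds
#'
#' Linear map of each of the seven channels onto [0, 1] over the fitted data.
#' Out-of-range inputs are extrapolated linearly, never clamped, so positional
#' information from unseen environments survives normalization.
#'
#' @slot lower,upper Named numeric vectors, one entry per channel.
#' @export
setClass("NormalizationBounds",
  representation(lower = "numeric", upper = "numeric"),
  validity = function(object) {
    ch <- emtChannels()
    if (!identical(names(object@lower), ch) || !identical(names(object@upper), ch))
      return("lower/upper must be named by the seven EMT channels in canonical order")
    if (any(!is.finite(object@lower)) || any(!is.finite(object@upper)))
      return("bounds must be finite")
    bad <- which(object@upper <= object@lower)
    if (length(bad) > 0L)
      return(paste0("degenerate channel (max <= min): ",
                    paste(ch[bad], collapse = ", ")))
    TRUE
  })

#' Parametric description of a simulated C-arm distortion field
#'
#' The field is a smooth, deterministic function of position: a linear trend
#' plus Gaussian radial-basis bumps, with an overall magnitude that grows as
#' the C-arm moves closer, \code{amplitudeMm * (referenceDistanceCm /
#' carmDistanceCm)^distanceExponent}. \code{amplitudeMm} is the RMS displacement
#' magnitude over the probe grid at the reference distance. Axis weights split
#' the displacement variance between x, y and z (z-dominant by default, as the
#' z component is the most distortion-susceptible channel of the tracker).
#' A fraction \code{1 - envPerturbFrac} of the field is shared between
#' environments generated from the same base seed (same device, same room),
#' the rest is environment-specific.
#'
#' @slot amplitudeMm Field magnitude (mm) at the reference distance: the RMS
#'   displacement difference across one lattice step.
#' @slot carmDistanceCm Nominal source distance (cm) of this environment.
#' @slot referenceDistanceCm Distance at which \code{amplitudeMm} is defined.
#' @slot distanceExponent Exponent of the inverse-distance amplitude law.
#' @slot lengthScaleMm Spatial smoothness (Gaussian bump width).
#' @slot axisWeights Nonnegative (x, y, z) variance shares, summing to 1.
#' @slot nBumps Number of radial-basis bumps per field component.
#' @slot seed Seed of the shared field component.
#' @slot envSeed Seed of the environment-specific component.
#' @slot envPerturbFrac Fraction (0..1) of field variance that is environment-specific.
#' @slot qualityBase Quality-channel reading in undistorted conditions.
#' @slot qualityCoupling Slope of q per mm of local displacement magnitude
#'   (positive: larger q means more distortion; sign is configurable).
#' @slot qualityBaselineSd RMS of the smooth position-dependent baseline
#'   variation of q that exists even without metallic distortion.
#' @slot angleNoiseDeg RMS orientation perturbation (degrees) at the reference distance.
#' @export
setClass("DistortionFieldSpec",
  representation(amplitudeMm = "numeric", carmDistanceCm = "numeric",
                 referenceDistanceCm = "numeric", distanceExponent = "numeric",
                 lengthScaleMm = "numeric", axisWeights = "numeric",
                 nBumps = "integer", seed = "integer", envSeed = "integer",
                 envPerturbFrac = "numeric", qualityBase = "numeric",
                 qualityCoupling = "numeric", qualityBaselineSd = "numeric",
                 angleNoiseDeg = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@amplitudeMm < 0) msg <- c(msg, "amplitudeMm must be >= 0")
    if (object@carmDistanceCm <= 0 || object@referenceDistanceCm <= 0)
      msg <- c(msg, "distances must be positive")
    if (object@lengthScaleMm <= 0) msg <- c(msg, "lengthScaleMm must be positive")
    w <- object@axisWeights
    if (length(w) != 3L || any(w < 0) || abs(sum(w) - 1) > 1e-8)
      msg <- c(msg, "axisWeights must be 3 nonnegative values summing to 1")
    if (object@envPerturbFrac < 0 || object@envPerturbFrac > 1)
      msg <- c(msg, "envPerturbFrac must be in [0, 1]")
    if (object@nBumps < 1L) msg <- c(msg, "nBumps must be >= 1")
    if (object@angleNoiseDeg < 0) msg <- c(msg, "angleNoiseDeg must be >= 0")
    if (length(msg) == 0L) TRUE else msg
  })

#' Realized distortion field
#'
#' A \linkS4class{DistortionFieldSpec} plus the seeded radial-basis parameters
#' and per-axis standardization constants, so the same physical field can be
#' evaluated at arbitrary positions (grid nodes, pull-out trajectories, ...).
#'
#' @slot spec The generating \linkS4class{DistortionFieldSpec}.
#' @slot centers Bump centres (rows) in mm.
#' @slot posCoef,angCoef,qualCoef Bump coefficients for the positional, angular
#'   and quality-baseline components.
#' @slot posTrend,angTrend,qualTrend 4 x k linear-trend coefficients
#'   (intercept + 3 position terms).
#' @slot posScale,angScale,qualScale Per-component standardization divisors.
#' @slot region Probe-grid bounding box used for standardization (2 x 3 matrix).
#' @export
setClass("DistortionField",
  representation(spec = "DistortionFieldSpec", centers = "matrix",
                 posCoef = "matrix", angCoef = "matrix", qualCoef = "matrix",
                 posTrend = "matrix", angTrend = "matrix", qualTrend = "matrix",
                 posScale = "numeric", angScale = "numeric", qualScale = "numeric",
                 region = "matrix"))

#' Acquisition / averaging protocol
#'
#' At every measuring point the tracker is sampled repeatedly and the samples
#' are averaged to suppress random noise (500 samples per point in the
#' reference protocol); residual noise shrinks as 1/sqrt(samplesPerPoint).
#'
#' @slot samplesPerPoint Number of raw samples averaged per measuring point.
#' @slot noiseSdMm Per-sample positional noise standard deviation (mm).
#' @slot qualityNoiseSd Per-sample noise on the quality channel.
#' @slot angleNoiseSdDeg Per-sample noise on the orientation channels (degrees).
#' @slot seed RNG seed for the acquisition noise.
#' @export
setClass("AcquisitionSpec",
  representation(samplesPerPoint = "integer", noiseSdMm = "numeric",
                 qualityNoiseSd = "numeric", angleNoiseSdDeg = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@samplesPerPoint < 1L) msg <- c(msg, "samplesPerPoint must be >= 1")
    if (object@noiseSdMm < 0 || object@qualityNoiseSd < 0 || object@angleNoiseSdDeg < 0)
      msg <- c(msg, "noise standard deviations must be >= 0")
    if (length(msg) == 0L) TRUE else msg
  })

#' Fully connected network
#'
#' A small dense stack with leaky-rectifier hidden activations and a linear or
#' sigmoid head. Weights are initialized uniformly on
#' +-1/sqrt(fan-in), seeded, so construction is deterministic.
#'
#' @slot dims Layer widths, input first (e.g. \code{c(7, 16, 16, 16, 5)}).
#' @slot weights,biases Lists of weight matrices (in x out) and bias vectors.
#' @slot hiddenSlope Negative slope of the leaky rectifier.
#' @slot outputActivation \code{"linear"} or \code{"sigmoid"}.
#' @slot seed Initialization seed.
#' @export
setClass("DenseNetwork",
  representation(dims = "integer", weights = "list", biases = "list",
                 hiddenSlope = "numeric", outputActivation = "character",
                 seed = "integer"),
  validity = function(object) {
    nl <- length(object@dims) - 1L
    if (nl < 1L) return("need at least one layer")
    if (length(object@weights) != nl || length(object@biases) != nl)
      return("weights/biases must have one entry per layer")
    for (k in seq_len(nl)) {
      if (!identical(dim(object@weights[[k]]),
                     c(object@dims[k], object@dims[k + 1L])))
        return(sprintf("weight %d has wrong shape", k))
      if (length(object@biases[[k]]) != object@dims[k + 1L])
        return(sprintf("bias %d has wrong length", k))
    }
    if (!object@outputActivation %in% c("linear", "sigmoid"))
      return("outputActivation must be linear or sigmoid")
    TRUE
  })

#' The trained translation model
#'
#' The two generators and two discriminators of the cycle-consistent pair,
#' together with the normalization bounds they were trained under (inference on
#' unseen environments reuses the training bounds). \code{gCL} translates C-arm
#' points to the laboratory domain and is the network used for compensation.
#'
#' @slot gCL,gLC Generator networks (C to L, L to C).
#' @slot dCL,dLC Discriminator networks judging the output of gCL / gLC.
#' @slot bounds \linkS4class{NormalizationBounds} fitted on the training data.
#' @slot seed Training seed.
#' @slot mode \code{"cyclegan"} or \code{"vanilla_gan"} (no cycle loss).
#' @slot log Per-step loss log (data.frame; empty before training).
#' @export
setClass("ModelPair",
  representation(gCL = "DenseNetwork", gLC = "DenseNetwork",
                 dCL = "DenseNetwork", dLC = "DenseNetwork",
                 bounds = "NormalizationBounds", seed = "integer",
                 mode = "character", log = "data.frame"),
  validity = function(object) {
    if (!object@mode %in% c("cyclegan", "vanilla_gan"))
      return("mode must be cyclegan or vanilla_gan")
    if (!identical(object@gCL@dims[1], 7L) || !identical(unname(object@gCL@dims[length(object@gCL@dims)]), 5L))
      return("generators must map 7 inputs to 5 outputs")
    if (!identical(unname(object@dCL@dims[length(object@dCL@dims)]), 1L))
      return("discriminators must have a scalar output")
    TRUE
  })

#' Training configuration
#'
#' Defaults follow the reference training protocol: generator loss
#' \code{lambdaAdv * L_adv + lambdaCycle * L_cycle + lambdaComp * L_comp} with
#' coefficients 0.5 / 10 / 1e-5; Adam with learning rate 5e-4, constant for the
#' first 100 epochs then decaying linearly to 0 at epoch 200; minibatch 16;
#' discriminators trained with soft labels drawn uniformly from [0, 0.2] (fake)
#' and [0.8, 1] (valid); a deep ensemble of 10 sequentially trained
#' initializations.
#'
#' @slot lambdaAdv,lambdaCycle,lambdaComp Loss weights.
#' @slot lr Initial Adam learning rate.
#' @slot decayStartEpoch Epoch at which linear decay begins.
#' @slot totalEpochs Total training epochs.
#' @slot batchSize Minibatch size.
#' @slot ensembleSize Number of ensemble members.
#' @slot softValidRange,softFakeRange Soft-label uniform ranges.
#' @slot mode \code{"cyclegan"} or \code{"vanilla_gan"} (ablation: cycle loss off).
#' @slot seed Master training seed.
#' @export
setClass("TrainConfig",
  representation(lambdaAdv = "numeric", lambdaCycle = "numeric",
                 lambdaComp = "numeric", lr = "numeric",
                 decayStartEpoch = "integer", totalEpochs = "integer",
                 batchSize = "integer", ensembleSize = "integer",
                 softValidRange = "numeric", softFakeRange = "numeric",
                 mode = "character", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (any(c(object@lambdaAdv, object@lambdaCycle, object@lambdaComp) < 0))
      msg <- c(msg, "loss weights must be >= 0")
    if (object@lr <= 0) msg <- c(msg, "lr must be positive")
    if (object@decayStartEpoch >= object@totalEpochs)
      msg <- c(msg, "decayStartEpoch must be < totalEpochs")
    if (object@batchSize < 2L) msg <- c(msg, "batchSize must be >= 2")
    if (object@ensembleSize < 1L) msg <- c(msg, "ensembleSize must be >= 1")
    if (!object@mode %in% c("cyclegan", "vanilla_gan"))
      msg <- c(msg, "mode must be cyclegan or vanilla_gan")
    if (length(msg) == 0L) TRUE else msg
  })

#' A set of point pairs with measured and true separations
#'
#' @slot pairs Two-column integer matrix of sample indices into the source dataset.
#' @slot nodePairs Two-column integer matrix of the corresponding grid node ids.
#' @slot measuredDist,trueDist Pair separations in mm.
#' @slot scheme Pair-selection scheme used.
#' @export
setClass("DisplacementSet",
  representation(pairs = "matrix", nodePairs = "matrix",
                 measuredDist = "numeric", trueDist = "numeric",
                 scheme = "character"),
  validity = function(object) {
    n <- nrow(object@pairs)
    if (length(object@measuredDist) != n || length(object@trueDist) != n)
      return("distance vectors must match the number of pairs")
    if (n > 0L && any(object@pairs[, 1L] == object@pairs[, 2L]))
      return("pairs must link two distinct samples")
    if (any(object@trueDist <= 0)) return("true distances must be positive")
    TRUE
  })

#' Displacement accuracy summary
#'
#' @slot rmse Root-mean-square displacement error (mm).
#' @slot sd Sample standard deviation of the per-pair errors (mm).
#' @slot nPairs Number of displacement pairs.
#' @export
setClass("ErrorSummary",
  representation(rmse = "numeric", sd = "numeric", nPairs = "integer"),
  validity = function(object) {
    if (object@rmse < 0 || object@sd < 0) return("rmse and sd must be >= 0")
    TRUE
  })

#' Ensemble-compensated dataset with predictive uncertainty
#'
#' @slot dataset Ensemble-mean compensated samples (laboratory-domain estimate).
#' @slot sigmaPred Per-point predictive spread (mm).
#' @slot sigmaAggregate Mean of \code{sigmaPred} over points (mm).
#' @slot memberSamples Per-member compensated sample frames (for diagnostics).
#' @export
setClass("CompensationResult",
  representation(dataset = "EnvironmentDataset", sigmaPred = "numeric",
                 sigmaAggregate = "numeric", memberSamples = "list"),
  validity = function(object) {
    if (length(object@sigmaPred) != nrow(object@dataset@samples))
      return("sigmaPred must have one entry per sample")
    if (any(object@sigmaPred < -1e-12)) return("sigmaPred must be >= 0")
    TRUE
  })

#' Linear x-y fine-tuning model
#'
#' Ordinary least-squares corrections (dx, dy) predicted from the features
#' (x, y, z, q), fitted in the laboratory domain against grid-anchored targets
#' after rigid alignment. A zero-coefficient model is the identity on positions.
#'
#' @slot coefX,coefY Named coefficients (intercept, x, y, z, q) for dx and dy.
#' @slot residualRmse In-plane residual RMSE (mm) on the fitted set.
#' @slot rotation,translation Rigid alignment (2 x 2 rotation, length-2 translation)
#'   mapping grid x-y coordinates into the measured frame.
#' @export
setClass("LinearCompensator",
  representation(coefX = "numeric", coefY = "numeric",
                 residualRmse = "numeric", rotation = "matrix",
                 translation = "numeric"),
  validity = function(object) {
    nm <- c("intercept", "x", "y", "z", "q")
    if (!identical(names(object@coefX), nm) || !identical(names(object@coefY), nm))
      return("coefficients must be named intercept, x, y, z, q")
    if (object@residualRmse < 0) return("residualRmse must be >= 0")
    TRUE
  })
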