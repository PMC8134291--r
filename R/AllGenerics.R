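#' @include AllClasses.R
NULL

#' Accessors for cycleEMT objects
#'
#' Slot access helpers; user code should prefer these over \code{@}.
#'
#' @param object A cycleEMT S4 object.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("measurements", function(object) standardGeneric("measurements"))

#' @rdname accessors
#' @export
setGeneric("envName", function(object) standardGeneric("envName"))

#' @rdname accessors
#' @export
setGeneric("envDomain", function(object) standardGeneric("envDomain"))

#' @rdname accessors
#' @export
setGeneric("carmDistance", function(object) standardGeneric("carmDistance"))

#' @rdname accessors
#' @export
setGeneric("gantryAngle", function(object) standardGeneric("gantryAngle"))

#' @rdname accessors
#' @export
setGeneric("nodeIndex", function(object) standardGeneric("nodeIndex"))

#' @rdname accessors
#' @export
setGeneric("gridPitch", function(object) standardGeneric("gridPitch"))

#' @rdname accessors
#' @export
setGeneric("gridNodes", function(object) standardGeneric("gridNodes"))

#' @rdname accessors
#' @export
setGeneric("layerElevations", function(object) standardGeneric("layerElevations"))

#' @rdname accessors
#' @export
setGeneric("modelBounds", function(object) standardGeneric("modelBounds"))

#' @rdname accessors
#' @export
setGeneric("trainingLog", function(object) standardGeneric("trainingLog"))

#' @rdname accessors
#' @export
setGeneric("sigmaPred", function(object) standardGeneric("sigmaPred"))

#' @rdname accessors
#' @export
setGeneric("errorRmse", function(object) standardGeneric("errorRmse"))

#' @rdname accessors
#' @export
setGeneric("errorSd", function(object) standardGeneric("errorSd"))

#' @rdname accessors
#' @export
setGeneric("nPairs", function(object) standardGeneric("nPairs"))

setMethod("measurements", "EnvironmentDataset", function(object) object@samples)
setMethod("measurements", "CompensationResult", function(object) object@dataset@samples)
setMethod("envName", "EnvironmentDataset", function(object) object@name)
setMethod("envDomain", "EnvironmentDataset", function(object) object@domain)
setMethod("carmDistance", "EnvironmentDataset", function(object) object@carmDistance)
setMethod("gantryAngle", "EnvironmentDataset", function(object) object@gantryAngle)
setMethod("nodeIndex", "EnvironmentDataset", function(object) object@samples$node_id)
setMethod("gridPitch", "GroundTruthGrid", function(object) object@pitch)
setMethod("gridNodes", "GroundTruthGrid", function(object) object@nodes)
setMethod("layerElevations", "GroundTruthGrid", function(object) object@layerElevations)
setMethod("modelBounds", "ModelPair", function(object) object@bounds)
setMethod("trainingLog", "ModelPair", function(object) object@log)
setMethod("sigmaPred", "CompensationResult", function(object) object@sigmaPred)
setMethod("errorRmse", "ErrorSummary", function(object) object@rmse)
setMethod("errorSd", "ErrorSummary", function(object) object@sd)
setMethod("nPairs", "ErrorSummary", function(object) object@nPairs)
setMethod("nPairs", "DisplacementSet", function(object) nrow(object@pairs))

setMethod("show", "GroundTruthGrid", function(object) {
  cat(sprintf("GroundTruthGrid: %d x %d nodes, %d layer(s), pitch %.3g mm (%d nodes)\n",
              object@dims[1], object@dims[2], length(object@layerElevations),
              object@pitch, nrow(object@nodes)))
  cat("  layer elevations (mm):", paste(signif(object@layerElevations, 4), collapse = ", "), "\n")
})

setMethod("show", "EnvironmentDataset", function(object) {
  extra <- if (identical(object@domain, "C"))
    sprintf(", C-arm distance %.3g cm%s", object@carmDistance,
            if (is.finite(object@gantryAngle))
              sprintf(", gantry %.3g deg", object@gantryAngle) else "")
  else ""
  cat(sprintf("EnvironmentDataset '%s': domain %s, %d samples%s\n",
              object@name, object@domain, nrow(object@samples), extra))
})

setMethod("show", "NormalizationBounds", function(object) {
  cat("NormalizationBounds:\n")
  print(rbind(lower = object@lower, upper = object@upper))
})

setMethod("show", "DenseNetwork", function(object) {
  cat(sprintf("DenseNetwork %s, leaky slope %.3g, %s head, %d parameters (seed %d)\n",
              paste(object@dims, collapse = "-"), object@hiddenSlope,
              object@outputActivation, parameterCount(object), object@seed))
})

setMethod("show", "ModelPair", function(object) {
  trained <- if (nrow(object@log) > 0L)
    sprintf("trained, %d logged steps", nrow(object@log)) else "untrained"
  cat(sprintf("ModelPair (%s, %s; seed %d)\n", object@mode, trained, object@seed))
  cat("  gCL:"); show(object@gCL)
  cat("  dCL:"); show(object@dCL)
})

setMethod("show", "ErrorSummary", function(object) {
  cat(sprintf("Displacement error: RMSE %.3f mm, sd %.3f mm over %d pairs\n",
              object@rmse, object@sd, object@nPairs))
})

setMethod("show", "DisplacementSet", function(object) {
  cat(sprintf("DisplacementSet: %d pairs (scheme '%s')\n",
              nrow(object@pairs), object@scheme))
})

setMethod("show", "CompensationResult", function(object) {
  cat(sprintf("CompensationResult: %d points, %d ensemble member(s), sigma_pred %.3f mm\n",
              nrow(object@dataset@samples), length(object@memberSamples),
              object@sigmaAggregate))
})

setMethod("show", "LinearCompensator", function(object) {
  cat("LinearCompensator (dx, dy ~ intercept + x + y + z + q)\n")
  print(rbind(dx = object@coefX, dy = object@coefY))
  cat(sprintf("  residual RMSE on fitted set: %.4f mm\n", object@residualRmse))
})

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(paste0("TrainConfig: mode %s, lambdas (adv %.3g, cycle %.3g, comp %.3g), ",
                     "lr %.4g (decay from epoch %d to %d), batch %d, ensemble %d, seed %d\n"),
              object@mode, object@lambdaAdv, object@lambdaCycle, object@lambdaComp,
              object@lr, object@decayStartEpoch, object@totalEpochs,
              object@batchSize, object@ensembleSize, object@seed))
})

setMethod("show", "DistortionFieldSpec", function(object) {
  cat(sprintf(paste0("DistortionFieldSpec: %.3g mm RMS at %.3g cm (ref %.3g cm, exponent %.3g), ",
                     "length scale %.3g mm, axis weights (%.2f, %.2f, %.2f)\n"),
              object@amplitudeMm, object@carmDistanceCm, object@referenceDistanceCm,
              object@distanceExponent, object@lengthScaleMm,
              object@axisWeights[1], object@axisWeights[2], object@axisWeights[3]))
})

setMethod("show", "AcquisitionSpec", function(object) {
  cat(sprintf("AcquisitionSpec: %d samples/point, noise %.3g mm (q %.3g, angles %.3g deg), seed %d\n",
              object@samplesPerPoint, object@noiseSdMm, object@qualityNoiseSd,
              object@angleNoiseSdDeg, object@seed))
})
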