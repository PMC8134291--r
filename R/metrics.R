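#' Build displacement pairs for a dataset
#'
#' Pairs measured points whose true separation is known from the lattice, the
#' basis of the displacement accuracy metric (a relative metric: no external
#' coordinate standard is needed). The default scheme \code{"lattice-neighbors"}
#' links each node to its adjacent lattice nodes within a layer and to the same
#' (ix, iy) node on adjacent layers; \code{"all-pairs"} links every pair of
#' distinct nodes.
#'
#' @param dataset An \linkS4class{EnvironmentDataset} (or a
#'   \linkS4class{CompensationResult}); every sample must map to a grid node.
#' @param grid The \linkS4class{GroundTruthGrid}.
#' @param scheme Pair-selection scheme.
#' @return A \linkS4class{DisplacementSet}.
#' @export
buildDisplacementPairs <- function(dataset, grid,
                                   scheme = c("lattice-neighbors", "all-pairs")) {
  scheme <- match.arg(scheme)
  if (is(dataset, "CompensationResult")) dataset <- dataset@dataset
  stopifnot(is(dataset, "EnvironmentDataset"), is(grid, "GroundTruthGrid"))
  s <- measurements(dataset)
  rowNode <- match(s$node_id, grid@nodes$node_id)
  if (anyNA(rowNode))
    .fail("sample(s) mapped to unknown grid node(s): ",
          paste(unique(s$node_id[is.na(rowNode)]), collapse = ", "))
  info <- grid@nodes[rowNode, ]
  n <- nrow(s)
  pairs <- if (scheme == "all-pairs") {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    idx[info$node_id[idx[, 1]] != info$node_id[idx[, 2]], , drop = FALSE]
  } else {
    if (anyDuplicated(s$node_id))
      .fail("lattice-neighbors scheme requires one sample per node")
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    di <- abs(info$ix[idx[, 1]] - info$ix[idx[, 2]])
    dj <- abs(info$iy[idx[, 1]] - info$iy[idx[, 2]])
    dl <- abs(info$layer[idx[, 1]] - info$layer[idx[, 2]])
    keep <- (dl == 0L & ((di == 1L & dj == 0L) | (di == 0L & dj == 1L))) |
      (dl == 1L & di == 0L & dj == 0L)
    idx[keep, , drop = FALSE]
  }
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  p <- as.matrix(s[, c("x", "y", "z")])
  measured <- unname(sqrt(rowSums((p[pairs[, 1L], , drop = FALSE] -
                                   p[pairs[, 2L], , drop = FALSE])^2)))
  nodePairs <- cbind(s$node_id[pairs[, 1L]], s$node_id[pairs[, 2L]])
  true <- trueDistances(grid, nodePairs[, 1L], nodePairs[, 2L])
  new("DisplacementSet", pairs = pairs, nodePairs = nodePairs,
      measuredDist = measured, trueDist = true, scheme = scheme)
}

#' Displacement error summary
#'
#' Root-mean-square and sample standard deviation (n - 1 denominator; 0 when
#' only one pair exists) of the per-pair errors (measured minus true distance).
#'
#' @param ds A \linkS4class{DisplacementSet}.
#' @return An \linkS4class{ErrorSummary}.
#' @export
displacementError <- function(ds) {
  stopifnot(is(ds, "DisplacementSet"))
  n <- nrow(ds@pairs)
  if (n < 1L) .fail("empty displacement set")
  err <- ds@measuredDist - ds@trueDist
  new("ErrorSummary", rmse = sqrt(mean(err^2)),
      sd = if (n > 1L) stats::sd(err) else 0, nPairs = n)
}

#' Predictive spread of an ensemble
#'
#' Per point, the standard deviation of the compensated position across the
#' ensemble members: the per-axis sample standard deviations combined as a
#' Euclidean norm. The aggregate value is the mean over points. This spread
#' approximates the model-inherent (epistemic) uncertainty of a deep ensemble.
#'
#' @param members List (length >= 2) of data.frames or matrices with identical
#'   row counts and columns x, y, z.
#' @return List with \code{perPoint} (numeric, mm) and \code{aggregate} (mm).
#' @export
predictionSpread <- function(members) {
  if (!is.list(members) || length(members) < 2L)
    .fail("need at least 2 ensemble members")
  mats <- lapply(members, function(m) {
    if (is(m, "CompensationResult")) m <- measurements(m)
    if (is(m, "EnvironmentDataset")) m <- measurements(m)
    as.matrix(as.data.frame(m)[, c("x", "y", "z")])
  })
  n <- nrow(mats[[1L]])
  if (any(vapply(mats, nrow, 1L) != n))
    .fail("ensemble members have mismatched point counts")
  perAxisVar <- Reduce(`+`, lapply(seq_len(3L), function(ax) {
    a <- vapply(mats, function(m) m[, ax], numeric(n))
    if (n == 1L) a <- matrix(a, nrow = 1L)
    apply(a, 1L, stats::var)
  }))
  perPoint <- sqrt(perAxisVar)
  list(perPoint = perPoint, aggregate = mean(perPoint))
}

#' Rotational stability of a trajectory
#'
#' Circular statistics of the orientation channels along an ordered trajectory
#' (e.g. a straight sensor pull-out): circular mean and circular standard
#' deviation per angle, plus the maximum drift from the starting orientation
#' after unwrapping. In the tracker convention used here phi_z is the azimuth,
#' phi_y the elevation and phi_x the roll of the sensor.
#'
#' @param trajectory An \linkS4class{EnvironmentDataset} or samples data.frame,
#'   ordered along the pull-out axis (>= 2 samples).
#' @return data.frame with one row per angle channel: channel, role, circMean,
#'   circSd, maxDrift (degrees).
#' @export
rotationalStability <- function(trajectory) {
  if (is(trajectory, "CompensationResult")) trajectory <- trajectory@dataset
  if (is(trajectory, "EnvironmentDataset")) trajectory <- measurements(trajectory)
  if (nrow(trajectory) < 2L) .fail("need at least 2 trajectory samples")
  roles <- c(phi_x = "roll", phi_y = "elevation", phi_z = "azimuth")
  out <- lapply(.ANGLE_CHANNELS, function(ch) {
    th <- wrapAngles(trajectory[[ch]])
    un <- unwrapAngles(th)
    data.frame(channel = ch, role = roles[[ch]],
               circMean = circularMean(th), circSd = circularSd(th),
               maxDrift = max(abs(un - un[1L])))
  })
  do.call(rbind, out)
}
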