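#' Build a calibrated ground-truth grid
#'
#' Enumerates a regular nx x ny lattice of pitch \code{pitchMm} at each layer
#' elevation, in row-major order (x index fastest, then y, then layer). The
#' default pitch of 8 mm matches the stepping of a calibrated pegboard phantom.
#'
#' @param pitchMm Lattice spacing in mm (> 0).
#' @param nx,ny Nodes per row / rows per layer.
#' @param layerElevations z elevation of each layer in mm.
#' @param layerMask Logical per layer; FALSE marks layers excluded from a use.
#' @return A \linkS4class{GroundTruthGrid}.
#' @export
#' @examples
#' makeGrid(8, nx = 2, ny = 1, layerElevations = 0)
makeGrid <- function(pitchMm = 8, nx = 5L, ny = 4L,
                     layerElevations = c(0, 9.6, 19.2),
                     layerMask = rep(TRUE, length(layerElevations))) {
  if (!is.finite(pitchMm) || pitchMm <= 0) .fail("pitch must be positive")
  pitchMm <- as.numeric(pitchMm)
  nx <- as.integer(nx); ny <- as.integer(ny)
  nl <- length(layerElevations)
  if (nx * ny * nl < 2L) .fail("grid needs at least 2 nodes")
  idx <- expand.grid(ix = seq_len(nx), iy = seq_len(ny), layer = seq_len(nl))
  nodes <- data.frame(node_id = seq_len(nrow(idx)),
                      ix = idx$ix, iy = idx$iy, layer = idx$layer,
                      x = (idx$ix - 1) * pitchMm,
                      y = (idx$iy - 1) * pitchMm,
                      z = layerElevations[idx$layer])
  new("GroundTruthGrid", pitch = pitchMm, dims = c(nx, ny),
      layerElevations = as.numeric(layerElevations),
      layerMask = as.logical(layerMask), nodes = nodes)
}

#' True node positions by node id
#'
#' @param grid A \linkS4class{GroundTruthGrid}.
#' @param nodeIds Integer node ids.
#' @return Numeric matrix (length(nodeIds) x 3) of (x, y, z) in mm.
#' @export
nodePositions <- function(grid, nodeIds) {
  stopifnot(is(grid, "GroundTruthGrid"))
  i <- match(nodeIds, grid@nodes$node_id)
  if (anyNA(i)) .fail("unknown node id(s): ",
                      paste(nodeIds[is.na(i)], collapse = ", "))
  as.matrix(grid@nodes[i, c("x", "y", "z")])
}

#' Closed-form true distances between grid nodes
#'
#' @param grid A \linkS4class{GroundTruthGrid}.
#' @param i,j Integer node id vectors (recycled pairwise).
#' @return Euclidean distances in mm.
#' @export
trueDistances <- function(grid, i, j) {
  a <- nodePositions(grid, i)
  b <- nodePositions(grid, j)
  unname(sqrt(rowSums((a - b)^2)))
}

## Nodes of the grid restricted to its active layers.
activeNodes <- function(grid) {
  grid@nodes[grid@layerMask[grid@nodes$layer], , drop = FALSE]
}
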