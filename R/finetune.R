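## Post-hoc linear x-y fine-tuning. The domain translation fixes z, q and the
## orientation but passes x and y through untouched, so residual in-plane error
## remains. Because translated points lie in the laboratory domain, a single
## laboratory-domain linear model can correct them.

## Optimal 2D rigid alignment (rotation + translation, row-vector convention
## target ~ source %*% R + t), closed form via SVD.
.rigidAlign2d <- function(source, target) {
  cs <- colMeans(source); ct <- colMeans(target)
  S <- crossprod(sweep(source, 2L, cs), sweep(target, 2L, ct))
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, d)) %*% t(sv$v)
  list(rotation = R, translation = as.numeric(ct - cs %*% R))
}

#' Fit the linear x-y compensator
#'
#' Fits, by ordinary least squares, corrective in-plane offsets (dx, dy) as
#' linear functions of the features (x, y, z, q). The regression targets are
#' grid-anchored: the known lattice x-y positions, rigidly aligned (rotation +
#' translation, closed form, deterministic) to the measured point set so that
#' only non-rigid residual error -- the part that displacement error can see --
#' is attributed to the compensator.
#'
#' @param data A laboratory-domain \linkS4class{CompensationResult} or
#'   \linkS4class{EnvironmentDataset} whose samples carry grid node ids.
#' @param grid The \linkS4class{GroundTruthGrid}.
#' @return A \linkS4class{LinearCompensator}.
#' @export
fitLinearCompensator <- function(data, grid) {
  if (is(data, "CompensationResult")) data <- data@dataset
  stopifnot(is(data, "EnvironmentDataset"), is(grid, "GroundTruthGrid"))
  df <- measurements(data)
  if (nrow(df) < 6L) .fail("need at least 6 points to fit 5 coefficients")
  gxy <- nodePositions(grid, df$node_id)[, 1:2, drop = FALSE]
  mxy <- as.matrix(df[, c("x", "y")])
  al <- .rigidAlign2d(gxy, mxy)
  target <- sweep(gxy %*% al$rotation, 2L, al$translation, "+")
  offsets <- target - mxy

  design <- cbind(intercept = 1, x = df$x, y = df$y, z = df$z, q = df$q)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    drop <- colnames(design)[qrd$pivot[(qrd$rank + 1L):ncol(design)]]
    .fail("rank-deficient fine-tuning design; collinear feature(s): ",
          paste(drop, collapse = ", "))
  }
  coefX <- qr.coef(qrd, offsets[, 1L])
  coefY <- qr.coef(qrd, offsets[, 2L])
  res <- offsets - cbind(design %*% coefX, design %*% coefY)
  new("LinearCompensator",
      coefX = stats::setNames(as.numeric(coefX), colnames(design)),
      coefY = stats::setNames(as.numeric(coefY), colnames(design)),
      residualRmse = sqrt(mean(rowSums(res^2))),
      rotation = al$rotation, translation = al$translation)
}

#' Apply the linear x-y compensator
#'
#' Shifts only the x and y components by the predicted offsets; z, q and the
#' orientation channels are untouched. For a \linkS4class{CompensationResult}
#' the predictive uncertainty is recomputed as the quadrature sum of the
#' ensemble spread and the compensator's residual RMSE, the fine-tuning step
#' being an additional source of predictive uncertainty.
#'
#' @param model A fitted \linkS4class{LinearCompensator}.
#' @param data A \linkS4class{CompensationResult}, \linkS4class{EnvironmentDataset}
#'   or samples data.frame.
#' @return Object of the same kind as the input with corrected x, y.
#' @export
applyFinetune <- function(model, data) {
  stopifnot(is(model, "LinearCompensator"))
  shift <- function(df) {
    design <- cbind(1, df$x, df$y, df$z, df$q)
    df$x <- df$x + as.numeric(design %*% model@coefX)
    df$y <- df$y + as.numeric(design %*% model@coefY)
    df
  }
  if (is(data, "CompensationResult")) {
    ds <- data@dataset
    ds@samples <- shift(measurements(ds))
    sig <- sqrt(data@sigmaPred^2 + model@residualRmse^2)
    new("CompensationResult", dataset = ds, sigmaPred = sig,
        sigmaAggregate = mean(sig), memberSamples = data@memberSamples)
  } else if (is(data, "EnvironmentDataset")) {
    data@samples <- shift(measurements(data))
    data
  } else {
    shift(data)
  }
}
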