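## Dense networks used by the domain-translation model. These are deliberately
## tiny (hidden width 16), so all linear algebra is plain base-R matrix code;
## forward and backward passes are exact and deterministic given parameters.

.initDense <- function(dims, seed, scale = 1) {
  withSeed(seed, {
    nl <- length(dims) - 1L
    W <- vector("list", nl)
    b <- vector("list", nl)
    for (k in seq_len(nl)) {
      bound <- scale / sqrt(dims[k])  # uniform +-scale/sqrt(fan-in)
      W[[k]] <- matrix(stats::runif(dims[k] * dims[k + 1L], -bound, bound),
                       dims[k], dims[k + 1L])
      b[[k]] <- stats::runif(dims[k + 1L], -bound, bound)
    }
    list(W = W, b = b)
  })
}

## Superimpose an identity pathway for the 5 translated channels (input
## channels 3..7 routed through hidden units 1..5 to the 5 outputs). On
## normalized inputs the leaky-rectifier is the identity for positive values,
## so a freshly built generator is a near-identity (no-op) compensator: the
## cycle loss starts near its optimum and training refines the translation
## instead of first having to rediscover the input.
.identityPath <- function(p, dims) {
  nl <- length(dims) - 1L
  for (j in 1:5) p$W[[1L]][2L + j, j] <- p$W[[1L]][2L + j, j] + 1
  for (k in seq(2L, nl)) {
    for (j in 1:5) p$W[[k]][j, j] <- p$W[[k]][j, j] + 1
  }
  p
}

#' Build a generator network
#'
#' Generators take the normalized 7-channel point (x, y, z, q, phi_x, phi_y,
#' phi_z) and emit the 5 domain-translated channels (z, q, phi_x, phi_y,
#' phi_z): four dense layers of width 16, leaky-rectifier activations with
#' slope 0.01, linear head. The x and y components are never produced by the
#' network; they are passed through unchanged by the compensation wrapper.
#'
#' Generators are initialized as a near-identity map: seeded small random
#' weights superimposed with an identity pathway for the five translated
#' channels, so an untrained model pair is approximately the no-op compensator.
#' Training then refines the translation away from the identity rather than
#' first having to recover the input, which keeps the strongly weighted cycle
#' loss near its optimum from the start.
#'
#' @param seed Initialization seed.
#' @param identityInit Superimpose the identity pathway (default TRUE)?
#' @return A \linkS4class{DenseNetwork}.
#' @export
buildGenerator <- function(seed = 1L, identityInit = TRUE) {
  dims <- c(7L, 16L, 16L, 16L, 5L)
  p <- .initDense(dims, seed, scale = if (identityInit) 0.1 else 1)
  if (identityInit) p <- .identityPath(p, dims)
  new("DenseNetwork", dims = dims, weights = p$W, biases = p$b,
      hiddenSlope = 0.01, outputActivation = "linear", seed = as.integer(seed))
}

#' Build a discriminator network
#'
#' Discriminators take a normalized 7-channel point and emit the probability
#' that it stems from their target domain: three dense layers of width 16,
#' leaky-rectifier activations with slope 0.2, sigmoid head (output strictly
#' inside (0, 1)).
#'
#' @param seed Initialization seed.
#' @return A \linkS4class{DenseNetwork}.
#' @export
buildDiscriminator <- function(seed = 1L) {
  dims <- c(7L, 16L, 16L, 1L)
  p <- .initDense(dims, seed)
  new("DenseNetwork", dims = dims, weights = p$W, biases = p$b,
      hiddenSlope = 0.2, outputActivation = "sigmoid", seed = as.integer(seed))
}

#' Number of trainable parameters
#'
#' @param net A \linkS4class{DenseNetwork}.
#' @return Integer parameter count (weights plus biases).
#' @export
parameterCount <- function(net) {
  stopifnot(is(net, "DenseNetwork"))
  sum(vapply(net@weights, length, 1L)) + sum(vapply(net@biases, length, 1L))
}

## Forward pass. X: n x dims[1]. Returns output only.
netForward <- function(net, X) {
  fw <- .forwardCache(net, X)
  fw$out
}

## Forward pass keeping activations for backprop.
## Returns list(out, hs = list of post-activation hidden matrices, pre = final
## pre-activation). Hidden activation: leaky ReLU; head: linear or sigmoid.
.forwardCache <- function(net, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != net@dims[1L]) .fail("input has wrong dimensionality")
  nl <- length(net@weights)
  hs <- vector("list", nl)  # hs[[k]]: activation entering layer k
  h <- X
  for (k in seq_len(nl)) {
    hs[[k]] <- h
    a <- sweep(h %*% net@weights[[k]], 2L, net@biases[[k]], "+")
    if (k < nl) {
      h <- ifelse(a > 0, a, net@hiddenSlope * a)
    } else {
      pre <- a
      h <- if (net@outputActivation == "sigmoid") 1 / (1 + exp(-a)) else a
    }
  }
  list(out = h, hs = hs, pre = pre)
}

## Backward pass. dOut is the loss gradient wrt the network output, unless
## fromPre = TRUE, in which case it is wrt the final pre-activation (the
## numerically stable route for BCE-through-sigmoid). Returns parameter
## gradients and the gradient wrt the input.
.backward <- function(net, cache, dOut, fromPre = FALSE) {
  nl <- length(net@weights)
  dW <- vector("list", nl)
  db <- vector("list", nl)
  da <- if (fromPre) {
    dOut
  } else if (net@outputActivation == "sigmoid") {
    dOut * cache$out * (1 - cache$out)
  } else {
    dOut
  }
  for (k in rev(seq_len(nl))) {
    h <- cache$hs[[k]]
    dW[[k]] <- crossprod(h, da)
    db[[k]] <- colSums(da)
    dh <- da %*% t(net@weights[[k]])
    if (k > 1L) {
      ## derivative of the leaky rectifier at the pre-activation of layer k-1;
      ## recover its sign from the stored post-activation (same sign).
      act <- cache$hs[[k]]
      da <- dh * ifelse(act > 0, 1, net@hiddenSlope)
    } else {
      dX <- dh
    }
  }
  list(dW = dW, db = db, dX = dX)
}

#' Translate points into the laboratory domain
#'
#' Applies the C-to-laboratory generator of a model pair to every sample:
#' inputs are normalized with the pair's training bounds, the generator output
#' replaces the z, q and orientation channels (denormalized, angles wrapped),
#' and the x and y components are copied bit-identically from the input -- a
#' structural guarantee, independent of the trained weights, that keeps the
#' translation explicable.
#'
#' @param pair A \linkS4class{ModelPair}.
#' @param dataset An \linkS4class{EnvironmentDataset} or samples data.frame.
#' @return Object of the same kind as the input, with compensated channels; a
#'   dataset keeps its name (suffixed \code{"_gCL"}) and becomes domain
#'   \code{"L"}.
#' @export
compensatePoints <- function(pair, dataset) {
  stopifnot(is(pair, "ModelPair"))
  df <- if (is(dataset, "EnvironmentDataset")) measurements(dataset) else dataset
  checkSampleFrame(df)
  out <- df
  if (nrow(df) > 0L) {
    Xn <- normalizeSamples(df, pair@bounds)
    gen <- netForward(pair@gCL, Xn)
    mm <- denormalizeChannels(gen, pair@bounds, c("z", "q", .ANGLE_CHANNELS))
    out$z <- mm[, 1L]
    out$q <- mm[, 2L]
    out$phi_x <- wrapAngles(mm[, 3L])
    out$phi_y <- wrapAngles(mm[, 4L])
    out$phi_z <- wrapAngles(mm[, 5L])
  }
  if (is(dataset, "EnvironmentDataset")) {
    environmentDataset(paste0(dataset@name, "_gCL"), "L", out)
  } else {
    out
  }
}

#' Save / load a model pair as a JSON checkpoint
#'
#' The checkpoint holds all four parameter sets, the normalization bounds, the
#' seed and the training mode, in plain JSON (full double precision).
#'
#' @param pair A \linkS4class{ModelPair}.
#' @param path Checkpoint file path.
#' @return \code{saveModelPair} invisibly returns \code{path};
#'   \code{readModelPair} returns the restored \linkS4class{ModelPair} (without
#'   the training log).
#' @export
saveModelPair <- function(pair, path) {
  stopifnot(is(pair, "ModelPair"))
  netJson <- function(net) list(
    dims = net@dims, hiddenSlope = net@hiddenSlope,
    outputActivation = net@outputActivation, seed = net@seed,
    weights = lapply(net@weights, as.numeric),  # column-major
    biases = net@biases)
  obj <- list(format = "cycleEMT-modelpair-1",
              mode = pair@mode, seed = pair@seed,
              bounds = list(lower = pair@bounds@lower, upper = pair@bounds@upper),
              gCL = netJson(pair@gCL), gLC = netJson(pair@gLC),
              dCL = netJson(pair@dCL), dLC = netJson(pair@dLC))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveModelPair
#' @export
readModelPair <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "cycleEMT-modelpair-1"))
    .fail("not a cycleEMT model checkpoint: ", path)
  netFrom <- function(nj) {
    dims <- as.integer(nj$dims)
    W <- lapply(seq_len(length(dims) - 1L), function(k)
      matrix(as.numeric(nj$weights[[k]]), dims[k], dims[k + 1L]))
    new("DenseNetwork", dims = dims, weights = unname(W),
        biases = lapply(unname(nj$biases), as.numeric),
        hiddenSlope = nj$hiddenSlope, outputActivation = nj$outputActivation,
        seed = as.integer(nj$seed))
  }
  ## bounds are stored in canonical channel order
  lo <- stats::setNames(as.numeric(obj$bounds$lower), emtChannels())
  hi <- stats::setNames(as.numeric(obj$bounds$upper), emtChannels())
  new("ModelPair", gCL = netFrom(obj$gCL), gLC = netFrom(obj$gLC),
      dCL = netFrom(obj$dCL), dLC = netFrom(obj$dLC),
      bounds = new("NormalizationBounds", lower = lo, upper = hi),
      seed = as.integer(obj$seed), mode = obj$mode, log = data.frame())
}
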