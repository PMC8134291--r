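#' Create a training configuration
#'
#' Defaults are the reference protocol: generator loss weights
#' \code{lambdaAdv = 0.5}, \code{lambdaCycle = 10}, \code{lambdaComp = 1e-5};
#' Adam learning rate 5e-4, constant for the first 100 epochs and decaying
#' linearly to 0 at epoch 200; batch size 16; soft discriminator labels drawn
#' uniformly from [0.8, 1] (valid) and [0, 0.2] (fake); an ensemble of 10
#' sequentially trained initializations. \code{mode = "vanilla_gan"} is the
#' ablation: adversarial training without the cycle-consistency term.
#'
#' @param lambdaAdv,lambdaCycle,lambdaComp Generator loss weights.
#' @param lr Initial learning rate.
#' @param decayStartEpoch Epoch at which the linear decay begins.
#' @param totalEpochs Total number of epochs.
#' @param batchSize Minibatch size.
#' @param ensembleSize Number of ensemble members.
#' @param softValidRange,softFakeRange Soft-label uniform ranges.
#' @param mode \code{"cyclegan"} or \code{"vanilla_gan"}.
#' @param seed Master training seed.
#' @return A \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(lambdaAdv = 0.5, lambdaCycle = 10, lambdaComp = 1e-5,
                        lr = 5e-4, decayStartEpoch = 100L, totalEpochs = 200L,
                        batchSize = 16L, ensembleSize = 10L,
                        softValidRange = c(0.8, 1.0), softFakeRange = c(0.0, 0.2),
                        mode = c("cyclegan", "vanilla_gan"), seed = 1L) {
  mode <- match.arg(mode)
  new("TrainConfig", lambdaAdv = lambdaAdv, lambdaCycle = lambdaCycle,
      lambdaComp = lambdaComp, lr = lr,
      decayStartEpoch = as.integer(decayStartEpoch),
      totalEpochs = as.integer(totalEpochs), batchSize = as.integer(batchSize),
      ensembleSize = as.integer(ensembleSize),
      softValidRange = softValidRange, softFakeRange = softFakeRange,
      mode = mode, seed = as.integer(seed))
}

#' Learning-rate schedule
#'
#' Constant at \code{lr} until \code{decayStartEpoch}, then linear decay
#' reaching exactly 0 at \code{totalEpochs}.
#'
#' @param epoch Epoch number (0-based; may be fractional).
#' @param cfg A \linkS4class{TrainConfig}.
#' @return Learning rate at that epoch.
#' @export
#' @examples
#' cfg <- trainConfig()
#' learningRate(c(0, 100, 150, 200), cfg)
learningRate <- function(epoch, cfg) {
  stopifnot(is(cfg, "TrainConfig"))
  frac <- (cfg@totalEpochs - epoch) / (cfg@totalEpochs - cfg@decayStartEpoch)
  cfg@lr * pmax(0, pmin(1, frac))
}

## Elementwise binary cross-entropy, clamped away from log(0).
.bce <- function(p, y) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  -(y * log(p) + (1 - y) * log(1 - p))
}

## Assemble the full 7-channel normalized point from the pass-through x, y of
## the generator input and the 5 generated channels.
.passThrough <- function(input7, gen5) {
  cbind(input7[, 1:2, drop = FALSE], gen5)
}

#' Adversarial generator loss
#'
#' \code{BCE(dCL(gCL(xC)), labelValid) + BCE(dLC(gLC(xL)), labelValid)},
#' each term averaged over its batch: how well each generator fools its
#' discriminator.
#'
#' @param batchC,batchL Normalized (n x 7) batches from the C-arm / laboratory domain.
#' @param pair A \linkS4class{ModelPair}.
#' @param labelValid Valid label (scalar or per-sample vector).
#' @return Scalar loss.
#' @export
adversarialLoss <- function(batchC, batchL, pair, labelValid = 1) {
  if (NROW(batchC) == 0L || NROW(batchL) == 0L) .fail("empty batch")
  fakeL <- .passThrough(batchC, netForward(pair@gCL, batchC))
  fakeC <- .passThrough(batchL, netForward(pair@gLC, batchL))
  mean(.bce(netForward(pair@dCL, fakeL), labelValid)) +
    mean(.bce(netForward(pair@dLC, fakeC), labelValid))
}

#' Cycle-consistency loss
#'
#' L1 recovery residual of the round trips L -> C -> L and C -> L -> C,
#' averaged over the batch and the 7 channels (the passed-through x and y
#' channels contribute exactly 0).
#'
#' @inheritParams adversarialLoss
#' @return Named numeric: \code{recovL}, \code{recovC} and their sum \code{cycle}.
#' @export
cycleLoss <- function(batchC, batchL, pair) {
  if (NROW(batchC) == 0L || NROW(batchL) == 0L) .fail("empty batch")
  fakeL <- .passThrough(batchC, netForward(pair@gCL, batchC))
  fakeC <- .passThrough(batchL, netForward(pair@gLC, batchL))
  recovC <- netForward(pair@gLC, fakeL)
  recovL <- netForward(pair@gCL, fakeC)
  lC <- sum(abs(recovC - batchC[, 3:7, drop = FALSE])) / (nrow(batchC) * 7)
  lL <- sum(abs(recovL - batchL[, 3:7, drop = FALSE])) / (nrow(batchL) * 7)
  c(recovL = lL, recovC = lC, cycle = lL + lC)
}

#' Compensation (distance) loss
#'
#' Mean squared difference, in mm^2, between the pairwise distances of
#' translated points and the true lattice distances: distance error is
#' penalized only in the laboratory domain, where ground truth exists.
#'
#' @param batchC Normalized (n x 7) C-arm batch.
#' @param nodeIds Grid node id of each batch row.
#' @param pair A \linkS4class{ModelPair}.
#' @param grid The \linkS4class{GroundTruthGrid}.
#' @param pairs Two-column index matrix into batch rows; defaults to
#'   consecutive rows (1,2), (3,4), ...
#' @return Scalar loss (mm^2).
#' @export
compensationLoss <- function(batchC, nodeIds, pair, grid, pairs = NULL) {
  n <- NROW(batchC)
  if (n < 2L) .fail("compensation loss needs at least 2 samples")
  if (is.null(pairs))
    pairs <- matrix(seq_len(n - n %% 2L), ncol = 2L, byrow = TRUE)
  gen <- netForward(pair@gCL, batchC)
  xy <- denormalizeChannels(batchC[, 1:2, drop = FALSE], pair@bounds, c("x", "y"))
  z <- denormalizeChannels(gen[, 1L, drop = FALSE], pair@bounds, "z")
  P <- cbind(xy, z)
  d <- sqrt(rowSums((P[pairs[, 1L], , drop = FALSE] -
                     P[pairs[, 2L], , drop = FALSE])^2))
  dtrue <- trueDistances(grid, nodeIds[pairs[, 1L]], nodeIds[pairs[, 2L]])
  mean((d - dtrue)^2)
}

#' Total generator loss
#'
#' The exact weighted sum \code{lambdaAdv * lAdv + lambdaCycle * lCycle +
#' lambdaComp * lComp}; in \code{vanilla_gan} mode the cycle term is excluded
#' (its weight is treated as 0).
#'
#' @param parts Named list or vector with \code{lAdv}, \code{lCycle}, \code{lComp}.
#' @param cfg A \linkS4class{TrainConfig}.
#' @return Scalar loss.
#' @export
totalGeneratorLoss <- function(parts, cfg) {
  stopifnot(is(cfg, "TrainConfig"))
  lc <- if (cfg@mode == "vanilla_gan") 0 else cfg@lambdaCycle
  cfg@lambdaAdv * parts[["lAdv"]] + lc * parts[["lCycle"]] +
    cfg@lambdaComp * parts[["lComp"]]
}

## ---- internal parameter plumbing -------------------------------------------

.netTensors <- function(net) c(net@weights, net@biases)

.setNetTensors <- function(net, tensors) {
  nl <- length(net@weights)
  net@weights <- tensors[seq_len(nl)]
  net@biases <- tensors[nl + seq_len(nl)]
  net
}

.gradTensors <- function(bk) c(bk$dW, bk$db)

.zeroTensors <- function(tensors) lapply(tensors, function(x) x * 0)

.addTensors <- function(a, b) Map(`+`, a, b)

.adamInit <- function(tensors) {
  list(m = .zeroTensors(tensors), v = .zeroTensors(tensors), t = 0L)
}

## One Adam step over a tensor list. beta1 = 0.5 (the usual setting for
## adversarial training, as in the original cycle-consistent GAN code),
## beta2 = 0.999, eps = 1e-8.
.adamStep <- function(state, tensors, grads, lr) {
  b1 <- 0.5; b2 <- 0.999; eps <- 1e-8
  state$t <- state$t + 1L
  c1 <- 1 - b1^state$t
  c2 <- 1 - b2^state$t
  for (i in seq_along(tensors)) {
    state$m[[i]] <- b1 * state$m[[i]] + (1 - b1) * grads[[i]]
    state$v[[i]] <- b2 * state$v[[i]] + (1 - b2) * grads[[i]]^2
    tensors[[i]] <- tensors[[i]] -
      lr * (state$m[[i]] / c1) / (sqrt(state$v[[i]] / c2) + eps)
  }
  list(state = state, tensors = tensors)
}

## ---- training ---------------------------------------------------------------

#' Train a cycle-consistent model pair
#'
#' Runs the adversarial training loop on unpaired batches from the two domains:
#' per step, each discriminator is first updated by its own Adam optimizer on
#' real samples (soft valid labels) versus generated samples (gradient-detached,
#' soft fake labels), then the two generators are updated jointly by one shared
#' Adam optimizer on the weighted sum of adversarial, cycle and compensation
#' losses, evaluated against the updated discriminators.
#' C-arm batches are sampled as lattice-neighbor pairs so the true
#' pair distances of the compensation loss are defined. Fully reproducible for
#' a fixed config and seed (single RNG stream, deterministic forward/backward).
#'
#' @param cfg A \linkS4class{TrainConfig}.
#' @param dataC List of C-arm-domain \linkS4class{EnvironmentDataset} (or one).
#' @param dataL List of laboratory-domain datasets (or one).
#' @param grid The \linkS4class{GroundTruthGrid}.
#' @param bounds Optional pre-fitted \linkS4class{NormalizationBounds};
#'   defaults to bounds fitted on the union of all supplied datasets
#'   (validation data excluded).
#' @param dataV Optional list of validation \linkS4class{EnvironmentDataset}
#'   (C-arm domain). When given, the translation is scored every
#'   \code{valEvery} epochs by its displacement RMSE on these environments and
#'   the best-scoring network snapshot is returned (model selection; the
#'   validation environments are never trained on).
#' @param valEvery Epochs between validation scores.
#' @return A trained \linkS4class{ModelPair}; \code{trainingLog(pair)} holds the
#'   per-step loss breakdown (lAdv, lRecovL, lRecovC, lCycle, lComp, lTotal,
#'   lDCL, lDLC, lr).
#' @export
trainModelPair <- function(cfg, dataC, dataL, grid, bounds = NULL,
                           dataV = NULL, valEvery = 1L) {
  stopifnot(is(cfg, "TrainConfig"), is(grid, "GroundTruthGrid"))
  if (is(dataC, "EnvironmentDataset")) dataC <- list(dataC)
  if (is(dataL, "EnvironmentDataset")) dataL <- list(dataL)
  if (length(dataC) == 0L || length(dataL) == 0L)
    .fail("need at least one dataset per domain")
  if (any(vapply(dataC, envDomain, "") != "C") ||
      any(vapply(dataL, envDomain, "") != "L"))
    .fail("dataC must be domain C and dataL domain L")
  if (is.null(bounds)) bounds <- fitNormalization(c(dataC, dataL))

  XC <- do.call(rbind, lapply(dataC, normalizeSamples, bounds = bounds))
  XL <- do.call(rbind, lapply(dataL, normalizeSamples, bounds = bounds))
  nodeC <- unlist(lapply(dataC, nodeIndex), use.names = FALSE)
  XCxyMm <- do.call(rbind, lapply(dataC, function(d)
    as.matrix(measurements(d)[, c("x", "y")])))
  nC <- nrow(XC); nL <- nrow(XL)

  ## lattice-neighbor pairs per C dataset, re-indexed into the pooled matrix
  off <- 0L
  pairRows <- NULL; pairTrue <- NULL
  for (d in dataC) {
    ds <- buildDisplacementPairs(d, grid, "lattice-neighbors")
    pairRows <- rbind(pairRows, ds@pairs + off)
    pairTrue <- c(pairTrue, ds@trueDist)
    off <- off + nrow(measurements(d))
  }
  nPr <- nrow(pairRows)
  if (nPr < 1L) .fail("no lattice-neighbor pairs available in the C-arm data")

  zRange <- (bounds@upper - bounds@lower)[["z"]]
  halfBatch <- max(1L, cfg@batchSize %/% 2L)
  stepsPerEpoch <- as.integer(ceiling(max(nC, nL) / cfg@batchSize))
  nSteps <- cfg@totalEpochs * stepsPerEpoch
  useCycle <- cfg@mode == "cyclegan" && cfg@lambdaCycle > 0
  lambdaCycleEff <- if (cfg@mode == "vanilla_gan") 0 else cfg@lambdaCycle

  ## validation scoring: displacement RMSE of the current translation
  if (!is.null(dataV)) {
    if (is(dataV, "EnvironmentDataset")) dataV <- list(dataV)
    valSets <- lapply(dataV, function(d) {
      ds <- buildDisplacementPairs(d, grid, "lattice-neighbors")
      list(X = normalizeSamples(d, bounds),
           xy = as.matrix(measurements(d)[, c("x", "y")]),
           pairs = ds@pairs, trueDist = ds@trueDist)
    })
    valScore <- function(gen) {
      errs <- unlist(lapply(valSets, function(v) {
        z <- netForward(gen, v$X)[, 1L] * zRange + bounds@lower[["z"]]
        P <- cbind(v$xy, z)
        d <- sqrt(rowSums((P[v$pairs[, 1L], , drop = FALSE] -
                           P[v$pairs[, 2L], , drop = FALSE])^2))
        d - v$trueDist
      }))
      sqrt(mean(errs^2))
    }
  }
  gCL <- buildGenerator(deriveSeed(cfg@seed, 11L))
  gLC <- buildGenerator(deriveSeed(cfg@seed, 12L))
  dCL <- buildDiscriminator(deriveSeed(cfg@seed, 13L))
  dLC <- buildDiscriminator(deriveSeed(cfg@seed, 14L))

  ## score the untrained (near-identity, i.e. no-op) snapshot first, so the
  ## selected model is never worse on validation than not compensating at all
  valHist <- NULL
  if (!is.null(dataV)) {
    bestScore <- valScore(gCL)
    valHist <- rbind(valHist, c(-1, bestScore))
    best <- list(gCL = gCL, gLC = gLC, dCL = dCL, dLC = dLC)
  } else {
    bestScore <- Inf
    best <- NULL
  }
  adamG <- .adamInit(c(.netTensors(gCL), .netTensors(gLC)))
  adamD1 <- .adamInit(.netTensors(dCL))
  adamD2 <- .adamInit(.netTensors(dLC))

  logM <- matrix(NA_real_, nSteps, 11L)
  colnames(logM) <- c("epoch", "step", "lAdv", "lRecovL", "lRecovC", "lCycle",
                      "lComp", "lTotal", "lDCL", "lDLC", "lr")
  row <- 0L

  withSeed(cfg@seed, {
    for (epoch in seq_len(cfg@totalEpochs) - 1L) {
      lr <- learningRate(epoch, cfg)
      for (step in seq_len(stepsPerEpoch)) {
        ip <- sample.int(nPr, halfBatch, replace = nPr < halfBatch)
        rows <- as.vector(t(pairRows[ip, , drop = FALSE]))
        bC <- XC[rows, , drop = FALSE]
        dtrue <- pairTrue[ip]
        il <- sample.int(nL, cfg@batchSize, replace = nL < cfg@batchSize)
        bL <- XL[il, , drop = FALSE]
        nb <- nrow(bC); ml <- nrow(bL)

        ## ---- forward generators (fakes used by both updates) -------------
        fw1 <- .forwardCache(gCL, bC);  outCL <- fw1$out
        fakeL <- .passThrough(bC, outCL)
        fw2 <- .forwardCache(gLC, bL);  outLC <- fw2$out
        fakeC <- .passThrough(bL, outLC)

        ## ---- discriminator updates first (fakes detached) -----------------
        lvD <- stats::runif(ml, cfg@softValidRange[1], cfg@softValidRange[2])
        lfD <- stats::runif(nb, cfg@softFakeRange[1], cfg@softFakeRange[2])
        fwR <- .forwardCache(dCL, bL); pR <- fwR$out
        fwF <- .forwardCache(dCL, fakeL); pF <- fwF$out
        lDCL <- 0.5 * (mean(.bce(pR, lvD)) + mean(.bce(pF, lfD)))
        bkR <- .backward(dCL, fwR, 0.5 * (pR - lvD) / ml, fromPre = TRUE)
        bkF <- .backward(dCL, fwF, 0.5 * (pF - lfD) / nb, fromPre = TRUE)
        up <- .adamStep(adamD1, .netTensors(dCL),
                        .addTensors(.gradTensors(bkR), .gradTensors(bkF)), lr)
        adamD1 <- up$state
        dCL <- .setNetTensors(dCL, up$tensors)

        lvD <- stats::runif(nb, cfg@softValidRange[1], cfg@softValidRange[2])
        lfD <- stats::runif(ml, cfg@softFakeRange[1], cfg@softFakeRange[2])
        fwR <- .forwardCache(dLC, bC); pR <- fwR$out
        fwF <- .forwardCache(dLC, fakeC); pF <- fwF$out
        lDLC <- 0.5 * (mean(.bce(pR, lvD)) + mean(.bce(pF, lfD)))
        bkR <- .backward(dLC, fwR, 0.5 * (pR - lvD) / nb, fromPre = TRUE)
        bkF <- .backward(dLC, fwF, 0.5 * (pF - lfD) / ml, fromPre = TRUE)
        up <- .adamStep(adamD2, .netTensors(dLC),
                        .addTensors(.gradTensors(bkR), .gradTensors(bkF)), lr)
        adamD2 <- up$state
        dLC <- .setNetTensors(dLC, up$tensors)

        ## ---- generator update against the updated discriminators ----------
        lvC <- stats::runif(nb, cfg@softValidRange[1], cfg@softValidRange[2])
        lvL <- stats::runif(ml, cfg@softValidRange[1], cfg@softValidRange[2])
        fwD1 <- .forwardCache(dCL, fakeL); pC <- fwD1$out
        fwD2 <- .forwardCache(dLC, fakeC); pL <- fwD2$out
        lAdv <- mean(.bce(pC, lvC)) + mean(.bce(pL, lvL))

        dOutCL <- matrix(0, nb, 5L)
        dOutLC <- matrix(0, ml, 5L)
        bkD <- .backward(dCL, fwD1, cfg@lambdaAdv * (pC - lvC) / nb, fromPre = TRUE)
        dOutCL <- dOutCL + bkD$dX[, 3:7, drop = FALSE]
        bkD <- .backward(dLC, fwD2, cfg@lambdaAdv * (pL - lvL) / ml, fromPre = TRUE)
        dOutLC <- dOutLC + bkD$dX[, 3:7, drop = FALSE]

        gradA <- NULL; gradB <- NULL
        if (useCycle) {
          fw3 <- .forwardCache(gLC, fakeL); recovC <- fw3$out
          fw4 <- .forwardCache(gCL, fakeC); recovL <- fw4$out
          resC <- recovC - bC[, 3:7, drop = FALSE]
          resL <- recovL - bL[, 3:7, drop = FALSE]
          lRecovC <- sum(abs(resC)) / (nb * 7)
          lRecovL <- sum(abs(resL)) / (ml * 7)
          bk3 <- .backward(gLC, fw3, cfg@lambdaCycle * sign(resC) / (nb * 7))
          gradB <- .gradTensors(bk3)
          dOutCL <- dOutCL + bk3$dX[, 3:7, drop = FALSE]
          bk4 <- .backward(gCL, fw4, cfg@lambdaCycle * sign(resL) / (ml * 7))
          gradA <- .gradTensors(bk4)
          dOutLC <- dOutLC + bk4$dX[, 3:7, drop = FALSE]
        } else {
          lRecovC <- 0; lRecovL <- 0
        }
        lCycle <- lRecovL + lRecovC

        ## compensation loss on translated C points, in mm
        zmm <- outCL[, 1L] * zRange + bounds@lower[["z"]]
        P <- cbind(XCxyMm[rows, , drop = FALSE], zmm)
        oddI <- seq(1L, nb, by = 2L); evenI <- oddI + 1L
        diffP <- P[oddI, , drop = FALSE] - P[evenI, , drop = FALSE]
        dmm <- sqrt(rowSums(diffP^2))
        errD <- dmm - dtrue
        lComp <- mean(errD^2)
        if (cfg@lambdaComp > 0) {
          gpair <- 2 * errD / length(errD)
          dPz <- gpair * diffP[, 3L] / pmax(dmm, 1e-12)
          dz <- numeric(nb)
          dz[oddI] <- dPz; dz[evenI] <- -dPz
          dOutCL[, 1L] <- dOutCL[, 1L] + cfg@lambdaComp * dz * zRange
        }

        bk1 <- .backward(gCL, fw1, dOutCL)
        gradA <- if (is.null(gradA)) .gradTensors(bk1)
                 else .addTensors(gradA, .gradTensors(bk1))
        bk2 <- .backward(gLC, fw2, dOutLC)
        gradB <- if (is.null(gradB)) .gradTensors(bk2)
                 else .addTensors(gradB, .gradTensors(bk2))

        tensors <- c(.netTensors(gCL), .netTensors(gLC))
        up <- .adamStep(adamG, tensors, c(gradA, gradB), lr)
        adamG <- up$state
        nT <- length(up$tensors) %/% 2L
        gCL <- .setNetTensors(gCL, up$tensors[seq_len(nT)])
        gLC <- .setNetTensors(gLC, up$tensors[nT + seq_len(nT)])

        lTotal <- cfg@lambdaAdv * lAdv + lambdaCycleEff * lCycle +
          cfg@lambdaComp * lComp
        row <- row + 1L
        logM[row, ] <- c(epoch, step, lAdv, lRecovL, lRecovC, lCycle,
                         lComp, lTotal, lDCL, lDLC, lr)
      }
      if (!is.null(dataV) &&
          (epoch %% valEvery == 0L || epoch == cfg@totalEpochs - 1L)) {
        sc <- valScore(gCL)
        valHist <- rbind(valHist, c(epoch, sc))
        if (sc < bestScore) {
          bestScore <- sc
          best <- list(gCL = gCL, gLC = gLC, dCL = dCL, dLC = dLC)
        }
      }
    }
  })
  if (!is.null(best)) {
    gCL <- best$gCL; gLC <- best$gLC; dCL <- best$dCL; dLC <- best$dLC
  }

  log <- as.data.frame(logM)
  if (!is.null(valHist)) {
    valHist <- as.data.frame(valHist)
    names(valHist) <- c("epoch", "valRmse")
    attr(log, "validation") <- valHist
  }
  new("ModelPair", gCL = gCL, gLC = gLC, dCL = dCL, dLC = dLC,
      bounds = bounds, seed = cfg@seed, mode = cfg@mode, log = log)
}

#' Train a deep ensemble of model pairs
#'
#' Sequentially trains \code{ensembleSize} members that differ only in their
#' initialization/training seed (master seed plus member index). Averaging
#' their predictions improves accuracy; their spread approximates epistemic
#' uncertainty.
#'
#' @inheritParams trainModelPair
#' @return List of trained \linkS4class{ModelPair} objects.
#' @export
trainEnsemble <- function(cfg, dataC, dataL, grid, bounds = NULL,
                          dataV = NULL, valEvery = 1L) {
  stopifnot(is(cfg, "TrainConfig"))
  lapply(seq_len(cfg@ensembleSize) - 1L, function(i) {
    mcfg <- cfg
    mcfg@seed <- cfg@seed + i
    trainModelPair(mcfg, dataC, dataL, grid, bounds = bounds,
                   dataV = dataV, valEvery = valEvery)
  })
}

#' Ensemble compensation with predictive uncertainty
#'
#' Translates a dataset with every ensemble member and combines the members:
#' x, y pass through untouched; z and q are averaged arithmetically; the
#' orientation angles by circular mean. The per-point predictive spread
#' sigma_pred is the across-member standard deviation of the compensated
#' position (\code{\link{predictionSpread}}); a single-member ensemble has
#' spread exactly 0.
#'
#' @param members List of trained \linkS4class{ModelPair} objects.
#' @param dataset An \linkS4class{EnvironmentDataset}.
#' @return A \linkS4class{CompensationResult}.
#' @export
ensembleCompensate <- function(members, dataset) {
  if (is(members, "ModelPair")) members <- list(members)
  if (length(members) == 0L) .fail("need at least one ensemble member")
  stopifnot(is(dataset, "EnvironmentDataset"))
  outs <- lapply(members, function(m) measurements(compensatePoints(m, dataset)))
  mean_ <- function(col) rowMeans(vapply(outs, `[[`, numeric(nrow(outs[[1]])), col))
  agg <- measurements(dataset)
  agg$z <- mean_("z")
  agg$q <- mean_("q")
  for (ch in .ANGLE_CHANNELS) {
    th <- vapply(outs, `[[`, numeric(nrow(outs[[1]])), ch)
    if (is.null(dim(th))) th <- matrix(th, nrow = 1L)
    agg[[ch]] <- apply(th, 1L, circularMean)
  }
  sp <- if (length(members) >= 2L) predictionSpread(outs)
        else list(perPoint = rep(0, nrow(agg)), aggregate = 0)
  ds <- environmentDataset(paste0(dataset@name, "_ens"), "L", agg)
  new("CompensationResult", dataset = ds, sigmaPred = sp$perPoint,
      sigmaAggregate = sp$aggregate, memberSamples = outs)
}
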