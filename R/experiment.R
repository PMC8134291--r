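## End-to-end experiment plumbing: YAML configs, on-disk dataset suites,
## checkpoints and Table-style evaluation reports. The heavy lifting lives in
## the simulator, trainer and metrics modules; everything here is orchestration.

.required <- function(lst, keys, what) {
  for (k in keys) if (is.null(lst[[k]])) .fail("missing config key '", k, "' in ", what)
  invisible(lst)
}

#' Read a suite configuration from YAML
#'
#' Schema (snake_case keys): \code{seed}; \code{grid} (pitch_mm, nx, ny,
#' layer_elevations); \code{lab} (name, layers); \code{carm} (list of name,
#' distance_cm, gantry_angle_deg, role); optional \code{field} and
#' \code{acquisition} overrides for \code{\link{distortionField}} /
#' \code{\link{acquisitionSpec}}.
#'
#' @param path YAML file path.
#' @return List with \code{grid} (a \linkS4class{GroundTruthGrid}) and
#'   \code{config} (a \code{\link{suiteConfig}}).
#' @export
readSuiteConfig <- function(path) {
  y <- yaml::read_yaml(path)
  .required(y, c("seed", "grid", "lab", "carm"), basename(path))
  .required(y$grid, c("pitch_mm", "nx", "ny", "layer_elevations"), "grid")
  .required(y$lab, c("name", "layers"), "lab")
  grid <- makeGrid(y$grid$pitch_mm, y$grid$nx, y$grid$ny,
                   unlist(y$grid$layer_elevations))
  carm <- do.call(rbind, lapply(y$carm, function(e) {
    .required(e, c("name", "distance_cm", "role"), "carm entry")
    data.frame(name = e$name, distance_cm = e$distance_cm,
               gantry_angle_deg = if (is.null(e$gantry_angle_deg)) NA_real_
                                  else e$gantry_angle_deg,
               role = e$role)
  }))
  snake2camel <- function(lst, map) {
    out <- list()
    for (k in names(lst)) {
      if (is.null(map[[k]])) .fail("unknown config key '", k, "'")
      out[[map[[k]]]] <- lst[[k]]
    }
    out
  }
  fieldMap <- list(amplitude_mm = "amplitudeMm", reference_distance_cm = "referenceDistanceCm",
                   distance_exponent = "distanceExponent", length_scale_mm = "lengthScaleMm",
                   axis_weights = "axisWeights", n_bumps = "nBumps",
                   env_perturb_frac = "envPerturbFrac", quality_base = "qualityBase",
                   quality_coupling = "qualityCoupling",
                   quality_baseline_sd = "qualityBaselineSd",
                   angle_noise_deg = "angleNoiseDeg")
  acqMap <- list(samples_per_point = "samplesPerPoint", noise_sd_mm = "noiseSdMm",
                 quality_noise_sd = "qualityNoiseSd", angle_noise_sd_deg = "angleNoiseSdDeg")
  cfg <- suiteConfig(labName = y$lab$name, labLayers = unlist(y$lab$layers),
                     carm = carm,
                     field = snake2camel(y$field, fieldMap),
                     intrinsic = snake2camel(y$intrinsic,
                                             list(scale_sd = "scaleSd",
                                                  translation_sd = "translationSd")),
                     acquisition = snake2camel(y$acquisition, acqMap),
                     seed = y$seed)
  list(grid = grid, config = cfg)
}

#' Read a training configuration from YAML
#'
#' Keys (all optional, defaults as in \code{\link{trainConfig}}): lambda_adv,
#' lambda_cycle, lambda_comp, lr, decay_start_epoch, total_epochs, batch_size,
#' ensemble_size, mode, seed.
#'
#' @param path YAML file path.
#' @return A \linkS4class{TrainConfig}.
#' @export
readTrainConfig <- function(path) {
  y <- yaml::read_yaml(path)
  map <- list(lambda_adv = "lambdaAdv", lambda_cycle = "lambdaCycle",
              lambda_comp = "lambdaComp", lr = "lr",
              decay_start_epoch = "decayStartEpoch", total_epochs = "totalEpochs",
              batch_size = "batchSize", ensemble_size = "ensembleSize",
              mode = "mode", seed = "seed")
  args <- list()
  for (k in names(y)) {
    if (is.null(map[[k]])) .fail("unknown config key '", k, "'")
    args[[map[[k]]]] <- y[[k]]
  }
  do.call(trainConfig, args)
}

.gridToJson <- function(grid) {
  list(pitch_mm = grid@pitch, nx = grid@dims[1], ny = grid@dims[2],
       layer_elevations = grid@layerElevations, layer_mask = grid@layerMask)
}

.gridFromJson <- function(g) {
  makeGrid(g$pitch_mm, g$nx, g$ny, unlist(g$layer_elevations),
           as.logical(unlist(g$layer_mask)))
}

#' Simulate an environment suite and write it to disk
#'
#' Generates the configured suite and writes one CSV (+ JSON metadata sidecar)
#' per environment, plus \code{manifest.json} describing the grid and the
#' environment roles. Byte-identical on rerun with the same config and seed.
#'
#' @param config A \code{\link{suiteConfig}} or path to a suite YAML; when a
#'   \code{suiteConfig} is given, \code{grid} must be supplied too.
#' @param outDir Output directory (created if needed).
#' @param grid A \linkS4class{GroundTruthGrid} (ignored when \code{config} is a
#'   YAML path, which carries its own grid).
#' @return Invisibly, the list of written datasets.
#' @export
runSimulate <- function(config, outDir, grid = NULL) {
  if (is.character(config)) {
    sc <- readSuiteConfig(config)
    grid <- sc$grid
    config <- sc$config
  }
  if (is.null(grid)) .fail("runSimulate needs a grid when config is not a YAML path")
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    .fail("cannot create output directory ", outDir)
  suite <- generateEnvironmentSuite(grid, config)
  roles <- stats::setNames(c("training", config$carm$role),
                           c(config$labName, config$carm$name))
  envs <- lapply(names(suite), function(nm) {
    d <- suite[[nm]]
    file <- paste0(nm, ".csv")
    writeDataset(d, file.path(outDir, file))
    list(name = nm, file = file, domain = d@domain, role = roles[[nm]],
         carm_distance_cm = d@carmDistance, gantry_angle_deg = d@gantryAngle)
  })
  manifest <- list(format = "cycleEMT-suite-1", seed = config$seed,
                   grid = .gridToJson(grid), lab_layers = config$labLayers,
                   environments = envs)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(suite)
}

#' Load a simulated suite from disk
#'
#' @param dataDir Directory written by \code{\link{runSimulate}}.
#' @return List with \code{grid}, \code{datasets} (named list) and \code{roles}
#'   (named character).
#' @export
readSuite <- function(dataDir) {
  mf <- file.path(dataDir, "manifest.json")
  if (!file.exists(mf)) .fail("no manifest.json in ", dataDir)
  manifest <- jsonlite::read_json(mf, simplifyVector = FALSE)
  if (!identical(manifest$format, "cycleEMT-suite-1"))
    .fail("unrecognized manifest format in ", mf)
  grid <- .gridFromJson(manifest$grid)
  datasets <- list()
  roles <- character()
  for (e in manifest$environments) {
    datasets[[e$name]] <- readDataset(file.path(dataDir, e$file))
    roles[[e$name]] <- e$role
  }
  list(grid = grid, datasets = datasets, roles = roles)
}

#' Evaluate raw and compensated accuracy over datasets
#'
#' Computes, per dataset and method, the displacement error summary and (for
#' ensemble methods) the aggregate predictive spread: the shape of a
#' method-by-environment accuracy table.
#'
#' @param grid The \linkS4class{GroundTruthGrid}.
#' @param datasets Named list of \linkS4class{EnvironmentDataset}.
#' @param members Optional list of trained \linkS4class{ModelPair} (method
#'   \code{"cyclegan"} or \code{"vanilla_gan"}, from the members' mode).
#' @param finetuneModel Optional \linkS4class{LinearCompensator} adding the
#'   fine-tuned method row.
#' @param scheme Displacement pair scheme.
#' @return data.frame with columns method, dataset, rmse_mm, sigma_error_mm,
#'   n_pairs, sigma_pred_mm.
#' @export
evaluateSuite <- function(grid, datasets, members = NULL, finetuneModel = NULL,
                          scheme = "lattice-neighbors") {
  rowFor <- function(method, name, summary, sigma) {
    data.frame(method = method, dataset = name, rmse_mm = summary@rmse,
               sigma_error_mm = summary@sd, n_pairs = summary@nPairs,
               sigma_pred_mm = sigma)
  }
  out <- list()
  for (nm in names(datasets)) {
    d <- datasets[[nm]]
    raw <- displacementError(buildDisplacementPairs(d, grid, scheme))
    out[[length(out) + 1L]] <- rowFor("raw", nm, raw, NA_real_)
    if (!is.null(members)) {
      method <- members[[1L]]@mode
      res <- ensembleCompensate(members, d)
      cs <- displacementError(buildDisplacementPairs(res, grid, scheme))
      out[[length(out) + 1L]] <- rowFor(method, nm, cs, res@sigmaAggregate)
      if (!is.null(finetuneModel)) {
        ft <- applyFinetune(finetuneModel, res)
        fs <- displacementError(buildDisplacementPairs(ft, grid, scheme))
        out[[length(out) + 1L]] <- rowFor(paste0(method, "+finetune"), nm, fs,
                                          ft@sigmaAggregate)
      }
    }
  }
  do.call(rbind, out)
}

#' Fit the x-y fine-tuning model on a suite's laboratory-domain points
#'
#' The linear compensator is fitted on all points that live in the laboratory
#' domain: the raw laboratory measurements and the ensemble-translated
#' training-role C-arm datasets. Both carry grid node ids, so grid-anchored
#' offsets are defined; pooling them lets the regression see both the
#' tracker-intrinsic error (from the lab) and the residual in-plane error of
#' translated points (from the training environments).
#'
#' @param members List of trained \linkS4class{ModelPair}.
#' @param suite A list as returned by \code{\link{readSuite}}, or a named list
#'   with elements \code{grid}, \code{datasets}, \code{roles}.
#' @return A \linkS4class{LinearCompensator}.
#' @export
fitFinetuneOnSuite <- function(members, suite) {
  isL <- vapply(suite$datasets, envDomain, "") == "L"
  roles <- suite$roles[names(suite$datasets)]
  parts <- lapply(suite$datasets[!isL & roles == "training"], function(d)
    measurements(ensembleCompensate(members, d)))
  parts <- c(parts, lapply(suite$datasets[isL], measurements))
  fitLinearCompensator(
    environmentDataset("finetune_fit", "L", do.call(rbind, parts)),
    suite$grid)
}

#' Train an ensemble on a simulated suite directory
#'
#' Trains on the training-role C-arm environments and the laboratory dataset,
#' then writes one JSON checkpoint per ensemble member, the per-step loss logs
#' (CSV) and a training manifest.
#'
#' @param cfg A \linkS4class{TrainConfig} or path to a training YAML.
#' @param dataDir Suite directory from \code{\link{runSimulate}}.
#' @param outDir Output directory for checkpoints.
#' @return Invisibly, the list of trained members.
#' @export
runTrain <- function(cfg, dataDir, outDir) {
  if (is.character(cfg)) cfg <- readTrainConfig(cfg)
  suite <- readSuite(dataDir)
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    .fail("cannot create output directory ", outDir)
  isL <- vapply(suite$datasets, envDomain, "") == "L"
  dataL <- suite$datasets[isL]
  roles <- suite$roles[names(suite$datasets)]
  dataC <- suite$datasets[!isL & roles == "training"]
  dataV <- suite$datasets[!isL & roles == "validation"]
  if (length(dataV) == 0L) dataV <- NULL
  if (length(dataC) == 0L) .fail("no training-role C-arm datasets in ", dataDir)
  members <- trainEnsemble(cfg, dataC, dataL, suite$grid, dataV = dataV)
  files <- character(length(members))
  for (i in seq_along(members)) {
    files[i] <- sprintf("member_%02d.json", i)
    saveModelPair(members[[i]], file.path(outDir, files[i]))
    utils::write.csv(trainingLog(members[[i]]),
                     file.path(outDir, sprintf("losslog_%02d.csv", i)),
                     row.names = FALSE)
  }
  manifest <- list(format = "cycleEMT-ensemble-1", mode = cfg@mode,
                   seed = cfg@seed, members = files,
                   training_envs = names(dataC), lab_envs = names(dataL))
  jsonlite::write_json(manifest, file.path(outDir, "ensemble.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(members)
}

#' Load a trained ensemble from disk
#'
#' @param modelsDir Directory written by \code{\link{runTrain}}.
#' @return List of \linkS4class{ModelPair}.
#' @export
readEnsemble <- function(modelsDir) {
  mf <- file.path(modelsDir, "ensemble.json")
  if (!file.exists(mf))
    .fail("no ensemble.json in ", modelsDir, "; run the training step first")
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  lapply(manifest$members, function(f) readModelPair(file.path(modelsDir, f)))
}

#' Compensate a dataset file with a trained ensemble
#'
#' @param modelsDir Ensemble directory from \code{\link{runTrain}}.
#' @param dataCsv Input dataset CSV.
#' @param outCsv Output CSV; compensated channels plus a sigma_pred_mm column.
#' @return Invisibly, the \linkS4class{CompensationResult}.
#' @export
runCompensate <- function(modelsDir, dataCsv, outCsv) {
  members <- readEnsemble(modelsDir)
  d <- readDataset(dataCsv)
  res <- ensembleCompensate(members, d)
  out <- measurements(res)
  out$sigma_pred_mm <- res@sigmaPred
  utils::write.csv(out, outCsv, row.names = FALSE)
  invisible(res)
}

#' Evaluate a trained ensemble on the evaluation environments
#'
#' Produces the method-by-environment accuracy report (raw, domain-translated,
#' domain-translated + fine-tuned) on the evaluation-role datasets, fitting the
#' x-y fine-tuning model on the compensated laboratory data. Written as JSON
#' and CSV.
#'
#' @param dataDir Suite directory.
#' @param modelsDir Ensemble directory.
#' @param reportPath Output path ending in \code{.json} (a \code{.csv} sibling
#'   is written alongside).
#' @param role Which datasets to report on (default \code{"evaluation"}).
#' @return Invisibly, the report data.frame.
#' @export
runEvaluate <- function(dataDir, modelsDir, reportPath, role = "evaluation") {
  suite <- readSuite(dataDir)
  members <- readEnsemble(modelsDir)
  evalsets <- suite$datasets[suite$roles[names(suite$datasets)] == role]
  if (length(evalsets) == 0L) .fail("no datasets with role '", role, "' in ", dataDir)
  ftModel <- fitFinetuneOnSuite(members, suite)
  report <- evaluateSuite(suite$grid, evalsets, members, ftModel)
  jsonlite::write_json(report, reportPath, digits = NA, na = "null", pretty = TRUE)
  utils::write.csv(report, sub("\\.json$", ".csv", reportPath), row.names = FALSE)
  invisible(report)
}

#' Ablation: cycle-consistent versus vanilla adversarial training
#'
#' Trains, on identical data and seeds, the full cycle-consistent model and the
#' vanilla GAN (no cycle loss), and reports raw / cyclegan / vanilla_gan rows
#' for each evaluation environment.
#'
#' @param cfg A \linkS4class{TrainConfig} (its mode is overridden per arm).
#' @param dataDir Suite directory.
#' @param outDir Output directory for the two ensembles and the report.
#' @return Invisibly, the combined report data.frame.
#' @export
runAblation <- function(cfg, dataDir, outDir) {
  if (is.character(cfg)) cfg <- readTrainConfig(cfg)
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    .fail("cannot create output directory ", outDir)
  suite <- readSuite(dataDir)
  evalsets <- suite$datasets[suite$roles[names(suite$datasets)] == "evaluation"]
  reports <- list()
  for (mode in c("cyclegan", "vanilla_gan")) {
    acfg <- cfg
    acfg@mode <- mode
    dir <- file.path(outDir, mode)
    runTrain(acfg, dataDir, dir)
    members <- readEnsemble(dir)
    r <- evaluateSuite(suite$grid, evalsets, members)
    reports[[mode]] <- r[r$method != "raw", ]
    if (mode == "cyclegan")
      reports$raw <- r[r$method == "raw", ]
  }
  report <- do.call(rbind, c(reports["raw"], reports[c("cyclegan", "vanilla_gan")]))
  rownames(report) <- NULL
  jsonlite::write_json(report, file.path(outDir, "ablation.json"),
                       digits = NA, na = "null", pretty = TRUE)
  utils::write.csv(report, file.path(outDir, "ablation.csv"), row.names = FALSE)
  invisible(report)
}
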