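#' Create an EMT sample table
#'
#' Builds the canonical samples data.frame from channel vectors, checking
#' finiteness and wrapping orientation angles to [-180, 180).
#'
#' @param node_id Integer grid node id per sample.
#' @param x,y,z Position in mm.
#' @param q Device quality estimate (dimensionless).
#' @param phi_x,phi_y,phi_z Orientation angles in degrees.
#' @return data.frame with columns node_id, x, y, z, q, phi_x, phi_y, phi_z.
#' @export
#' @examples
#' emtSamples(1:2, x = c(0, 8), y = 0, z = 0, q = 1,
#'            phi_x = 0, phi_y = 0, phi_z = 185)
emtSamples <- function(node_id, x, y, z, q, phi_x = 0, phi_y = 0, phi_z = 0) {
  df <- data.frame(node_id = as.integer(node_id), x = x, y = y, z = z, q = q,
                   phi_x = wrapAngles(phi_x), phi_y = wrapAngles(phi_y),
                   phi_z = wrapAngles(phi_z))
  checkSampleFrame(df)
  df
}

#' Create an environment dataset
#'
#' @param name Environment label.
#' @param domain \code{"C"} (C-arm bedside) or \code{"L"} (laboratory bench).
#' @param samples Samples data.frame (see \code{\link{emtSamples}}).
#' @param carmDistance C-arm source distance in cm (domain C only).
#' @param gantryAngle Gantry rotation in degrees, if recorded.
#' @return An \linkS4class{EnvironmentDataset}.
#' @export
environmentDataset <- function(name, domain, samples,
                               carmDistance = NA_real_, gantryAngle = NA_real_) {
  samples$node_id <- as.integer(samples$node_id)
  samples[.ANGLE_CHANNELS] <- lapply(samples[.ANGLE_CHANNELS], wrapAngles)
  new("EnvironmentDataset", name = as.character(name), domain = as.character(domain),
      samples = samples[, c("node_id", emtChannels())],
      carmDistance = as.numeric(carmDistance), gantryAngle = as.numeric(gantryAngle))
}

#' Fit per-channel normalization bounds
#'
#' Bounds are the observed extrema over the union of all supplied datasets
#' (both domains), so the same linear map serves training and later inference.
#'
#' @param datasets A list of \linkS4class{EnvironmentDataset} objects (or one).
#' @return A \linkS4class{NormalizationBounds}.
#' @export
#' @examples
#' d <- environmentDataset("lab", "L",
#'        emtSamples(1:3, x = c(0, 8, 16), y = 0:2, z = c(0, 5, 9), q = 1:3,
#'                   phi_x = c(-1, 0, 1), phi_y = c(-2, 0, 2), phi_z = c(-3, 0, 3)))
#' fitNormalization(d)
fitNormalization <- function(datasets) {
  if (is(datasets, "EnvironmentDataset")) datasets <- list(datasets)
  if (length(datasets) == 0L) .fail("need at least one dataset")
  mats <- lapply(datasets, function(d) as.matrix(measurements(d)[, emtChannels()]))
  all <- do.call(rbind, mats)
  if (nrow(all) == 0L) .fail("need at least one sample")
  lo <- apply(all, 2L, min)
  hi <- apply(all, 2L, max)
  flat <- which(hi <= lo)
  if (length(flat) > 0L)
    .fail("degenerate channel (max == min): ",
          paste(emtChannels()[flat], collapse = ", "))
  new("NormalizationBounds", lower = lo, upper = hi)
}

.asChannelMatrix <- function(samples) {
  if (is(samples, "EnvironmentDataset")) samples <- measurements(samples)
  if (is.data.frame(samples)) samples <- as.matrix(samples[, emtChannels()])
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1L,
                                               dimnames = list(NULL, emtChannels()))
  if (ncol(samples) != 7L) .fail("expected 7 channels")
  colnames(samples) <- emtChannels()
  samples
}

#' Normalize samples to the unit interval
#'
#' Linear min-max map per channel. In-range values land in [0, 1]; out-of-range
#' values are extrapolated linearly (no clamping), preserving positional
#' information from unseen environments.
#'
#' @param samples An \linkS4class{EnvironmentDataset}, samples data.frame, or
#'   numeric matrix/vector of the 7 channels.
#' @param bounds A \linkS4class{NormalizationBounds}.
#' @return Numeric matrix (n x 7) in normalized units.
#' @export
normalizeSamples <- function(samples, bounds) {
  stopifnot(is(bounds, "NormalizationBounds"))
  m <- .asChannelMatrix(samples)
  if (any(!is.finite(m))) .fail("non-finite sample value")
  sweep(sweep(m, 2L, bounds@lower, "-"), 2L, bounds@upper - bounds@lower, "/")
}

#' Invert the normalization map
#'
#' @param normalized Numeric matrix (n x 7) or vector in normalized units.
#' @param bounds A \linkS4class{NormalizationBounds}.
#' @return Numeric matrix (n x 7) on the original scales.
#' @export
denormalizeSamples <- function(normalized, bounds) {
  stopifnot(is(bounds, "NormalizationBounds"))
  if (is.null(dim(normalized)))
    normalized <- matrix(normalized, nrow = 1L)
  if (ncol(normalized) != 7L) .fail("expected 7 channels")
  out <- sweep(sweep(normalized, 2L, bounds@upper - bounds@lower, "*"),
               2L, bounds@lower, "+")
  colnames(out) <- emtChannels()
  out
}

## Denormalize a subset of channels (by name) of a matrix in normalized units.
denormalizeChannels <- function(mat, bounds, channels) {
  idx <- match(channels, emtChannels())
  sweep(sweep(mat, 2L, (bounds@upper - bounds@lower)[idx], "*"),
        2L, bounds@lower[idx], "+")
}

#' Read / write an environment dataset as CSV
#'
#' The CSV dialect is comma-separated, dot decimal, UTF-8, with a mandatory
#' header \code{node_id,x,y,z,q,phi_x,phi_y,phi_z}. Environment metadata (name,
#' domain, C-arm distance, gantry angle) travels in a JSON sidecar
#' \code{<path>.meta.json}; if absent, it must be supplied via arguments.
#' Writing then reading is lossless for finite values to well below 1e-9.
#'
#' @param path CSV file path.
#' @param name,domain,carmDistance,gantryAngle Metadata overrides used when no
#'   sidecar is present (arguments win over sidecar values when given).
#' @return \code{readDataset} returns an \linkS4class{EnvironmentDataset};
#'   \code{writeDataset} invisibly returns \code{path}.
#' @export
readDataset <- function(path, name = NULL, domain = NULL,
                        carmDistance = NULL, gantryAngle = NULL) {
  if (!file.exists(path)) .fail("no such file: ", path)
  df <- utils::read.csv(path, colClasses = "numeric")
  need <- c("node_id", emtChannels())
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    .fail("file ", path, " is missing column(s): ", paste(missing, collapse = ", "))
  for (col in need) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad) > 0L)
      .fail("file ", path, ": non-finite value in column '", col, "' at row ", bad[1L])
  }
  meta <- list()
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pick <- function(arg, key, default) {
    if (!is.null(arg)) arg
    else if (!is.null(meta[[key]]) && !all(is.na(meta[[key]]))) meta[[key]]
    else default
  }
  environmentDataset(
    name = pick(name, "name", sub("\\.csv$", "", basename(path))),
    domain = pick(domain, "domain", "L"),
    samples = df,
    carmDistance = pick(carmDistance, "carm_distance_cm", NA_real_),
    gantryAngle = pick(gantryAngle, "gantry_angle_deg", NA_real_))
}

#' @param dataset An \linkS4class{EnvironmentDataset} to write.
#' @param sidecar Write the JSON metadata sidecar alongside the CSV?
#' @rdname readDataset
#' @export
writeDataset <- function(dataset, path, sidecar = TRUE) {
  stopifnot(is(dataset, "EnvironmentDataset"))
  df <- measurements(dataset)
  txt <- vapply(df, function(col) format(col, digits = 17, scientific = FALSE, trim = TRUE),
                character(nrow(df)))
  txt <- matrix(txt, nrow = nrow(df), dimnames = list(NULL, names(df)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  if (nrow(df) > 0L)
    writeLines(apply(txt, 1L, paste, collapse = ","), con)
  if (sidecar) {
    meta <- list(name = dataset@name, domain = dataset@domain,
                 carm_distance_cm = dataset@carmDistance,
                 gantry_angle_deg = dataset@gantryAngle)
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  }
  invisible(path)
}
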