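#' Channel names of an EMT measuring point
#'
#' A tracked point is the 7-vector (x, y, z, q, phi_x, phi_y, phi_z):
#' position in tracker-frame millimetres, the device quality estimate q
#' (dimensionless, larger means more metallic distortion by default), and the
#' three orientation angles in degrees.
#'
#' @return Character vector of the seven channel names, in canonical order.
#' @export
#' @examples
#' emtChannels()
emtChannels <- function() {
  c("x", "y", "z", "q", "phi_x", "phi_y", "phi_z")
}

.ANGLE_CHANNELS <- c("phi_x", "phi_y", "phi_z")

#' Wrap angles to [-180, 180)
#'
#' @param theta Numeric vector of angles in degrees.
#' @return Angles wrapped into the half-open interval [-180, 180).
#' @export
#' @examples
#' wrapAngles(c(-180, 180, 359, 725))
wrapAngles <- function(theta) {
  stopifnot(is.numeric(theta))
  ((theta + 180) %% 360) - 180
}

## Circular mean of angles in degrees.
circularMean <- function(theta) {
  rad <- theta * pi / 180
  wrapAngles(atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi)
}

## Circular standard deviation (degrees): sqrt(-2 log R) on the unit circle.
circularSd <- function(theta) {
  rad <- theta * pi / 180
  r <- sqrt(mean(sin(rad))^2 + mean(cos(rad))^2)
  r <- min(max(r, .Machine$double.eps), 1)
  sqrt(-2 * log(r)) * 180 / pi
}

## Unwrap a wrapped angle series: remove +-360 jumps so drift is measurable.
unwrapAngles <- function(theta) {
  if (length(theta) < 2L) return(theta)
  d <- diff(theta)
  d <- d - 360 * round(d / 360)
  theta[1L] + c(0, cumsum(d))
}

#' Derive a child seed from a master seed
#'
#' All stochastic stages (per-environment fields, acquisition noise, ensemble
#' members) draw their seeds from one master seed through this map, so a whole
#' experiment is reproducible from a single integer.
#'
#' @param master Integer master seed.
#' @param index Non-negative integer stream index.
#' @return An integer seed in [1, 2^31 - 2].
#' @export
deriveSeed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.numeric(index), all(index >= 0))
  ((abs(master) + 7919 * (index + 1)) %% (.Machine$integer.max - 1)) + 1
}

## Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
## .Random.seed is restored afterwards, so library code never perturbs user RNG.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Internal: stop() with a consistent header.
.fail <- function(...) stop(..., call. = FALSE)

## Validate that a samples data.frame has the canonical columns and finite values.
checkSampleFrame <- function(df, requireNode = TRUE) {
  need <- c(if (requireNode) "node_id", emtChannels())
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    .fail("missing column(s): ", paste(missing, collapse = ", "))
  for (col in need) {
    v <- df[[col]]
    if (!is.numeric(v))
      .fail("column '", col, "' is not numeric")
    bad <- which(!is.finite(v))
    if (length(bad) > 0L)
      .fail("non-finite value in column '", col, "' at row ", bad[1L])
  }
  invisible(df)
}
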