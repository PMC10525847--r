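# Diagonal-anchored square regions of interest.
#
# Both ROIs are squares whose edge length is a multiple of d, the
# diagonal of the detected optic-disc box: alpha * d around the disc
# center O, beta * d around the macula center M. Anchoring the size to d
# keeps the physical area covered consistent across images regardless of
# camera framing. Crops that extend past the canvas are padded with a
# constant fill so the output shape is always exactly round(edge)^2.

# round half up (R's round() is banker's rounding)
.round_half_up <- function(x) floor(x + 0.5)

#' ROI extraction configuration
#'
#' @param alpha optic-disc-area edge multiplier (edge `alpha * d`).
#' @param beta macula-area edge multiplier (edge `beta * d`).
#' @param fill_value intensity used to pad out-of-canvas regions.
#' @return object of class `roi_config`.
#' @export
roi_config <- function(alpha = 3.0, beta = 6.0, fill_value = 0) {
  stopifnot(alpha > 0, beta > 0)
  structure(list(alpha = alpha, beta = beta, fill_value = fill_value),
            class = "roi_config")
}

#' Extract a square crop centered at a point
#'
#' Returns a `round(edge) x round(edge)` crop of `image` centered at the
#' continuous 0-based coordinate `center = c(x, y)`. Pixels falling
#' outside the canvas are set to `fill_value`; the output size never
#' depends on clipping. Fractional edges round half up.
#'
#' @param image numeric matrix (rows = y).
#' @param center crop center `c(x, y)`, 0-based continuous coordinates.
#' @param edge requested edge length in pixels (> 0).
#' @param fill_value padding intensity.
#' @return `side x side` numeric matrix, `side = round(edge)`.
#' @export
extract_square <- function(image, center, edge, fill_value = 0) {
  if (edge <= 0) stop("edge must be positive")
  side <- as.integer(.round_half_up(edge))
  if (side < 1L) stop("edge rounds to zero pixels")
  x0 <- as.integer(.round_half_up(center[1] - side / 2))
  y0 <- as.integer(.round_half_up(center[2] - side / 2))
  out <- matrix(fill_value, side, side)
  h <- nrow(image); w <- ncol(image)
  # source range (0-based) clipped to canvas
  sx <- max(x0, 0L):min(x0 + side - 1L, w - 1L)
  sy <- max(y0, 0L):min(y0 + side - 1L, h - 1L)
  if (length(sx) && length(sy) && sx[1] <= sx[length(sx)] &&
      sy[1] <= sy[length(sy)] && max(x0, 0L) <= min(x0 + side - 1L, w - 1L) &&
      max(y0, 0L) <= min(y0 + side - 1L, h - 1L)) {
    out[sy - y0 + 1L, sx - x0 + 1L] <- image[sy + 1L, sx + 1L]
  }
  out
}

#' Extract the three classification regions
#'
#' Builds the region set consumed by the classifier branches: the
#' optic-disc area (edge `alpha * d` at `O`), the macula area (edge
#' `beta * d` at `M`) and the untouched full image.
#'
#' @param image numeric matrix.
#' @param landmarks a `landmarks` object (see [select_landmarks()]).
#' @param config a [roi_config()].
#' @return object of class `roi_set`: list with `od_roi`, `macula_roi`,
#'   `full` and `provenance` (the landmarks and configuration used).
#' @export
make_rois <- function(image, landmarks, config = roi_config()) {
  stopifnot(inherits(landmarks, "landmarks"))
  if (!is.finite(landmarks$d) || landmarks$d <= 0) {
    stop("landmarks$d must be positive")
  }
  od <- extract_square(image, landmarks$O, config$alpha * landmarks$d,
                       config$fill_value)
  mac <- extract_square(image, landmarks$M, config$beta * landmarks$d,
                        config$fill_value)
  structure(list(od_roi = od, macula_roi = mac, full = image,
                 provenance = list(landmarks = landmarks, config = config)),
            class = "roi_set")
}
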