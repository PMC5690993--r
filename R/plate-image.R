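#' Plate images
#'
#' A `plate_image` is the in-memory form of a computed-radiography (CR) scan:
#' a matrix of non-negative integer pixel values plus the metadata needed to
#' interpret them physically.  Raw Fuji-style plates are nominally 12-bit with
#' a 0.2 mm pixel pitch (5 pixels/mm); "processed" plates are the bit-reduced,
#' latitude-scaled images a CR reader exports (e.g. 10-bit DICOM), for which
#' the latitude parameter `L` controls the half-maximum threshold.
#'
#' Collimation bands are assumed to run along rows, so the measurement
#' profile is taken along a row (across columns); use `transpose` in
#' [extract_profile()] for plates scanned the other way.
#'
#' @param pixels integer-valued matrix of pixel values, row-major plate
#'   layout; every value must lie in `[0, 2^bit_depth - 1]`.
#' @param bit_depth integer, bits per pixel (default 12; ceiling `2^12-1 = 4095`).
#' @param pixel_pitch_mm detector sampling interval in mm per pixel
#'   (default 0.2, i.e. 5 pixels/mm).
#' @param kind `"raw"` or `"processed"`.
#' @param latitude CR processor latitude `L`; only meaningful (and only
#'   allowed) when `kind = "processed"`.
#'
#' @return An object of class `plate_image`: a list with elements `pixels`,
#'   `bit_depth`, `pixel_pitch_mm`, `kind` and `latitude`.
#' @seealso [read_raw_plate()], [extract_profile()], [render_plate()]
#' @export
#' @examples
#' img <- plate_image(matrix(0:5, nrow = 2, byrow = TRUE))
#' plate_ceiling(img)
plate_image <- function(pixels, bit_depth = 12L, pixel_pitch_mm = 0.2,
                        kind = c("raw", "processed"), latitude = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L) {
    crc_error("crc_format_error",
              "'pixels' must be a matrix with at least one row and one column")
  }
  if (!is_count(bit_depth) || bit_depth < 1L || bit_depth > 16L) {
    crc_error("crc_domain_error", "'bit_depth' must be an integer in 1..16")
  }
  if (!is_number(pixel_pitch_mm) || pixel_pitch_mm <= 0) {
    crc_error("crc_domain_error", "'pixel_pitch_mm' must be a positive number")
  }
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels)) {
    crc_error("crc_format_error", "'pixels' contains missing values")
  }
  ceiling_pv <- 2L^as.integer(bit_depth) - 1L
  if (any(pixels < 0L) || any(pixels > ceiling_pv)) {
    crc_error("crc_range_error", sprintf(
      "pixel values must lie in [0, %d] for bit_depth %d (found range [%d, %d])",
      ceiling_pv, bit_depth, min(pixels), max(pixels)))
  }
  if (kind == "raw" && !is.null(latitude)) {
    crc_error("crc_domain_error", "raw plates must not carry a latitude value")
  }
  if (!is.null(latitude) && (!is_number(latitude) || latitude <= 0)) {
    crc_error("crc_domain_error", "'latitude' must be a positive number")
  }
  structure(
    list(pixels = pixels,
         bit_depth = as.integer(bit_depth),
         pixel_pitch_mm = as.numeric(pixel_pitch_mm),
         kind = kind,
         latitude = if (is.null(latitude)) NULL else as.numeric(latitude)),
    class = "plate_image"
  )
}

#' @rdname plate_image
#' @param x,image a `plate_image`.
#' @export
is_plate_image <- function(x) inherits(x, "plate_image")

#' @rdname plate_image
#' @export
plate_ceiling <- function(image) {
  stopifnot(is_plate_image(image))
  2L^image$bit_depth - 1L
}

#' @export
print.plate_image <- function(x, ...) {
  cat(sprintf("<plate_image> %d x %d px, %d-bit %s, pitch %.3g mm/px (%.1f x %.1f mm)\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$kind,
              x$pixel_pitch_mm,
              nrow(x$pixels) * x$pixel_pitch_mm,
              ncol(x$pixels) * x$pixel_pitch_mm))
  if (!is.null(x$latitude)) cat(sprintf("  latitude L = %g\n", x$latitude))
  cat(sprintf("  pixel range [%d, %d], ceiling %d\n",
              min(x$pixels), max(x$pixels), plate_ceiling(x)))
  n_sat <- sum(x$pixels == plate_ceiling(x))
  if (n_sat > 0L) cat(sprintf("  %d pixels at ceiling (saturated)\n", n_sat))
  invisible(x)
}

#' @export
dim.plate_image <- function(x) dim(x$pixels)

#' @exportS3Method base::all.equal
all.equal.plate_image <- function(target, current, ...) {
  if (!is_plate_image(current)) return("'current' is not a plate_image")
  all.equal(unclass(target), unclass(current), ...)
}
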