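#' Extract the measurement profile from a plate
#'
#' The collimation profile is the sequence of pixel values along the central
#' row of the plate, perpendicular to the radiation bands: with the cassette
#' at gantry isocenter that row crosses the narrowest part of every band.
#' An odd `n_rows > 1` takes a per-column median over the rows centred on
#' `row_index`, which suppresses shot noise at the cost of departing from the
#' strict single-row reading; the default is the single row.
#'
#' @param image a [plate_image()].
#' @param row_index 1-based row to read; default is the central row
#'   `floor(nrow/2) + 1`.
#' @param transpose read down a column instead (for plates scanned with
#'   bands along columns); `row_index` then indexes columns.
#' @param n_rows odd number of rows to median-combine (default 1).
#' @return an object of class `cr_profile`: list with `values`,
#'   `pixel_pitch_mm`, `source_row_index`, `bit_depth`, `kind`, `latitude`.
#' @export
extract_profile <- function(image, row_index = NULL, transpose = FALSE,
                            n_rows = 1L) {
  if (!is_plate_image(image)) {
    crc_error("crc_domain_error", "'image' must be a plate_image")
  }
  px <- if (transpose) t(image$pixels) else image$pixels
  if (is.null(row_index)) row_index <- nrow(px) %/% 2L + 1L
  if (!is_count(row_index) || row_index < 1L || row_index > nrow(px)) {
    crc_error("crc_bounds_error", sprintf(
      "row_index %s out of range 1..%d", format(row_index), nrow(px)))
  }
  if (!is_count(n_rows) || n_rows < 1L || n_rows %% 2L == 0L) {
    crc_error("crc_domain_error", "'n_rows' must be a positive odd integer")
  }
  if (n_rows == 1L) {
    values <- as.numeric(px[row_index, ])
  } else {
    half <- (n_rows - 1L) %/% 2L
    rows <- max(1L, row_index - half):min(nrow(px), row_index + half)
    values <- apply(px[rows, , drop = FALSE], 2L, stats::median)
  }
  if (length(values) < 3L) {
    crc_error("crc_domain_error", "profile must have at least 3 samples")
  }
  structure(
    list(values = values,
         pixel_pitch_mm = image$pixel_pitch_mm,
         source_row_index = as.integer(row_index),
         bit_depth = image$bit_depth,
         kind = image$kind,
         latitude = image$latitude),
    class = "cr_profile"
  )
}

#' @export
print.cr_profile <- function(x, ...) {
  cat(sprintf("<cr_profile> %d samples from %s row %d, pitch %g mm/px, range [%g, %g]\n",
              length(x$values), x$kind, x$source_row_index,
              x$pixel_pitch_mm, min(x$values), max(x$values)))
  invisible(x)
}

#' Segment the bands of a multi-collimation profile
#'
#' A plate typically carries several collimation bands, spaced at least twice
#' the prescribed width apart so they do not overlap.  The background level
#' is estimated as the profile median (bands occupy a minority of the row);
#' bands are maximal runs of samples exceeding `background +
#' min_prominence_pv`, and runs separated by fewer than `min_separation_px`
#' samples are merged so a noisy notch cannot split one band in two.
#'
#' The default prominence is half the raw half-maximum offset,
#' `1024 * log10(2) / 2` (about 154 pixel values): generous enough that any
#' band bright enough to be measurable is found, while exposure-level
#' background texture is not.
#'
#' @param profile a [extract_profile()] result.
#' @param min_prominence_pv minimum pixel-value excess over background for a
#'   sample to belong to a band.
#' @param min_separation_px runs closer than this many pixels are merged.
#' @return a data frame with 1-based inclusive columns `start_px`, `end_px`,
#'   one row per band, ordered left to right (empty for a flat profile).
#' @export
segment_peaks <- function(profile, min_prominence_pv = 1024 * log10(2) / 2,
                          min_separation_px = 10L) {
  stopifnot(inherits(profile, "cr_profile"))
  v <- profile$values
  background <- stats::median(v)
  above <- v > background + min_prominence_pv
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) {
    return(data.frame(start_px = integer(0), end_px = integer(0)))
  }
  starts <- starts[keep]; ends <- ends[keep]
  # merge runs with a short gap between them
  if (length(starts) > 1L) {
    merged_s <- starts[1L]; merged_e <- ends[1L]
    for (i in 2L:length(starts)) {
      if (starts[i] - merged_e[length(merged_e)] - 1L < min_separation_px) {
        merged_e[length(merged_e)] <- ends[i]
      } else {
        merged_s <- c(merged_s, starts[i])
        merged_e <- c(merged_e, ends[i])
      }
    }
    starts <- merged_s; ends <- merged_e
  }
  data.frame(start_px = as.integer(starts), end_px = as.integer(ends))
}

#' Measure the FWHM of one band
#'
#' The band's peak pixel value \eqn{y_{max}} is the single maximum within the
#' region.  The half-maximum threshold is [half_max_pixel()] for raw input,
#' or [half_max_pixel_processed()] when a latitude is supplied (processed
#' input).  The width is the length of the maximal contiguous run of samples
#' with value `>= yh` that contains the peak, counted in whole pixels and
#' converted to mm by the pixel pitch — no sub-pixel interpolation, matching
#' the 2-pixel (0.4 mm at 0.2 mm pitch) measurement uncertainty of the
#' method.  Supra-threshold islands disjoint from the peak (noise, a
#' neighbouring band's tail) are ignored.  `interpolate = TRUE` instead
#' locates each half-maximum crossing by linear interpolation between the
#' bracketing samples and reports the sub-pixel width.
#'
#' A peak at the image ceiling is saturated: the true maximum intensity is
#' unknown, so no width is reported and `saturated` is set.
#'
#' @param profile a [extract_profile()] result.
#' @param region band region: either one row of [segment_peaks()] output or
#'   an integer vector `c(start_px, end_px)` (1-based, inclusive).
#' @param model a [calibration_model()] supplying the raw slope.
#' @param latitude_L CR processor latitude for processed input; default is
#'   the latitude carried by the profile (`NULL` for raw input).
#' @param interpolate use sub-pixel linear interpolation at the half-maximum
#'   crossings (default `FALSE`: whole-pixel counting).
#' @return an object of class `peak_measurement`: list with
#'   `region_start_px`, `region_end_px`, `ymax`, `yh`, `fwhm_px`, `fwhm_mm`,
#'   `saturated` (width fields are `NA` when saturated).
#' @export
measure_fwhm <- function(profile, region, model, latitude_L = NULL,
                         interpolate = FALSE) {
  stopifnot(inherits(profile, "cr_profile"),
            inherits(model, "cr_calibration"))
  if (is.data.frame(region)) {
    region <- c(region$start_px[1L], region$end_px[1L])
  }
  start <- as.integer(region[1L]); end <- as.integer(region[2L])
  n <- length(profile$values)
  if (is.na(start) || is.na(end) || start < 1L || end > n || start > end) {
    crc_error("crc_bounds_error", sprintf(
      "region [%s, %s] outside profile 1..%d", region[1L], region[2L], n))
  }
  if (is.null(latitude_L)) latitude_L <- profile$latitude
  v <- profile$values[start:end]
  ymax <- max(v)
  img_ceiling <- 2L^profile$bit_depth - 1L
  if (ymax >= img_ceiling) {
    return(structure(
      list(region_start_px = start, region_end_px = end, ymax = ymax,
           yh = NA_real_, fwhm_px = NA_integer_, fwhm_mm = NA_real_,
           saturated = TRUE),
      class = "peak_measurement"))
  }
  yh <- if (is.null(latitude_L)) {
    ymax - model$slope * log10(2)
  } else {
    half_max_pixel_processed(ymax, latitude_L, slope = model$slope)
  }
  peak <- which.max(v)
  above <- v >= yh            # ties at the threshold are included
  # contiguous run of supra-threshold samples containing the peak
  left <- peak
  while (left > 1L && above[left - 1L]) left <- left - 1L
  right <- peak
  while (right < length(v) && above[right + 1L]) right <- right + 1L
  if (interpolate) {
    x_left <- if (left == 1L) left else {
      left - (v[left] - yh) / (v[left] - v[left - 1L])
    }
    x_right <- if (right == length(v)) right else {
      right + (v[right] - yh) / (v[right] - v[right + 1L])
    }
    fwhm_px_out <- x_right - x_left
    fwhm_mm <- fwhm_px_out * profile$pixel_pitch_mm
  } else {
    fwhm_px_out <- right - left + 1L
    fwhm_mm <- fwhm_px_out * profile$pixel_pitch_mm
  }
  structure(
    list(region_start_px = start, region_end_px = end, ymax = ymax,
         yh = yh, fwhm_px = fwhm_px_out, fwhm_mm = fwhm_mm,
         saturated = FALSE),
    class = "peak_measurement")
}

#' @export
print.peak_measurement <- function(x, ...) {
  if (x$saturated) {
    cat(sprintf("<peak_measurement> region [%d, %d]: SATURATED (ymax %g at ceiling)\n",
                x$region_start_px, x$region_end_px, x$ymax))
  } else {
    cat(sprintf("<peak_measurement> region [%d, %d]: ymax %g, yh %.2f, FWHM %s px = %.2f mm\n",
                x$region_start_px, x$region_end_px, x$ymax, x$yh,
                format(x$fwhm_px), x$fwhm_mm))
  }
  invisible(x)
}

#' Measure every collimation band on a plate
#'
#' Composes [extract_profile()], [segment_peaks()] and [measure_fwhm()]:
#' extracts the central-row profile, finds the bands, and measures each
#' band's FWHM in mm.  When nominal widths are supplied they are paired with
#' the measured bands positionally (left to right equals acquisition order),
#' and their count must match the number of bands found.
#'
#' For processed plates the latitude stored on the image (or passed
#' explicitly) selects the latitude-scaled threshold, and the default
#' segmentation prominence is scaled down by the same factor.
#'
#' @inheritParams extract_profile
#' @param model a [calibration_model()].
#' @param nominal_widths_mm optional prescribed collimation widths, mm,
#'   left to right.
#' @param latitude_L override the image's latitude (processed input).
#' @param min_prominence_pv,min_separation_px see [segment_peaks()];
#'   prominence defaults to `slope_eff * log10(2) / 2` where `slope_eff` is
#'   the raw slope divided by the latitude when one applies.
#' @param interpolate see [measure_fwhm()].
#' @return an object of class `plate_measurement`: a data frame with one row
#'   per band and columns `band`, `region_start_px`, `region_end_px`,
#'   `ymax`, `yh`, `fwhm_px`, `fwhm_mm`, `saturated` (plus `nominal_mm` when
#'   nominals were given), carrying the profile as an attribute for
#'   plotting.
#' @export
#' @examples
#' model <- calibration_model()
#' plate <- render_plate(phantom_spec(c(5, 10, 20)), model)
#' measure_plate(plate$image, model, nominal_widths_mm = c(5, 10, 20))
measure_plate <- function(image, model, nominal_widths_mm = NULL,
                          row_index = NULL, transpose = FALSE, n_rows = 1L,
                          latitude_L = NULL,
                          min_prominence_pv = NULL, min_separation_px = 10L,
                          interpolate = FALSE) {
  profile <- extract_profile(image, row_index = row_index,
                             transpose = transpose, n_rows = n_rows)
  if (is.null(latitude_L)) latitude_L <- image$latitude
  slope_eff <- if (is.null(latitude_L)) model$slope else model$slope / latitude_L
  if (is.null(min_prominence_pv)) {
    min_prominence_pv <- slope_eff * log10(2) / 2
  }
  regions <- segment_peaks(profile, min_prominence_pv = min_prominence_pv,
                           min_separation_px = min_separation_px)
  if (!is.null(nominal_widths_mm) && length(nominal_widths_mm) != nrow(regions)) {
    crc_error("crc_pairing_error", sprintf(
      "found %d bands but %d nominal widths were supplied",
      nrow(regions), length(nominal_widths_mm)))
  }
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    m <- measure_fwhm(profile, regions[i, ], model,
                      latitude_L = latitude_L, interpolate = interpolate)
    data.frame(band = i,
               region_start_px = m$region_start_px,
               region_end_px = m$region_end_px,
               ymax = m$ymax, yh = m$yh,
               fwhm_px = as.numeric(m$fwhm_px), fwhm_mm = m$fwhm_mm,
               saturated = m$saturated)
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(band = integer(0), region_start_px = integer(0),
               region_end_px = integer(0), ymax = numeric(0),
               yh = numeric(0), fwhm_px = numeric(0), fwhm_mm = numeric(0),
               saturated = logical(0))
  }
  if (!is.null(nominal_widths_mm)) out$nominal_mm <- as.numeric(nominal_widths_mm)
  structure(out,
            class = c("plate_measurement", "data.frame"),
            profile = profile, model = model)
}

#' @export
print.plate_measurement <- function(x, ...) {
  cat(sprintf("<plate_measurement> %d band(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(format_measurement_df(x), row.names = FALSE)
  invisible(x)
}

#' @export
summary.plate_measurement <- function(object, ...) {
  cat(sprintf("Plate measurement: %d band(s), %d saturated\n",
              nrow(object), sum(object$saturated)))
  if ("nominal_mm" %in% names(object) && nrow(object)) {
    dev <- object$fwhm_mm - object$nominal_mm
    cat(sprintf("Deviation from nominal (mm): min %.2f, median %.2f, max %.2f\n",
                min(dev, na.rm = TRUE), stats::median(dev, na.rm = TRUE),
                max(dev, na.rm = TRUE)))
  }
  invisible(object)
}

format_measurement_df <- function(x) {
  d <- as.data.frame(x)
  for (col in c("yh", "fwhm_mm", "nominal_mm")) {
    if (col %in% names(d)) d[[col]] <- round(d[[col]], 2L)
  }
  d
}

#' Plot a plate's profile with its width measurements
#'
#' Draws the measurement profile with a horizontal segment at each band's
#' half-maximum threshold spanning the measured width, annotated with the
#' width in mm — the standard way these QC measurements are reviewed.
#'
#' @param x a [measure_plate()] result.
#' @param ... passed to the underlying [plot()].
#' @export
plot.plate_measurement <- function(x, ...) {
  profile <- attr(x, "profile")
  pos_mm <- (seq_along(profile$values) - 0.5) * profile$pixel_pitch_mm
  graphics::plot(pos_mm, profile$values, type = "l",
                 xlab = "position (mm)", ylab = "pixel value", ...)
  for (i in seq_len(nrow(x))) {
    if (isTRUE(x$saturated[i]) || is.na(x$fwhm_mm[i])) next
    v <- profile$values[x$region_start_px[i]:x$region_end_px[i]]
    peak_px <- x$region_start_px[i] + which.max(v) - 1L
    half_w <- x$fwhm_mm[i] / 2
    graphics::segments(pos_mm[peak_px] - half_w, x$yh[i],
                       pos_mm[peak_px] + half_w, x$yh[i],
                       col = "red", lwd = 2L)
    graphics::text(pos_mm[peak_px], x$yh[i],
                   sprintf("%.1f mm", x$fwhm_mm[i]), pos = 1L, col = "red")
  }
  invisible(x)
}

#' Compare raw and processed width measurements of the same plate
#'
#' Measures the same collimation bands on a raw plate (raw half-maximum
#' threshold) and on its processed, bit-reduced counterpart
#' (latitude-scaled threshold) and tabulates the per-band difference
#' `processed - raw` in mm and in whole pixels.  Bit-depth reduction rounds
#' the penumbra samples, which can move a half-maximum crossing by one pixel
#' per side — so differences are expected in `{0, 0.2, 0.4}` mm at 0.2 mm
#' pitch.
#'
#' @param raw a raw [plate_image()].
#' @param processed the processed counterpart, same geometry; must carry a
#'   latitude (or supply `latitude_L`).
#' @param model a [calibration_model()].
#' @param latitude_L latitude of the processed image (default: taken from it).
#' @param ... further arguments passed to [measure_plate()] for both plates.
#' @return an object of class `width_comparison`: a data frame with columns
#'   `band`, `raw_fwhm_mm`, `processed_fwhm_mm`, `diff_mm`, `diff_px`.
#' @seealso [bit_reduce()], [width_diff_summary()]
#' @export
compare_raw_processed <- function(raw, processed, model, latitude_L = NULL,
                                  ...) {
  if (is.null(latitude_L)) latitude_L <- processed$latitude
  if (is.null(latitude_L)) {
    crc_error("crc_domain_error",
              "processed plate carries no latitude; supply 'latitude_L'")
  }
  m_raw <- measure_plate(raw, model, ...)
  m_proc <- measure_plate(processed, model, latitude_L = latitude_L, ...)
  if (nrow(m_raw) != nrow(m_proc)) {
    crc_error("crc_comparison_error", sprintf(
      "band count mismatch: %d bands in raw plate, %d in processed plate",
      nrow(m_raw), nrow(m_proc)))
  }
  diff_mm <- m_proc$fwhm_mm - m_raw$fwhm_mm
  out <- data.frame(band = m_raw$band,
                    raw_fwhm_mm = m_raw$fwhm_mm,
                    processed_fwhm_mm = m_proc$fwhm_mm,
                    diff_mm = diff_mm,
                    diff_px = as.integer(round(diff_mm / raw$pixel_pitch_mm)))
  structure(out, class = c("width_comparison", "data.frame"),
            pixel_pitch_mm = raw$pixel_pitch_mm)
}

#' @export
print.width_comparison <- function(x, ...) {
  cat(sprintf("<width_comparison> %d band(s)\n", nrow(x)))
  print.data.frame(as.data.frame(x), row.names = FALSE, digits = 4L)
  print(width_diff_summary(x))
  invisible(x)
}

#' Histogram of raw-vs-processed width differences
#'
#' Tallies per-band width differences into whole-pixel steps (0, 1, 2, ...
#' pixels, i.e. 0, 0.2, 0.4, ... mm at 0.2 mm pitch) and reports the count
#' and the percentage of bands in each step, percentages rounded to whole
#' percent.
#'
#' @param diffs a [compare_raw_processed()] result, or a numeric vector of
#'   per-band differences in pixels, or a pre-tallied named count vector
#'   (names = difference in pixels).
#' @param pixel_pitch_mm pitch used to label the mm column (default 0.2).
#' @return a data frame with columns `diff_px`, `diff_mm`, `count`,
#'   `percent`.
#' @export
#' @examples
#' width_diff_summary(c("0" = 2, "1" = 6, "2" = 10))  # 11%, 33%, 56% of 18
width_diff_summary <- function(diffs, pixel_pitch_mm = 0.2) {
  if (inherits(diffs, "width_comparison")) {
    pixel_pitch_mm <- attr(diffs, "pixel_pitch_mm")
    counts <- table(diffs$diff_px)
  } else if (!is.null(names(diffs))) {
    counts <- diffs
  } else {
    counts <- table(diffs)
  }
  px <- as.integer(names(counts))
  n <- sum(counts)
  data.frame(diff_px = px,
             diff_mm = px * pixel_pitch_mm,
             count = as.integer(counts),
             percent = round(100 * as.integer(counts) / n))
}
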