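#' Log-linear CR detector response model
#'
#' Raw CR pixel values follow a log-linear response in detector air kerma,
#'
#' \deqn{y = s \cdot \log_{10}(x) + C}
#'
#' where \eqn{y} is the raw pixel value, \eqn{x} the detector air kerma in
#' \eqn{\mu}Gy, \eqn{s} the slope in pixel values per decade of exposure
#' (1024 for Fuji raw data) and \eqn{C} a scalar intercept that depends on
#' tube potential and reader sensitivity.  The response is clipped at the
#' bit-depth ceiling \eqn{2^{\mathrm{bits}}-1}; a pixel at the ceiling is
#' saturated and its exposure is unrecoverable.
#'
#' `calibration_model()` builds a model from known constants;
#' [fit_log_linear()] estimates one from measured calibration points.
#'
#' @param slope pixel value per decade of air kerma (default 1024, the Fuji
#'   raw convention).
#' @param intercept pixel value at 1 \eqn{\mu}Gy (the constant \eqn{C}).
#' @param bit_depth bits per pixel; the ceiling is `2^bit_depth - 1`.
#' @param kvp optional tube potential (kVp) recorded for context; the
#'   intercept is only valid at the potential it was calibrated at.
#'
#' @return An object of class `cr_calibration` with elements `slope`,
#'   `intercept`, `ceiling`, `kvp`, and (when fitted) `r_squared`,
#'   `n_used`, `n_excluded_saturated`, `points`.
#' @seealso [fit_log_linear()], [kerma_to_pixel()], [saturation_kerma()]
#' @export
#' @examples
#' m <- calibration_model(intercept = 1052)
#' kerma_to_pixel(100, m)      # 1024 * 2 + 1052 = 3100
#' saturation_kerma(m)         # ~937 uGy reaches the 4095 ceiling
calibration_model <- function(slope = 1024, intercept = 1052,
                              bit_depth = 12L, kvp = NULL) {
  if (!is_number(slope) || slope <= 0) {
    crc_error("crc_domain_error", "'slope' must be a positive number")
  }
  if (!is_number(intercept)) {
    crc_error("crc_domain_error", "'intercept' must be a finite number")
  }
  if (!is_count(bit_depth) || bit_depth < 1L) {
    crc_error("crc_domain_error", "'bit_depth' must be a positive integer")
  }
  m <- structure(
    list(slope = as.numeric(slope), intercept = as.numeric(intercept),
         ceiling = 2L^as.integer(bit_depth) - 1L,
         kvp = if (is.null(kvp)) NULL else as.numeric(kvp)),
    class = "cr_calibration"
  )
  sk <- saturation_kerma(m)
  if (!is.finite(sk) || sk <= 0) {
    crc_error("crc_domain_error", "model implies a non-positive saturation kerma")
  }
  m
}

#' Forward and inverse response evaluation
#'
#' `kerma_to_pixel()` evaluates the response model at an air kerma, clipping
#' to `[0, ceiling]`; results that hit the ceiling carry a logical
#' `saturated` attribute.  `pixel_to_kerma()` inverts the model on the
#' unsaturated range; a pixel at or above the ceiling raises a saturation
#' error because the exposure is unrecoverable.  `saturation_kerma()` returns
#' the air kerma at which the response reaches the ceiling,
#' \eqn{10^{(\mathrm{ceiling}-C)/s}}.
#'
#' @param air_kerma_uGy air kerma in \eqn{\mu}Gy, strictly positive (vectorised).
#' @param model a [calibration_model()].
#' @param clip clip to `[0, ceiling]` and flag saturation (default `TRUE`);
#'   `clip = FALSE` returns the un-clipped model value, which is what the
#'   synthetic generator quantises.
#' @return `kerma_to_pixel()`: numeric pixel values with attribute
#'   `saturated`; `pixel_to_kerma()` and `saturation_kerma()`: air kerma in
#'   \eqn{\mu}Gy.
#' @export
kerma_to_pixel <- function(air_kerma_uGy, model, clip = TRUE) {
  stopifnot(inherits(model, "cr_calibration"))
  if (any(!is.finite(air_kerma_uGy)) || any(air_kerma_uGy <= 0)) {
    crc_error("crc_domain_error", "air kerma must be positive and finite")
  }
  y <- model$slope * log10(air_kerma_uGy) + model$intercept
  if (!clip) return(y)
  sat <- y >= model$ceiling
  y <- pmin(pmax(y, 0), model$ceiling)
  attr(y, "saturated") <- sat
  y
}

#' @rdname kerma_to_pixel
#' @param pixel_value raw pixel value(s) in `[0, ceiling)`.
#' @export
pixel_to_kerma <- function(pixel_value, model) {
  stopifnot(inherits(model, "cr_calibration"))
  if (any(!is.finite(pixel_value)) || any(pixel_value < 0)) {
    crc_error("crc_domain_error", "pixel values must be non-negative and finite")
  }
  if (any(pixel_value >= model$ceiling)) {
    crc_error("crc_saturation_error", sprintf(
      "pixel value at or above the ceiling %d is saturated; air kerma is not recoverable",
      model$ceiling))
  }
  10^((pixel_value - model$intercept) / model$slope)
}

#' @rdname kerma_to_pixel
#' @export
saturation_kerma <- function(model) {
  stopifnot(inherits(model, "cr_calibration"))
  10^((model$ceiling - model$intercept) / model$slope)
}

#' Half-maximum thresholds in pixel space
#'
#' Because the response is log-linear, the pixel value corresponding to half
#' the maximum radiation intensity is a fixed offset below the peak pixel
#' value, independent of the intercept \eqn{C}:
#' \deqn{y_h = y_{max} - s \cdot \log_{10}(2)}
#' For processed (latitude-scaled) images the amplifier slope is divided by
#' the latitude \eqn{L}, so
#' \deqn{y_{hD} = y_{maxD} - (s/L) \cdot \log_{10}(2)}
#' with \eqn{s = 1024} for the Fuji convention.  Both require an unsaturated
#' peak: at the ceiling the true maximum intensity is unknown.
#'
#' @param ymax peak pixel value (unsaturated: strictly below the ceiling).
#' @param model a [calibration_model()] supplying the slope and ceiling.
#' @return the threshold pixel value \eqn{y_h}.
#' @export
#' @examples
#' m <- calibration_model()
#' half_max_pixel(4000, m)                 # 4000 - 1024*log10(2) ~ 3691.75
#' half_max_pixel_processed(1000, 4)       # 1000 -  256*log10(2) ~  922.94
half_max_pixel <- function(ymax, model) {
  stopifnot(inherits(model, "cr_calibration"))
  if (any(ymax >= model$ceiling)) {
    crc_error("crc_saturation_error", sprintf(
      "peak pixel value %s is saturated (ceiling %d); half-maximum undefined",
      max(ymax), model$ceiling))
  }
  ymax - model$slope * log10(2)
}

#' @rdname half_max_pixel
#' @param latitude_L CR processor latitude \eqn{L > 0}.
#' @param slope raw-convention slope the latitude divides (default 1024).
#' @export
half_max_pixel_processed <- function(ymax, latitude_L, slope = 1024) {
  if (!is_number(latitude_L) || latitude_L <= 0) {
    crc_error("crc_domain_error", "'latitude_L' must be a positive number")
  }
  ymax - (slope / latitude_L) * log10(2)
}

#' Calibration points and tables
#'
#' A calibration point is one exposure of known air kerma together with the
#' mean raw pixel value measured over its ROI.  `calibration_points()`
#' assembles a validated data frame; `read_calibration_table()` reads a CSV
#' with (at least) columns `air_kerma_uGy` and `mean_pixel_value`, plus an
#' optional logical `saturated` column.
#'
#' @param air_kerma_uGy positive air kerma values, \eqn{\mu}Gy.
#' @param mean_pixel_value mean ROI pixel values.
#' @param saturated logical; marks points whose ROI hit the ceiling.
#' @return a data frame with columns `air_kerma_uGy`, `mean_pixel_value`,
#'   `saturated`.
#' @export
calibration_points <- function(air_kerma_uGy, mean_pixel_value,
                               saturated = FALSE) {
  if (any(!is.finite(air_kerma_uGy)) || any(air_kerma_uGy <= 0)) {
    crc_error("crc_domain_error", "air kerma values must be positive")
  }
  if (any(!is.finite(mean_pixel_value)) || any(mean_pixel_value < 0)) {
    crc_error("crc_domain_error", "pixel values must be non-negative")
  }
  data.frame(air_kerma_uGy = as.numeric(air_kerma_uGy),
             mean_pixel_value = as.numeric(mean_pixel_value),
             saturated = rep_len(as.logical(saturated),
                                 length(air_kerma_uGy)))
}

#' @rdname calibration_points
#' @param path CSV file with a header row.
#' @export
read_calibration_table <- function(path) {
  if (!file.exists(path)) {
    crc_error("crc_io_error", sprintf("calibration table not found: %s", path))
  }
  tab <- utils::read.csv(path)
  need <- c("air_kerma_uGy", "mean_pixel_value")
  if (!all(need %in% names(tab))) {
    crc_error("crc_format_error", sprintf(
      "calibration table must have columns %s", paste(need, collapse = ", ")))
  }
  calibration_points(tab$air_kerma_uGy, tab$mean_pixel_value,
                     if ("saturated" %in% names(tab)) tab$saturated else FALSE)
}

#' Fit the log-linear response to calibration data
#'
#' Least-squares fit of mean pixel value against \eqn{\log_{10}} air kerma.
#' Points flagged saturated, or whose pixel value has reached the ceiling,
#' are excluded before fitting — the response plateaus at the ceiling and
#' including such points biases the slope.
#'
#' @param points a data frame from [calibration_points()] or
#'   [read_calibration_table()] (columns `air_kerma_uGy`,
#'   `mean_pixel_value`, optional `saturated`).
#' @param bit_depth bit depth defining the ceiling used both for exclusion
#'   and for the returned model.
#' @inheritParams calibration_model
#' @return a fitted `cr_calibration` (see [calibration_model()]) whose
#'   `slope` and `intercept` are the regression estimates, with fit
#'   diagnostics `r_squared`, `n_used`, `n_excluded_saturated` and the
#'   retained `points` attached.
#' @export
#' @examples
#' pts <- calibration_points(c(1, 10), c(1052, 2076))
#' coef(fit_log_linear(pts))    # slope 1024, intercept 1052
fit_log_linear <- function(points, bit_depth = 12L, kvp = NULL) {
  points <- as.data.frame(points)
  if (is.null(points$saturated)) points$saturated <- FALSE
  ceiling_pv <- 2L^as.integer(bit_depth) - 1L
  usable <- !points$saturated & points$mean_pixel_value < ceiling_pv
  used <- points[usable, , drop = FALSE]
  if (nrow(used) < 2L || length(unique(used$air_kerma_uGy)) < 2L) {
    crc_error("crc_insufficient_data", sprintf(
      "need at least 2 unsaturated points with distinct kerma values (have %d usable of %d)",
      nrow(used), nrow(points)))
  }
  fit <- stats::lm(mean_pixel_value ~ log10(air_kerma_uGy), data = used)
  cf <- stats::coef(fit)
  model <- calibration_model(slope = unname(cf[2L]),
                             intercept = unname(cf[1L]),
                             bit_depth = bit_depth, kvp = kvp)
  # noiseless synthetic data fit perfectly; silence summary.lm's warning
  model$r_squared <- suppressWarnings(summary(fit)$r.squared)
  model$n_used <- nrow(used)
  model$n_excluded_saturated <- nrow(points) - nrow(used)
  model$points <- points
  model
}

#' Check that measured calibration data are log-linear
#'
#' The half-maximum method only needs the log-linear form to hold (the
#' intercept cancels), so a calibration session is validated by the quality
#' of the regression: the report passes when \eqn{R^2} reaches `r2_min` and
#' the fitted slope is within `max_slope_deviation` of the nominal
#' pixels-per-decade slope.  Saturated points are excluded as in
#' [fit_log_linear()].
#'
#' @inheritParams fit_log_linear
#' @param nominal_slope expected pixels-per-decade slope (default 1024).
#' @param r2_min minimum \eqn{R^2} to pass (default 0.99).
#' @param max_slope_deviation maximum |fitted - nominal| / nominal (default 0.02).
#' @return an object of class `linearity_report`: a list with `r_squared`,
#'   `slope_deviation_fraction`, `n_points_used`,
#'   `n_points_excluded_saturated`, `passes`, and the fitted `model`.
#' @export
validate_log_linearity <- function(points, nominal_slope = 1024,
                                   r2_min = 0.99, max_slope_deviation = 0.02,
                                   bit_depth = 12L) {
  points <- as.data.frame(points)
  if (nrow(points) < 3L) {
    crc_error("crc_insufficient_data",
              "linearity validation needs at least 3 calibration points")
  }
  model <- fit_log_linear(points, bit_depth = bit_depth)
  if (model$n_used < 3L) {
    crc_error("crc_insufficient_data",
              "linearity validation needs at least 3 unsaturated points")
  }
  dev <- abs(model$slope - nominal_slope) / nominal_slope
  structure(
    list(r_squared = model$r_squared,
         slope_deviation_fraction = dev,
         n_points_used = model$n_used,
         n_points_excluded_saturated = model$n_excluded_saturated,
         passes = model$r_squared >= r2_min && dev <= max_slope_deviation,
         r2_min = r2_min, max_slope_deviation = max_slope_deviation,
         nominal_slope = nominal_slope,
         model = model),
    class = "linearity_report"
  )
}

#' @export
print.linearity_report <- function(x, ...) {
  cat("<linearity_report>\n")
  cat(sprintf("  R-squared:        %.6f (min %.3g)\n", x$r_squared, x$r2_min))
  cat(sprintf("  slope deviation:  %.4f%% of nominal %g (max %.3g%%)\n",
              100 * x$slope_deviation_fraction, x$nominal_slope,
              100 * x$max_slope_deviation))
  cat(sprintf("  points: %d used, %d excluded as saturated\n",
              x$n_points_used, x$n_points_excluded_saturated))
  cat(sprintf("  verdict: %s\n", if (x$passes) "PASS" else "FAIL"))
  invisible(x)
}

# ---- cr_calibration methods --------------------------------------------

#' @export
print.cr_calibration <- function(x, ...) {
  cat("<cr_calibration> y = slope * log10(kerma) + C\n")
  cat(sprintf("  slope:     %.4f pixel values / decade\n", x$slope))
  cat(sprintf("  C:         %.4f pixel value at 1 uGy\n", x$intercept))
  cat(sprintf("  ceiling:   %d (saturation at %.1f uGy)\n",
              x$ceiling, saturation_kerma(x)))
  if (!is.null(x$kvp)) cat(sprintf("  kVp:       %g\n", x$kvp))
  if (!is.null(x$r_squared)) {
    cat(sprintf("  fitted on %d points (%d saturated excluded), R^2 = %.6f\n",
                x$n_used, x$n_excluded_saturated, x$r_squared))
  }
  invisible(x)
}

#' @export
coef.cr_calibration <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' Predict pixel values from air kerma
#'
#' @param object a `cr_calibration`.
#' @param air_kerma_uGy air kerma values (\eqn{\mu}Gy) to evaluate at; when
#'   omitted and the model was fitted, the calibration points are used.
#' @param ... unused.
#' @return predicted (clipped) pixel values, as [kerma_to_pixel()].
#' @export
predict.cr_calibration <- function(object, air_kerma_uGy = NULL, ...) {
  if (is.null(air_kerma_uGy)) {
    if (is.null(object$points)) {
      crc_error("crc_domain_error",
                "supply 'air_kerma_uGy' for a model built from constants")
    }
    air_kerma_uGy <- object$points$air_kerma_uGy
  }
  kerma_to_pixel(air_kerma_uGy, object)
}

#' @export
residuals.cr_calibration <- function(object, ...) {
  if (is.null(object$points)) {
    crc_error("crc_domain_error", "model has no attached calibration points")
  }
  pts <- object$points
  usable <- !pts$saturated & pts$mean_pixel_value < object$ceiling
  pts$mean_pixel_value[usable] -
    (object$slope * log10(pts$air_kerma_uGy[usable]) + object$intercept)
}

#' Plot a calibration curve
#'
#' Measured points against air kerma on a log axis with the fitted (or
#' nominal) response line and the saturation ceiling.
#'
#' @param x a `cr_calibration`.
#' @param ... passed to [plot()].
#' @export
plot.cr_calibration <- function(x, ...) {
  if (!is.null(x$points)) {
    pts <- x$points
    graphics::plot(pts$air_kerma_uGy, pts$mean_pixel_value, log = "x",
                   xlab = "air kerma (uGy)", ylab = "mean raw pixel value",
                   pch = ifelse(pts$saturated, 4L, 19L), ...)
  } else {
    k <- 10^seq(0, log10(saturation_kerma(x)) + 0.2, length.out = 200L)
    graphics::plot(k, kerma_to_pixel(k, x), log = "x", type = "n",
                   xlab = "air kerma (uGy)", ylab = "raw pixel value", ...)
  }
  k <- 10^seq(log10(max(1e-2, 10^(-x$intercept / x$slope))),
              log10(saturation_kerma(x)) + 0.3, length.out = 400L)
  graphics::lines(k, kerma_to_pixel(k, x), col = "red")
  graphics::abline(h = x$ceiling, lty = 2L)
  invisible(x)
}
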