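#' Specify one synthetic collimation band
#'
#' The synthetic beam model is a trapezoid in the dose (air kerma) domain: a
#' flat plateau at `plateau_kerma_uGy` flanked by linear penumbra ramps of
#' width `penumbra_mm` falling to zero, all riding on the plate's background
#' kerma.  With plateau width `nominal_fwhm_mm - penumbra_mm`, the half
#' maximum of the band sits exactly at each ramp midpoint, so the
#' dose-domain FWHM equals `nominal_fwhm_mm` analytically — that is the
#' ground truth the profilometry is tested against.
#'
#' @param nominal_fwhm_mm true dose-domain FWHM of the band, mm; must exceed
#'   the penumbra so a plateau exists.
#' @param penumbra_mm linear ramp width on each side, mm (default 0.8,
#'   a typical CT penumbra at isocenter).
#' @param plateau_kerma_uGy plateau air kerma above background, \eqn{\mu}Gy
#'   (default 600, mid exposure range and below the ~937 \eqn{\mu}Gy
#'   saturation of the nominal response).
#' @param center_offset_mm sub-pixel shift of the band center relative to
#'   its nominal layout position, mm; lets quantisation-error sweeps realise
#'   the full ±2-pixel range.
#' @return an object of class `band_spec`.
#' @export
band_spec <- function(nominal_fwhm_mm, penumbra_mm = 0.8,
                      plateau_kerma_uGy = 600, center_offset_mm = 0) {
  if (!is_number(nominal_fwhm_mm) || nominal_fwhm_mm <= 0) {
    crc_error("crc_domain_error", "'nominal_fwhm_mm' must be positive")
  }
  if (!is_number(penumbra_mm) || penumbra_mm < 0) {
    crc_error("crc_domain_error", "'penumbra_mm' must be non-negative")
  }
  if (nominal_fwhm_mm <= penumbra_mm) {
    crc_error("crc_spec_error", sprintf(
      "nominal FWHM %g mm must exceed penumbra %g mm so a plateau exists",
      nominal_fwhm_mm, penumbra_mm))
  }
  if (!is_number(plateau_kerma_uGy) || plateau_kerma_uGy <= 0) {
    crc_error("crc_domain_error", "'plateau_kerma_uGy' must be positive")
  }
  structure(
    list(nominal_fwhm_mm = as.numeric(nominal_fwhm_mm),
         penumbra_mm = as.numeric(penumbra_mm),
         plateau_kerma_uGy = as.numeric(plateau_kerma_uGy),
         center_offset_mm = as.numeric(center_offset_mm)),
    class = "band_spec")
}

#' Specify a synthetic multi-band phantom plate
#'
#' Emulates the acquisition in which axial scans at several collimations are
#' taken on one CR plate, advancing the cassette between scans with spacings
#' of at least twice the prescribed collimation width so the bands do not
#' overlap.  Band centers are laid out left to right with separation
#' `min_spacing_factor` times the wider of each adjacent pair of nominal
#' widths (plus a guard so wide penumbras of narrow bands cannot touch);
#' each band's `center_offset_mm` is then added.  The plate width is sized
#' to fit unless `plate_cols` is given.
#'
#' @param bands list of [band_spec()] objects, or a numeric vector of
#'   nominal widths (mm) which is expanded with default band parameters.
#' @param background_kerma_uGy plate background air kerma, \eqn{\mu}Gy
#'   (default 10: scatter floor well below any plateau).
#' @param plate_rows number of rows (default 32; every row carries the same
#'   dose, the profile row is arbitrary).
#' @param plate_cols number of columns; default sized from the band layout.
#' @param pixel_pitch_mm detector pitch (default 0.2 mm).
#' @param bit_depth bits per pixel (default 12).
#' @param noise_sigma_pv additive Gaussian noise, in pixel values, applied
#'   after the log response (default 0: noiseless).
#' @param seed RNG seed used when rendering noise.
#' @param min_spacing_factor minimum center separation as a multiple of the
#'   wider adjacent nominal width (default 2).
#' @param centers_mm optional explicit band center positions, mm, overriding
#'   the automatic layout (offsets are still added).
#' @return an object of class `phantom_spec` with the validated layout
#'   (element `centers_mm` holds the final band centers).
#' @export
#' @examples
#' spec <- phantom_spec(c(1.25, 2.5, 5, 10, 20, 40))
#' spec$centers_mm
phantom_spec <- function(bands, background_kerma_uGy = 10,
                         plate_rows = 32L, plate_cols = NULL,
                         pixel_pitch_mm = 0.2, bit_depth = 12L,
                         noise_sigma_pv = 0, seed = 1L,
                         min_spacing_factor = 2, centers_mm = NULL) {
  if (is.numeric(bands)) bands <- lapply(bands, band_spec)
  if (!length(bands) || !all(vapply(bands, inherits, TRUE, "band_spec"))) {
    crc_error("crc_domain_error",
              "'bands' must be band widths or a list of band_spec objects")
  }
  if (!is_number(background_kerma_uGy) || background_kerma_uGy <= 0) {
    crc_error("crc_domain_error", "'background_kerma_uGy' must be positive")
  }
  plateaus <- vapply(bands, `[[`, 0, "plateau_kerma_uGy")
  if (any(background_kerma_uGy >= plateaus)) {
    crc_error("crc_spec_error",
              "background kerma must be below every band's plateau kerma")
  }
  w <- vapply(bands, `[[`, 0, "nominal_fwhm_mm")
  p <- vapply(bands, `[[`, 0, "penumbra_mm")
  off <- vapply(bands, `[[`, 0, "center_offset_mm")
  n <- length(bands)
  if (is.null(centers_mm)) {
    # pad the nominal separation so sub-pixel offsets cannot shrink a gap
    # below the spacing rule
    pad <- 2 * max(abs(off), 0) + 1e-6
    centers_mm <- numeric(n)
    # lead margin scales with the band width so background always
    # dominates the profile (the band segmenter estimates it as the median)
    centers_mm[1L] <- max(5, 1.5 * w[1L]) + w[1L] / 2 + p[1L]
    if (n > 1L) for (i in 2L:n) {
      sep <- max(min_spacing_factor * max(w[i - 1L], w[i]),
                 w[i - 1L] / 2 + p[i - 1L] + w[i] / 2 + p[i] + 1) + pad
      centers_mm[i] <- centers_mm[i - 1L] + sep
    }
  } else if (length(centers_mm) != n) {
    crc_error("crc_spec_error", "'centers_mm' must match the number of bands")
  }
  centers_mm <- centers_mm + off
  if (n > 1L) {
    sep <- diff(centers_mm)
    need <- min_spacing_factor * pmax(w[-n], w[-1L])
    if (any(sep < need - 1e-9)) {
      crc_error("crc_spec_error", sprintf(
        "band centers too close: separation %.2f mm < required %.2f mm (>= %g x the wider nominal width)",
        min(sep - need) + need[which.min(sep - need)],
        need[which.min(sep - need)], min_spacing_factor))
    }
  }
  extent_mm <- centers_mm[n] + w[n] / 2 + p[n] + max(5, 1.5 * w[n])
  if (is.null(plate_cols)) {
    plate_cols <- as.integer(ceiling(extent_mm / pixel_pitch_mm))
  } else if (plate_cols * pixel_pitch_mm < extent_mm) {
    crc_error("crc_spec_error", sprintf(
      "plate_cols %d (%.1f mm) cannot hold the band layout (%.1f mm needed)",
      plate_cols, plate_cols * pixel_pitch_mm, extent_mm))
  }
  structure(
    list(bands = bands, background_kerma_uGy = background_kerma_uGy,
         plate_rows = as.integer(plate_rows),
         plate_cols = as.integer(plate_cols),
         pixel_pitch_mm = pixel_pitch_mm, bit_depth = as.integer(bit_depth),
         noise_sigma_pv = noise_sigma_pv, seed = as.integer(seed),
         min_spacing_factor = min_spacing_factor,
         centers_mm = centers_mm),
    class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  w <- vapply(x$bands, `[[`, 0, "nominal_fwhm_mm")
  cat(sprintf("<phantom_spec> %d band(s) [%s] mm on %d x %d px plate, background %g uGy\n",
              length(x$bands), paste(w, collapse = ", "),
              x$plate_rows, x$plate_cols, x$background_kerma_uGy))
  invisible(x)
}

#' Dose profile of one trapezoidal band
#'
#' Evaluates the trapezoid beam model of a [band_spec()] on a grid of
#' positions: `plateau_kerma` over the flat top of width
#' `nominal_fwhm_mm - penumbra_mm`, falling linearly to zero over
#' `penumbra_mm` on each side, added on top of `background_kerma_uGy`.  The
#' dose-domain FWHM of the band (above background) is exactly
#' `nominal_fwhm_mm`.
#'
#' @param spec a [band_spec()].
#' @param positions_mm positions to evaluate at, mm.
#' @param background_kerma_uGy constant background added everywhere
#'   (default 0).
#' @param center_mm band center position, mm (default: the spec's own
#'   `center_offset_mm`, i.e. a band centred at the origin plus its offset).
#' @return air kerma values, \eqn{\mu}Gy, same length as `positions_mm`.
#' @export
band_dose_profile <- function(spec, positions_mm, background_kerma_uGy = 0,
                              center_mm = spec$center_offset_mm) {
  stopifnot(inherits(spec, "band_spec"))
  d <- abs(positions_mm - center_mm)
  half_plateau <- (spec$nominal_fwhm_mm - spec$penumbra_mm) / 2
  f <- if (spec$penumbra_mm == 0) {
    as.numeric(d <= spec$nominal_fwhm_mm / 2)
  } else {
    pmin(1, pmax(0, (half_plateau + spec$penumbra_mm - d) / spec$penumbra_mm))
  }
  background_kerma_uGy + spec$plateau_kerma_uGy * f
}

#' Render a synthetic raw plate with known ground truth
#'
#' Maps the phantom's per-pixel dose through the calibration model
#' (un-clipped log response), adds seeded Gaussian pixel noise if requested,
#' rounds to integers and clips to the bit-depth ceiling.  All rows carry
#' the same dose, so any row is a valid measurement row (up to noise).  The
#' returned manifest records each band's analytic FWHM, final center, and
#' whether its plateau saturates the response — a saturated band must be
#' reported as such by the profilometry, never as a silent wrong width.
#'
#' @param spec a [phantom_spec()].
#' @param model a [calibration_model()].
#' @return a list of class `synthetic_plate`: `image` (a raw
#'   [plate_image()]) and `manifest` (data frame with `band`,
#'   `nominal_fwhm_mm`, `center_mm`, `penumbra_mm`, `plateau_kerma_uGy`,
#'   `saturated`).
#' @export
#' @examples
#' plate <- render_plate(phantom_spec(c(5, 10)), calibration_model())
#' plate$manifest
render_plate <- function(spec, model) {
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(model, "cr_calibration"))
  positions <- (seq_len(spec$plate_cols) - 0.5) * spec$pixel_pitch_mm
  dose <- rep(spec$background_kerma_uGy, spec$plate_cols)
  for (i in seq_along(spec$bands)) {
    b <- spec$bands[[i]]
    dose <- dose + band_dose_profile(b, positions, center_mm = spec$centers_mm[i])
  }
  y <- kerma_to_pixel(dose, model, clip = FALSE)
  ceiling_pv <- 2L^spec$bit_depth - 1L
  pixels <- matrix(rep(y, each = spec$plate_rows),
                   nrow = spec$plate_rows, ncol = spec$plate_cols)
  if (spec$noise_sigma_pv > 0) {
    pixels <- with_seed(spec$seed, {
      pixels + stats::rnorm(length(pixels), sd = spec$noise_sigma_pv)
    })
  }
  pixels <- matrix(as.integer(pmin(pmax(round(pixels), 0), ceiling_pv)),
                   nrow = spec$plate_rows)
  sat_k <- saturation_kerma(model)
  manifest <- data.frame(
    band = seq_along(spec$bands),
    nominal_fwhm_mm = vapply(spec$bands, `[[`, 0, "nominal_fwhm_mm"),
    center_mm = spec$centers_mm,
    penumbra_mm = vapply(spec$bands, `[[`, 0, "penumbra_mm"),
    plateau_kerma_uGy = vapply(spec$bands, `[[`, 0, "plateau_kerma_uGy"),
    saturated = spec$background_kerma_uGy +
      vapply(spec$bands, `[[`, 0, "plateau_kerma_uGy") >= sat_k)
  structure(
    list(image = plate_image(pixels, bit_depth = spec$bit_depth,
                             pixel_pitch_mm = spec$pixel_pitch_mm,
                             kind = "raw"),
         manifest = manifest, spec = spec),
    class = "synthetic_plate")
}

#' @export
print.synthetic_plate <- function(x, ...) {
  cat("<synthetic_plate>\n")
  print(x$image)
  cat("manifest:\n")
  print.data.frame(x$manifest, row.names = FALSE, digits = 4L)
  invisible(x)
}

#' Default calibration exposure ladder
#'
#' Ten air-kerma levels log-spaced across the 37–1236 \eqn{\mu}Gy exposure
#' range used to characterise the response at 80 kVp; the top of the range
#' deliberately exceeds the ~937 \eqn{\mu}Gy saturation kerma of the nominal
#' response so the ladder exercises the ceiling.
#'
#' @param n number of levels (default 10).
#' @param range_uGy exposure range, \eqn{\mu}Gy (default `c(37, 1236)`).
#' @return air kerma values, \eqn{\mu}Gy.
#' @export
calibration_kerma_ladder <- function(n = 10L, range_uGy = c(37, 1236)) {
  10^seq(log10(range_uGy[1L]), log10(range_uGy[2L]), length.out = n)
}

#' Render a synthetic calibration grid plate
#'
#' Emulates the calibration exposure protocol: a lead mask with a square
#' hole is moved over one plate, exposing a grid of uniform squares at
#' known air kermas, with generous spacing between exposed areas (9 cm in
#' the reference protocol).  The squares are laid out row-major; the plate
#' is sized to fit.  A centred ROI covering half the square's linear extent
#' is recorded for each exposure.
#'
#' @param kermas_uGy air kermas of the squares (default
#'   [calibration_kerma_ladder()]).
#' @param model a [calibration_model()].
#' @param square_size_mm side of each exposed square, mm (default 30: the
#'   3 cm mask hole).
#' @param spacing_mm gap between exposed areas, mm (default 90).
#' @param noise_sigma_pv Gaussian pixel noise (default 0).
#' @param seed RNG seed for the noise.
#' @param pixel_pitch_mm,bit_depth plate properties.
#' @return a list of class `calibration_grid`: `image` (a raw
#'   [plate_image()]), `rois` (data frame `row_start`, `row_end`,
#'   `col_start`, `col_end`, 1-based inclusive) and `kermas_uGy`.
#' @export
make_calibration_grid <- function(kermas_uGy = calibration_kerma_ladder(),
                                  model = calibration_model(),
                                  square_size_mm = 30, spacing_mm = 90,
                                  noise_sigma_pv = 0, seed = 1L,
                                  pixel_pitch_mm = 0.2, bit_depth = 12L) {
  if (any(kermas_uGy <= 0)) {
    crc_error("crc_domain_error", "air kermas must be positive")
  }
  if (spacing_mm < 0 || square_size_mm <= 0) {
    crc_error("crc_spec_error", "square size must be positive and spacing non-negative")
  }
  n <- length(kermas_uGy)
  n_cols_sq <- ceiling(sqrt(n))
  n_rows_sq <- ceiling(n / n_cols_sq)
  sq_px <- as.integer(round(square_size_mm / pixel_pitch_mm))
  gap_px <- as.integer(round(spacing_mm / pixel_pitch_mm))
  pitch_px <- sq_px + gap_px
  rows <- n_rows_sq * pitch_px + gap_px
  cols <- n_cols_sq * pitch_px + gap_px
  ceiling_pv <- 2L^as.integer(bit_depth) - 1L
  pixels <- matrix(0, nrow = rows, ncol = cols)
  rois <- data.frame(row_start = integer(n), row_end = integer(n),
                     col_start = integer(n), col_end = integer(n))
  for (i in seq_len(n)) {
    r_sq <- (i - 1L) %/% n_cols_sq
    c_sq <- (i - 1L) %% n_cols_sq
    r0 <- gap_px + r_sq * pitch_px + 1L
    c0 <- gap_px + c_sq * pitch_px + 1L
    pixels[r0:(r0 + sq_px - 1L), c0:(c0 + sq_px - 1L)] <-
      kerma_to_pixel(kermas_uGy[i], model, clip = FALSE)
    inset <- sq_px %/% 4L
    rois[i, ] <- c(r0 + inset, r0 + sq_px - 1L - inset,
                   c0 + inset, c0 + sq_px - 1L - inset)
  }
  if (noise_sigma_pv > 0) {
    pixels <- with_seed(seed, {
      pixels + stats::rnorm(length(pixels), sd = noise_sigma_pv)
    })
  }
  pixels <- matrix(as.integer(pmin(pmax(round(pixels), 0), ceiling_pv)),
                   nrow = rows)
  structure(
    list(image = plate_image(pixels, bit_depth = bit_depth,
                             pixel_pitch_mm = pixel_pitch_mm, kind = "raw"),
         rois = rois, kermas_uGy = as.numeric(kermas_uGy)),
    class = "calibration_grid")
}

#' Measure mean pixel values over ROIs
#'
#' Replicates the manual ROI step of the calibration protocol: the mean raw
#' pixel value over each rectangle.  An ROI is flagged saturated when at
#' least 1% of its pixels sit at the ceiling — the mean of a clipped
#' distribution is biased, so such points must be excluded from fitting.
#'
#' @param image a [plate_image()].
#' @param rois data frame with 1-based inclusive columns `row_start`,
#'   `row_end`, `col_start`, `col_end` (as produced by
#'   [make_calibration_grid()]).
#' @param kermas_uGy optional known air kermas, attached to the output so it
#'   can feed [fit_log_linear()] directly.
#' @param saturated_fraction ceiling-pixel fraction above which an ROI is
#'   flagged saturated (default 0.01).
#' @return a [calibration_points()] data frame (with `air_kerma_uGy = NA`
#'   when kermas were not supplied).
#' @export
measure_roi_means <- function(image, rois, kermas_uGy = NULL,
                              saturated_fraction = 0.01) {
  if (!is_plate_image(image)) {
    crc_error("crc_domain_error", "'image' must be a plate_image")
  }
  rois <- as.data.frame(rois)
  ceiling_pv <- plate_ceiling(image)
  nr <- nrow(image$pixels); nc <- ncol(image$pixels)
  means <- numeric(nrow(rois)); sat <- logical(nrow(rois))
  for (i in seq_len(nrow(rois))) {
    r0 <- rois$row_start[i]; r1 <- rois$row_end[i]
    c0 <- rois$col_start[i]; c1 <- rois$col_end[i]
    if (r0 < 1L || c0 < 1L || r1 > nr || c1 > nc || r0 > r1 || c0 > c1) {
      crc_error("crc_bounds_error", sprintf(
        "ROI %d [%s:%s, %s:%s] outside the %d x %d plate",
        i, r0, r1, c0, c1, nr, nc))
    }
    block <- image$pixels[r0:r1, c0:c1]
    means[i] <- mean(block)
    sat[i] <- mean(block == ceiling_pv) >= saturated_fraction
  }
  out <- data.frame(
    air_kerma_uGy = if (is.null(kermas_uGy)) NA_real_
                    else as.numeric(kermas_uGy),
    mean_pixel_value = means,
    saturated = sat)
  out
}

#' Emulate the processed pathway by bit-depth reduction
#'
#' CR readers export processed DICOM images with the dynamic range reduced
#' (typically 12 to 10 bits).  Each pixel is divided by `2^(source - target)`
#' and rounded — how the rounding is done affects the precision of the
#' half-maximum determination, so it is a parameter: `"half_up"`
#' (`floor(v / k + 0.5)`, the default) or `"floor"`.  The result is clipped
#' to the new ceiling and marked `processed`, carrying the effective
#' latitude `L = 2^(source - target)` that makes the latitude-scaled
#' half-maximum threshold consistent with the reduced 1024-per-decade slope
#' (12 to 10 bits gives `L = 4`).
#'
#' This emulates only the range reduction; real CR processing may add
#' nonlinear tone scaling, which is deliberately not modelled.
#'
#' @param image a [plate_image()] (normally raw).
#' @param target_bits target bit depth, at most the source depth.
#' @param rounding `"half_up"` or `"floor"`.
#' @return a processed [plate_image()] of `target_bits` with latitude
#'   `2^(source - target)`.
#' @export
#' @examples
#' img <- plate_image(matrix(c(0L, 6L, 4095L), 1))
#' bit_reduce(img, 10L)$pixels    # 0, 2, 1023
bit_reduce <- function(image, target_bits, rounding = c("half_up", "floor")) {
  rounding <- match.arg(rounding)
  if (!is_plate_image(image)) {
    crc_error("crc_domain_error", "'image' must be a plate_image")
  }
  if (!is_count(target_bits) || target_bits < 1L) {
    crc_error("crc_domain_error", "'target_bits' must be a positive integer")
  }
  if (target_bits > image$bit_depth) {
    crc_error("crc_domain_error", sprintf(
      "target bit depth %d exceeds source depth %d", target_bits,
      image$bit_depth))
  }
  shift <- image$bit_depth - as.integer(target_bits)
  k <- 2L^shift
  v <- switch(rounding,
              half_up = floor(image$pixels / k + 0.5),
              floor = image$pixels %/% k)
  new_ceiling <- 2L^as.integer(target_bits) - 1L
  v <- matrix(as.integer(pmin(v, new_ceiling)), nrow = nrow(image$pixels))
  plate_image(v, bit_depth = target_bits,
              pixel_pitch_mm = image$pixel_pitch_mm,
              kind = "processed", latitude = as.numeric(k))
}
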