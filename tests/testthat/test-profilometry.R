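test_that("profile extraction reads the central row by default", {
  img <- plate_image(matrix(rep(0:6, each = 5), nrow = 7, byrow = TRUE))
  prof <- extract_profile(img)
  # 7 rows: central row is the 4th (value 3)
  expect_equal(prof$source_row_index, 4L)
  expect_equal(prof$values, rep(3, 5))
  expect_equal(prof$pixel_pitch_mm, img$pixel_pitch_mm)
  expect_error(extract_profile(img, row_index = 8L), class = "crc_bounds_error")

  # transpose of a column-banded plate gives the row-banded profile
  plate <- one_band_plate(5)
  flipped <- plate_image(t(plate$image$pixels))
  expect_equal(extract_profile(flipped, transpose = TRUE)$values,
               extract_profile(plate$image)$values)

  # n-row median equals the single row on a noiseless plate
  expect_equal(extract_profile(plate$image, n_rows = 5L)$values,
               extract_profile(plate$image)$values)
  expect_error(extract_profile(plate$image, n_rows = 2L),
               class = "crc_domain_error")
})

test_that("segmentation finds each band once, in order", {
  flat <- extract_profile(plate_image(matrix(2076L, 3, 50)))
  expect_equal(nrow(segment_peaks(flat)), 0L)

  plate <- one_band_plate(5)
  prof <- extract_profile(plate$image)
  seg <- segment_peaks(prof)
  expect_equal(nrow(seg), 1L)
  peak <- which.max(prof$values)
  expect_true(seg$start_px[1] <= peak && peak <= seg$end_px[1])

  widths <- c(1.25, 2.5, 5, 10, 20, 40)
  multi <- render_plate(phantom_spec(widths), nominal_model())
  prof <- extract_profile(multi$image)
  seg <- segment_peaks(prof)
  expect_equal(nrow(seg), 6L)
  # left-to-right order matches generation order: region centers track
  # the manifest centers
  centers_mm <- (seg$start_px + seg$end_px) / 2 * prof$pixel_pitch_mm
  expect_lt(max(abs(centers_mm - multi$manifest$center_mm)), 1)
})

test_that("FWHM is the contiguous supra-threshold run around the peak", {
  m <- nominal_model()
  # 25 contiguous pixels at the plateau, others below threshold
  v <- c(rep(2000L, 10), rep(3600L, 25), rep(2000L, 10))
  prof <- extract_profile(plate_image(matrix(v, 1), pixel_pitch_mm = 0.2),
                          row_index = 1L)
  pm <- measure_fwhm(prof, c(1L, length(v)), m)
  expect_equal(pm$fwhm_px, 25L)
  expect_equal(pm$fwhm_mm, 5.0)
  expect_equal(pm$ymax, 3600)
  expect_equal(pm$yh, 3600 - 1024 * log10(2))
  expect_false(pm$saturated)
  expect_equal(pm$fwhm_mm, pm$fwhm_px * prof$pixel_pitch_mm)

  # disjoint supra-threshold island is ignored
  v2 <- c(rep(3500L, 3), rep(2000L, 10), rep(3600L, 25), rep(2000L, 10))
  prof2 <- extract_profile(plate_image(matrix(v2, 1)), row_index = 1L)
  expect_equal(measure_fwhm(prof2, c(1L, length(v2)), m)$fwhm_px, 25L)

  expect_error(measure_fwhm(prof, c(0L, 10L), m), class = "crc_bounds_error")
  expect_error(measure_fwhm(prof, c(1L, 99L), m), class = "crc_bounds_error")
})

test_that("trapezoidal bands measure within the stated 0.4 mm error", {
  # plateau 9.6 mm + 0.8 mm penumbras: analytic dose-domain FWHM 10.4 mm
  plate <- one_band_plate(10.4, penumbra_mm = 0.8)
  mp <- measure_plate(plate$image, nominal_model())
  expect_equal(nrow(mp), 1L)
  expect_lte(abs(mp$fwhm_mm - 10.4), 0.4)

  # every band of a noiseless multi-width plate is within 2 pixels of truth
  widths <- c(1.25, 2.5, 5, 10, 20, 40)
  multi <- render_plate(phantom_spec(widths), nominal_model())
  mp <- measure_plate(multi$image, nominal_model(), nominal_widths_mm = widths)
  expect_equal(mp$nominal_mm, widths)
  expect_true(all(abs(mp$fwhm_mm - multi$manifest$nominal_fwhm_mm) <= 0.4))
})

test_that("saturated bands are flagged, never silently measured", {
  # plateau kerma above ~937 uGy clips the plateau at the 4095 ceiling
  plate <- one_band_plate(10, kerma = 1000)
  expect_true(plate$manifest$saturated)
  mp <- measure_plate(plate$image, nominal_model())
  expect_true(mp$saturated)
  expect_true(is.na(mp$fwhm_mm))
})

test_that("integer-pixel FWHM equals the brute-force oracle on random profiles", {
  set.seed(101)
  m <- nominal_model()
  for (i in seq_len(1000L)) {
    n <- sample(60:140, 1L)
    base <- runif(1, 1500, 2200)
    peak <- runif(1, base + 600, 4000)
    ramp <- sample(2:8, 1L)
    top <- sample(5:40, 1L)
    start <- sample(5:(n - top - 2L * ramp - 5L), 1L)
    v <- rep(base, n)
    idx <- start:(start + 2L * ramp + top - 1L)
    shape <- c(seq(0, 1, length.out = ramp + 1L)[-1L], rep(1, top),
               seq(1, 0, length.out = ramp + 1L)[-1L])
    v[idx] <- base + (peak - base) * shape
    v <- pmin(round(v + rnorm(n, sd = runif(1, 0, 20))), 4000)
    prof <- extract_profile(plate_image(matrix(as.integer(pmax(v, 0)), 1)),
                            row_index = 1L)
    pm <- measure_fwhm(prof, c(1L, n), m)
    expect_identical(pm$fwhm_px, oracle_fwhm_px(prof$values, pm$yh))
  }
})

test_that("widening a band one-sided by k pixels adds exactly k pixels", {
  base <- 10.4
  ref <- measure_plate(one_band_plate(base, offset_mm = 0.07)$image,
                       nominal_model())
  for (k in 1:5) {
    # extend the right edge only: width +k px, center shifted +k/2 px
    wider <- one_band_plate(base + k * 0.2, offset_mm = 0.07 + k * 0.1)
    mp <- measure_plate(wider$image, nominal_model())
    expect_equal(mp$fwhm_px, ref$fwhm_px + k)
  }
})

test_that("whole-pixel translation leaves the measured width unchanged", {
  ref <- measure_plate(one_band_plate(10.4, offset_mm = 0.07)$image,
                       nominal_model())
  for (shift_px in c(1, 3, 10)) {
    moved <- one_band_plate(10.4, offset_mm = 0.07 + shift_px * 0.2)
    expect_equal(measure_plate(moved$image, nominal_model())$fwhm_px,
                 ref$fwhm_px)
  }
})

test_that("nominal pairing is positional and counts must match", {
  widths <- c(5, 10, 20)
  plate <- render_plate(phantom_spec(widths), nominal_model())
  expect_error(measure_plate(plate$image, nominal_model(),
                             nominal_widths_mm = c(5, 10)),
               class = "crc_pairing_error")
  empty <- plate_image(matrix(2076L, 4, 60))
  expect_equal(nrow(measure_plate(empty, nominal_model())), 0L)
})

test_that("optional sub-pixel interpolation tracks the analytic width", {
  plate <- one_band_plate(10.4, offset_mm = 0.13)
  mp <- measure_plate(plate$image, nominal_model(), interpolate = TRUE)
  expect_lte(abs(mp$fwhm_mm - 10.4), 0.2)
  expect_false(mp$fwhm_px == round(mp$fwhm_px))
})

test_that("raw-vs-processed comparison reproduces whole-pixel differences", {
  m <- nominal_model()
  widths <- c(1.25, 2.5, 5, 10, 20, 40)
  set.seed(11)
  bands <- lapply(widths, function(w)
    band_spec(w, penumbra_mm = runif(1, 0.4, 1.0),
              plateau_kerma_uGy = runif(1, 300, 900),
              center_offset_mm = runif(1, 0, 0.2)))
  plate <- render_plate(phantom_spec(bands), m)
  proc <- bit_reduce(plate$image, 10L)
  cmp <- compare_raw_processed(plate$image, proc, m)
  expect_equal(nrow(cmp), 6L)
  expect_true(all(abs(cmp$diff_mm) <= 0.4 + 1e-12))
  expect_equal(cmp$diff_mm, cmp$diff_px * 0.2)

  # processed copy identical to raw with L = 1 gives all-zero differences
  same <- bit_reduce(plate$image, 12L)
  expect_equal(compare_raw_processed(plate$image, same, m)$diff_mm,
               rep(0, 6))

  # band-count mismatch between the two plates is an error
  single <- render_plate(phantom_spec(5), m)
  expect_error(
    compare_raw_processed(plate$image, bit_reduce(single$image, 10L), m),
    class = "crc_comparison_error")
})

test_that("difference summaries tally counts into rounded percentages", {
  s <- width_diff_summary(c("0" = 2, "1" = 6, "2" = 10))
  expect_equal(s$percent, c(11, 33, 56))
  expect_equal(s$diff_mm, c(0, 0.2, 0.4))
  expect_equal(sum(s$count), 18L)
})
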