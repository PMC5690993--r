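test_that("forward response follows the log-linear model and clips", {
  m <- nominal_model()
  expect_equal(as.numeric(kerma_to_pixel(1, m)), 1052)
  expect_equal(as.numeric(kerma_to_pixel(100, m)), 3100)       # 1024*2 + 1052
  y <- kerma_to_pixel(1236, m)
  expect_equal(as.numeric(y), 4095)
  expect_true(attr(y, "saturated"))
  expect_false(attr(kerma_to_pixel(900, m), "saturated"))
  expect_error(kerma_to_pixel(0, m), class = "crc_domain_error")
  expect_error(kerma_to_pixel(-5, m), class = "crc_domain_error")
})

test_that("inverse response recovers kerma and refuses saturated pixels", {
  m <- nominal_model()
  expect_equal(pixel_to_kerma(1052, m), 1)
  expect_equal(pixel_to_kerma(3100, m), 100)
  expect_error(pixel_to_kerma(4095, m), class = "crc_saturation_error")
  # round trip over the whole unsaturated range
  kermas <- 10^seq(log10(1), log10(900), length.out = 50L)
  expect_equal(pixel_to_kerma(as.numeric(kerma_to_pixel(kermas, m)), m),
               kermas, tolerance = 1e-9)
})

test_that("saturation kerma matches the ceiling inversion", {
  m <- nominal_model()
  sk <- saturation_kerma(m)
  expect_equal(sk, 10^((4095 - 1052) / 1024))
  expect_gte(sk, 935)
  expect_equal(saturation_kerma(calibration_model(intercept = 4095)), 1)
  # shifting C up by slope*log10(2) halves the saturation kerma exactly
  m2 <- calibration_model(intercept = 1052 + 1024 * log10(2))
  expect_equal(saturation_kerma(m2), sk / 2, tolerance = 1e-12)
})

test_that("half-maximum thresholds follow the log-domain offsets", {
  m <- nominal_model()
  expect_equal(half_max_pixel(4000, m), 4000 - 1024 * log10(2))
  expect_equal(half_max_pixel(4000, m), 3691.7503, tolerance = 1e-4)
  expect_error(half_max_pixel(4095, m), class = "crc_saturation_error")

  expect_equal(half_max_pixel_processed(1000, 4), 1000 - 256 * log10(2))
  expect_equal(half_max_pixel_processed(1000, 4), 922.9376, tolerance = 1e-4)
  # L = 1 reduces to the raw threshold offset
  expect_equal(half_max_pixel_processed(4000, 1), half_max_pixel(4000, m))
  # large L: threshold approaches the peak itself
  expect_equal(half_max_pixel_processed(1000, 1e9), 1000, tolerance = 1e-5)
  expect_error(half_max_pixel_processed(1000, 0), class = "crc_domain_error")
})

test_that("halving the dose drops the pixel value by exactly the half-max offset", {
  m <- nominal_model()
  for (x in c(2, 10, 123.4, 500, 900)) {
    expect_equal(as.numeric(kerma_to_pixel(x, m)) -
                   as.numeric(kerma_to_pixel(x / 2, m)),
                 m$slope * log10(2), tolerance = 1e-9)
    expect_equal(half_max_pixel(as.numeric(kerma_to_pixel(x, m)), m),
                 as.numeric(kerma_to_pixel(x / 2, m)), tolerance = 1e-9)
  }
})

test_that("half-max threshold is independent of the intercept C", {
  for (C in c(0, 500, 1052, 2000)) {
    m <- calibration_model(intercept = C)
    expect_equal(half_max_pixel(3000, m), 3000 - 1024 * log10(2))
  }
})

test_that("least-squares fit recovers generating constants", {
  m <- nominal_model()
  # two-point line solved by hand
  fit2 <- fit_log_linear(calibration_points(c(1, 10), c(1052, 2076)))
  expect_equal(unname(coef(fit2)), c(1024, 1052))

  # noiseless ladder over the exposure range: exact recovery, saturated
  # top-of-ladder points auto-excluded
  kermas <- calibration_kerma_ladder()
  y <- kerma_to_pixel(kermas, m)
  pts <- calibration_points(kermas, as.numeric(y),
                            saturated = attr(y, "saturated"))
  fit <- fit_log_linear(pts)
  expect_equal(fit$slope, 1024, tolerance = 1e-9)
  expect_equal(fit$intercept, 1052, tolerance = 1e-9)
  expect_equal(fit$n_used + fit$n_excluded_saturated, nrow(pts))
  expect_gt(fit$n_excluded_saturated, 0L)

  # degenerate inputs
  expect_error(fit_log_linear(calibration_points(c(5, 5), c(100, 100))),
               class = "crc_insufficient_data")
  expect_error(
    fit_log_linear(calibration_points(c(1000, 1200), c(4095, 4095))),
    class = "crc_insufficient_data")
})

test_that("linearity validation passes log-linear data and rejects nonlinear", {
  m <- nominal_model()
  kermas <- calibration_kerma_ladder(8L, c(37, 900))
  pts <- calibration_points(kermas, kerma_to_pixel(kermas, m, clip = FALSE))
  rep_lin <- validate_log_linearity(pts)
  expect_true(rep_lin$passes)
  expect_equal(rep_lin$r_squared, 1)
  expect_equal(rep_lin$slope_deviation_fraction, 0, tolerance = 1e-12)

  # a square-root response is grossly non-log-linear
  rep_sqrt <- validate_log_linearity(
    calibration_points(kermas, 100 * sqrt(kermas)))
  expect_false(rep_sqrt$passes)

  # moderate pixel noise does not break the verdict
  set.seed(7)
  noisy <- calibration_points(
    kermas, kerma_to_pixel(kermas, m, clip = FALSE) + rnorm(8, sd = 5))
  expect_true(validate_log_linearity(noisy)$passes)

  expect_error(validate_log_linearity(pts[1:2, ]),
               class = "crc_insufficient_data")
})

test_that("fitted model behaves as a model object", {
  m <- nominal_model()
  kermas <- calibration_kerma_ladder(8L, c(37, 900))
  fit <- fit_log_linear(
    calibration_points(kermas, kerma_to_pixel(kermas, m, clip = FALSE)))
  expect_named(coef(fit), c("slope", "intercept"))
  expect_equal(as.numeric(predict(fit, 100)), 3100, tolerance = 1e-9)
  expect_equal(as.numeric(predict(fit)),
               as.numeric(kerma_to_pixel(kermas, m)), tolerance = 1e-6)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-9)
  expect_output(print(fit), "slope")
})

test_that("calibration tables round-trip through CSV", {
  pts <- calibration_points(c(37, 100, 500), c(2658.5, 3100, 3815.7),
                            saturated = c(FALSE, FALSE, FALSE))
  path <- file.path(tempdir(), "cal.csv")
  utils::write.csv(pts, path, row.names = FALSE)
  expect_equal(read_calibration_table(path), pts)
  writeLines("a,b\n1,2", path)
  expect_error(read_calibration_table(path), class = "crc_format_error")
})
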