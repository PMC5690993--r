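# Shared fixtures: the nominal Fuji-style response model and small random
# plates for round-trip testing.

nominal_model <- function() calibration_model(slope = 1024, intercept = 1052)

random_plate <- function(max_rows = 6L, max_cols = 8L) {
  rows <- sample(max_rows, 1L)
  cols <- sample(3:max_cols, 1L)
  bit_depth <- sample(c(8L, 10L, 12L, 16L), 1L)
  kind <- sample(c("raw", "processed"), 1L)
  plate_image(
    matrix(sample(0:(2L^bit_depth - 1L), rows * cols, replace = TRUE),
           rows, cols),
    bit_depth = bit_depth,
    pixel_pitch_mm = sample(c(0.1, 0.2, 0.5), 1L),
    kind = kind,
    latitude = if (kind == "processed") sample(c(1, 2, 4), 1L))
}

# Independent brute-force FWHM: enumerate every maximal contiguous
# supra-threshold run and take the one containing the profile maximum.
oracle_fwhm_px <- function(values, yh) {
  idx <- which(values >= yh)
  runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
  peak <- which.max(values)
  for (r in runs) if (peak %in% r) return(length(r))
  stop("peak not above threshold; impossible by construction")
}

# Run the CLI discarding its printed tables; return the exit status.
capture_output_status <- function(args) {
  status <- NULL
  utils::capture.output(status <- crcollim::run_cli(args))
  status
}

# Single-band plate with explicit geometry; returns the synthetic_plate.
one_band_plate <- function(width_mm, penumbra_mm = 0.8, kerma = 600,
                           offset_mm = 0, noise = 0, seed = 1L,
                           model = nominal_model()) {
  spec <- phantom_spec(
    list(band_spec(width_mm, penumbra_mm = penumbra_mm,
                   plateau_kerma_uGy = kerma, center_offset_mm = offset_mm)),
    noise_sigma_pv = noise, seed = seed)
  render_plate(spec, model)
}
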