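---
title: "Measuring CT collimation width from raw CR plates: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring CT collimation width from raw CR plates: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcollim)
```

## The measurement problem

The CT collimation (radiation-profile) width at isocenter is a routine
quality-control quantity: a beam wider than prescribed irradiates the
patient needlessly, a narrower one degrades image quality. A CR cassette
placed at isocenter and exposed to one axial scan per collimation records
every beam profile on a single plate; the width of each band, read as a
full width at half maximum (FWHM), is the collimation width. `crcollim`
implements that measurement on raw CR data, where the detector response is
known analytically, and provides everything around it: calibration,
segmentation, compliance, the processed-pathway comparison, and a synthetic
test bed.

## Detector response model

Raw CR pixel values are assumed log-linear in detector air kerma $x$
(μGy):

$$y = s \, \log_{10}(x) + C$$

with $s = 1024$ pixel values per decade for Fuji-style raw data and $C$ a
session constant (it changes with tube potential and reader sensitivity,
and is the only quantity that does). The representable range ends at the
bit-depth ceiling $2^{\text{bits}} - 1$; with 12-bit data and $C = 1052$
the response reaches 4095 near $10^{(4095-1052)/1024} \approx 937$ μGy,
and any pixel at the ceiling is treated as saturated: its exposure is
unrecoverable, and any measurement that depends on it is refused rather
than reported wrong.

Two consequences of the logarithmic form carry the whole method:

* **Half the dose is a fixed pixel offset.** For any unsaturated exposure,
  $y(x) - y(x/2) = s\,\log_{10} 2$. The half-maximum threshold is therefore
  $y_h = y_{\max} - s\,\log_{10} 2$, independent of $C$ — no calibration
  constant is needed to measure a width, only confirmation that the
  log-linear form holds.
* **Processed images scale the offset by the latitude.** Bit-reduced,
  latitude-scaled processed output divides the amplifier slope by the
  latitude $L$, giving $y_{hD} = y_{\max D} - (s/L)\,\log_{10} 2$. The
  latitude is a required user input on the processed path: CR readers do
  not expose it in any standard way, so the package never guesses it. The
  exception is the package's own emulated pathway, where a
  $b \to b'$-bit reduction fixes $L = 2^{b - b'}$ by construction.

`validate_log_linearity()` checks the form on measured calibration points:
it passes when $R^2 \ge 0.99$ and the fitted slope is within 2 % of the
nominal 1024. Both thresholds are package defaults, exposed as arguments —
they encode "the relationship is confirmed" as a reproducible rule, and a
site with a non-Fuji reader can supply its own nominal slope. Saturated
points (ROI mean at the ceiling, or flagged because ≥ 1 % of ROI pixels sit
there) are excluded from every fit: the response plateaus at the ceiling
and including such points biases the slope downward.

One deliberate approximation: the threshold is half of the *maximum total
intensity*, not half of (maximum − background). A scatter background $B$
under a plateau $K$ moves each half-maximum crossing outward by
$p \cdot B / (2K)$ on a penumbra of width $p$ — about 0.01 mm at the
default synthetic conditions ($B = 10$, $K = 600$ μGy, $p = 0.8$ mm),
far below the method's 0.4 mm resolution. The implementation follows the
literal definition and documents the approximation here.

## Width measurement

`measure_plate()` composes three steps:

1. **Profile extraction** — the central row of the plate (bands run along
   rows; a `transpose` flag handles the other orientation). An optional
   odd-`n` per-column median over adjacent rows is available for noisy
   plates but the default is the single row, matching the method's
   definition.
2. **Segmentation** — background is estimated as the profile median (valid
   because bands are spaced at least twice their width apart, so background
   dominates the row); bands are maximal runs exceeding background plus a
   prominence of half the half-max offset ($s_{\text{eff}}\log_{10}2 / 2
   \approx 154$ pixel values raw, scaled by $1/L$ on the processed path),
   with runs closer than 10 px merged. Both parameters are exposed; the
   defaults are generous enough to find any measurable band while ignoring
   exposure-level background texture.
3. **FWHM** — $y_{\max}$ is the single maximum pixel in the region (not a
   plateau average), $y_h$ the offset threshold, and the width the length
   of the contiguous run of samples $\ge y_h$ containing the peak, in whole
   pixels, times the pitch. Ties at the threshold are included; disjoint
   supra-threshold islands (noise, a neighbour's tail) are ignored.

Whole-pixel counting is the default because the method's stated uncertainty
— 2 pixels, 0.4 mm at the 0.2 mm pitch — implies whole-pixel localisation
of the two crossings; an `interpolate = TRUE` mode locates each crossing by
linear interpolation between the bracketing samples for users who want the
sub-pixel estimate, but it is off by default. Region indices are 1-based
and inclusive throughout, as R idiom dictates.

Compliance uses the ACR CT Quality Control Manual rule: tolerance
$\max(3\ \text{mm},\ 0.3\,w_{\text{nominal}})$, with the boundary read
inclusively ("within" ≙ $\le$); a `strict` flag flips the boundary, and
the tolerance function itself is pluggable for other jurisdictions.

## The synthetic test bed

The generator exists so every claim above is testable with known ground
truth. Its beam model is a trapezoid in the dose domain: a plateau at
`plateau_kerma_uGy` of width `nominal_fwhm_mm − penumbra_mm`, linear ramps
of width `penumbra_mm` each side falling to zero, riding on a uniform
background. The trapezoid is chosen *because* its FWHM is analytic — the
half-maximum sits exactly at each ramp midpoint, so the true width equals
`nominal_fwhm_mm` by construction and any measurement error is attributable
to the estimator, not the phantom.

Defaults encode the study conditions: 0.2 mm pitch, 12-bit depth, band
widths drawn from the clinical set {1.25, 2.5, 5, 10, 20, 40} mm, centers
spaced at least twice the wider adjacent width apart, background 10 μGy,
plateau 600 μGy (mid exposure range, safely below the ≈ 937 μGy
saturation), penumbra 0.8 mm, noise off. Noise, when requested, is
additive Gaussian in pixel-value space (post-log), seeded and reproducible;
no physical noise model is claimed. Sub-pixel band centers
(`center_offset_mm`) exist so placement sweeps can realise the full
±2-pixel quantisation error range. The calibration-grid generator mirrors
the exposure protocol (3 cm squares, 9 cm spacing, a 37–1236 μGy ladder
whose top rung saturates on purpose).

The emulated processed pathway is a pure bit-depth reduction:
$v \mapsto \lfloor v/2^{b-b'} + 1/2 \rfloor$ (half-up, the default) or
floor division, clipped, with the effective latitude $2^{b-b'}$ recorded on
the image. Rounding is a parameter because it is exactly what perturbs the
half-maximum determination: each penumbra crossing can move by one pixel,
so processed-minus-raw differences come in steps of 0, 1, 2 pixels (0, 0.2,
0.4 mm). Real CR processing can additionally apply nonlinear tone scaling;
that is out of scope and the emulation makes no claim to reproduce it —
which is also what passing tests do and do not show about real data: they
validate the estimator against the stated response model, not the phosphor
physics, scatter, plate tilt, or reader-specific processing of a physical
plate.

## Numerical and design choices

* The native file container is a documented pair — little-endian uint16
  payload plus JSON sidecar — because the vendor `.std` layout is
  undocumented; a reader-adapter registry (`register_plate_reader()`) lets
  a site plug in its own parser, which must be explicit about its own
  endianness/inversion assumptions. 16-bit PGM and single-channel 16-bit
  TIFF are accepted as interchange formats; 8-bit or multi-channel input is
  refused rather than silently rescaled.
* Degenerate inputs fail loudly with typed conditions: fewer than two
  usable calibration points, all-saturated ladders, out-of-range ROIs,
  band-count mismatches between plate and nominal list (or raw and
  processed plate), spacing-rule violations in a phantom layout.
* A saturated band yields a flagged result with no width — never a silent
  wrong number — and propagates to a nonzero CLI exit code.
* Auto-layout margins scale with band width (1.5× the edge band's width,
  minimum 5 mm) so the median background estimate stays valid even for a
  single 40 mm band on a small synthetic plate.
* QC reports fix field order and float formatting (one decimal, half a
  pixel, for display; full precision in JSON) so regenerated reports are
  byte-identical — a property the tests assert.
* The model object stores its *fitted* slope rather than assuming 1024, so
  non-Fuji readers with a different decade scaling work unchanged; all
  kermas are μGy and all logarithms base 10.

## Problem sizes used in the test suite

The suite runs entirely on generated data: the round-trip property uses
1000 random small plates, the estimator-vs-oracle property 1000 random
noisy trapezoid profiles, calibration recovery 200 seeded replicates of an
8-point ladder with σ = 5 pixel noise, the placement sweep 21 sub-pixel
offsets, and the raw-vs-processed ensemble 18 bands (three per clinical
width). These sizes give stable pass/fail behaviour at interactive run
times; all are parameters of ordinary R functions and can be scaled up
freely.

## Known limitations

* Segmentation's median background assumes bands occupy a minority of the
  measurement row — guaranteed by the spacing rule and the generator's
  layout, but a plate dominated by one huge exposure would need an explicit
  background estimate.
* No plate-tilt correction beyond the transpose flag; the cassette is
  assumed aligned with the pixel grid, as the acquisition protocol
  arranges.
* The latitude of real processed DICOM output must be supplied by the user;
  only the emulated pathway knows its own latitude exactly.
* Energy response, phosphor fading, scatter and MTF are not modelled; $C$
  is a per-session constant, not a physical model of the reader.
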