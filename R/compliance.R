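#' ACR beam-width tolerance
#'
#' The ACR CT Quality Control Manual requires the measured radiation beam
#' width to be accurate to within 3 mm or 30% of the total nominal collimated
#' beam width, whichever is greater.  The absolute limit dominates for
#' nominal widths up to 10 mm; above that the fractional limit takes over.
#'
#' @param nominal_mm nominal collimated beam width(s), mm, positive
#'   (vectorised).
#' @return tolerance in mm: `pmax(3, 0.30 * nominal_mm)`.
#' @export
#' @examples
#' acr_tolerance(c(5, 10, 40))   # 3, 3, 12
acr_tolerance <- function(nominal_mm) {
  if (any(!is.finite(nominal_mm)) || any(nominal_mm <= 0)) {
    crc_error("crc_domain_error", "nominal width must be positive and finite")
  }
  pmax(3, 0.30 * nominal_mm)
}

#' Assess measured collimation widths against a tolerance rule
#'
#' Pairs each measured width with its nominal, computes the deviation
#' (measured minus nominal) and the tolerance from `tolerance_fun`, and
#' passes a band when the absolute deviation is within tolerance.  "Within"
#' is read inclusively by default (a deviation exactly at the limit passes);
#' `strict = TRUE` makes the boundary exclusive.  A different jurisdiction's
#' limit can be plugged in via `tolerance_fun`.
#'
#' @param nominal_mm nominal width(s), mm, positive.
#' @param measured_mm measured width(s), mm, positive, same length (or
#'   either of length 1).
#' @param tolerance_fun function of nominal width returning the tolerance in
#'   mm (default [acr_tolerance()]).
#' @param strict if `TRUE`, a deviation exactly equal to the tolerance fails.
#' @return an object of class `collimation_assessment`: a data frame with
#'   columns `nominal_mm`, `measured_mm`, `deviation_mm`, `tolerance_mm`,
#'   `passes`.
#' @export
#' @examples
#' assess(5, 7.9)    # deviation 2.9 <= 3 mm: pass
#' assess(5, 8.1)    # deviation 3.1 >  3 mm: fail
assess <- function(nominal_mm, measured_mm, tolerance_fun = acr_tolerance,
                   strict = FALSE) {
  if (any(!is.finite(nominal_mm)) || any(nominal_mm <= 0) ||
      any(!is.finite(measured_mm)) || any(measured_mm <= 0)) {
    crc_error("crc_domain_error",
              "nominal and measured widths must be positive and finite")
  }
  n <- max(length(nominal_mm), length(measured_mm))
  nominal_mm <- rep_len(as.numeric(nominal_mm), n)
  measured_mm <- rep_len(as.numeric(measured_mm), n)
  tolerance_mm <- tolerance_fun(nominal_mm)
  deviation_mm <- measured_mm - nominal_mm
  passes <- if (strict) abs(deviation_mm) < tolerance_mm
            else abs(deviation_mm) <= tolerance_mm
  structure(
    data.frame(nominal_mm = nominal_mm, measured_mm = measured_mm,
               deviation_mm = deviation_mm, tolerance_mm = tolerance_mm,
               passes = passes),
    class = c("collimation_assessment", "data.frame"))
}

#' @export
print.collimation_assessment <- function(x, ...) {
  cat(sprintf("<collimation_assessment> %d band(s), %d exceed limit\n",
              nrow(x), sum(!x$passes)))
  d <- as.data.frame(x)
  for (col in c("nominal_mm", "measured_mm", "deviation_mm", "tolerance_mm")) {
    d[[col]] <- sprintf("%.1f", d[[col]])
  }
  d$verdict <- ifelse(x$passes, "pass", "FAIL")
  d$passes <- NULL
  print.data.frame(d, row.names = FALSE)
  invisible(x)
}

#' Write a deterministic QC report
#'
#' Renders a collimation assessment as CSV and/or JSON for QC records.  The
#' field order and float formatting are fixed, so regenerating the report on
#' identical input is byte-identical; mm values are displayed to one decimal
#' (half a pixel at 0.2 mm pitch) in the CSV while the JSON keeps full
#' precision.
#'
#' @param results a [assess()] result (or data frame with its columns).
#' @param csv_path,json_path output paths; either may be `NULL` to skip.
#' @param metadata named list recorded verbatim in the JSON report (scanner,
#'   date, operator, ...).
#' @return invisibly, a list with `results`, `n_fail`, `summary` (a one-line
#'   verdict string) and `metadata`.
#' @export
qc_report <- function(results, csv_path = NULL, json_path = NULL,
                      metadata = list()) {
  results <- as.data.frame(results)
  if (nrow(results) == 0L) {
    crc_error("crc_insufficient_data", "cannot report on zero results")
  }
  need <- c("nominal_mm", "measured_mm", "deviation_mm", "tolerance_mm", "passes")
  if (!all(need %in% names(results))) {
    crc_error("crc_format_error", sprintf(
      "results must have columns %s", paste(need, collapse = ", ")))
  }
  n_fail <- sum(!results$passes)
  summary_line <- sprintf("%d of %d band(s) exceed limit", n_fail, nrow(results))
  if (!is.null(csv_path)) {
    header <- "band,nominal_mm,measured_mm,deviation_mm,tolerance_mm,verdict"
    rows <- sprintf("%d,%.1f,%.1f,%.1f,%.1f,%s",
                    seq_len(nrow(results)),
                    results$nominal_mm, results$measured_mm,
                    results$deviation_mm, results$tolerance_mm,
                    ifelse(results$passes, "pass", "fail"))
    writeLines(c(header, rows, sprintf("# %s", summary_line)), csv_path)
  }
  if (!is.null(json_path)) {
    payload <- list(
      metadata = metadata,
      bands = cbind(band = seq_len(nrow(results)), results),
      n_fail = n_fail,
      summary = summary_line)
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(list(results = results, n_fail = n_fail,
                 summary = summary_line, metadata = metadata))
}
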