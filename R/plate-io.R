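#' Read and write plates in the native raw container
#'
#' The native on-disk form of a plate is a pair of files: `<name>.raw`, the
#' pixel payload stored row-major as little-endian unsigned 16-bit integers,
#' and `<name>.json`, a sidecar declaring `rows`, `cols`, `bit_depth`,
#' `pixel_pitch_mm`, `kind` and (for processed plates) `latitude`.  The pair
#' round-trips a [plate_image()] bit-exactly.  Vendor-specific raw formats
#' (e.g. Fuji `*.std`, whose binary layout is undocumented) are handled
#' through the adapter registry, see [register_plate_reader()].
#'
#' @param path path to the `.raw` payload (the sidecar path is derived by
#'   replacing the extension with `.json`).
#' @return `read_raw_plate()` returns a [plate_image()]; `write_raw_plate()`
#'   invisibly returns `path`.
#' @export
#' @examples
#' img <- plate_image(matrix(c(0L, 1L, 2L, 3L, 4L, 4095L), 2, byrow = TRUE))
#' f <- file.path(tempdir(), "demo.raw")
#' write_raw_plate(img, f)
#' identical(read_raw_plate(f)$pixels, img$pixels)
read_raw_plate <- function(path) {
  sidecar <- sidecar_path(path)
  if (!file.exists(path)) {
    crc_error("crc_io_error", sprintf("payload file not found: %s", path))
  }
  if (!file.exists(sidecar)) {
    crc_error("crc_format_error", sprintf("missing sidecar file: %s", sidecar))
  }
  meta <- tryCatch(jsonlite::read_json(sidecar, simplifyVector = TRUE),
                   error = function(e) {
                     crc_error("crc_format_error",
                               sprintf("unreadable sidecar %s: %s",
                                       sidecar, conditionMessage(e)))
                   })
  required <- c("rows", "cols", "bit_depth", "pixel_pitch_mm", "kind")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    crc_error("crc_format_error", sprintf(
      "sidecar %s lacks required keys: %s", sidecar,
      paste(missing, collapse = ", ")))
  }
  rows <- meta$rows; cols <- meta$cols
  if (!is_count(rows) || !is_count(cols) || rows < 1 || cols < 1) {
    crc_error("crc_format_error", "sidecar rows/cols must be positive integers")
  }
  n <- as.integer(rows) * as.integer(cols)
  payload_size <- file.info(path)$size
  if (payload_size != 2L * n) {
    crc_error("crc_format_error", sprintf(
      "payload %s has %d bytes; sidecar declares %d x %d pixels (%d bytes expected)",
      path, payload_size, rows, cols, 2L * n))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, what = "integer", n = n, size = 2L,
               signed = FALSE, endian = "little")
  ceiling_pv <- 2L^as.integer(meta$bit_depth) - 1L
  if (any(v > ceiling_pv)) {
    crc_error("crc_range_error", sprintf(
      "payload contains value %d exceeding the %d-bit ceiling %d",
      max(v), meta$bit_depth, ceiling_pv))
  }
  pixels <- matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
  plate_image(pixels,
              bit_depth = meta$bit_depth,
              pixel_pitch_mm = meta$pixel_pitch_mm,
              kind = meta$kind,
              latitude = if (identical(meta$kind, "processed")) meta$latitude)
}

#' @rdname read_raw_plate
#' @param image a [plate_image()].
#' @export
write_raw_plate <- function(image, path) {
  if (!is_plate_image(image)) {
    crc_error("crc_domain_error", "'image' must be a plate_image")
  }
  v <- as.vector(t(image$pixels))       # row-major order on disk
  # writeBin() takes signed integers; map the upper half of the uint16
  # range onto negative two's-complement values.
  v <- ifelse(v > 32767L, v - 65536L, v)
  con <- tryCatch(file(path, "wb"), error = function(e) {
    crc_error("crc_io_error", sprintf("cannot open %s for writing: %s",
                                      path, conditionMessage(e)))
  })
  writeBin(as.integer(v), con, size = 2L, endian = "little")
  close(con)
  meta <- list(rows = nrow(image$pixels), cols = ncol(image$pixels),
               bit_depth = image$bit_depth,
               pixel_pitch_mm = image$pixel_pitch_mm,
               kind = image$kind)
  if (!is.null(image$latitude)) meta$latitude <- image$latitude
  jsonlite::write_json(meta, sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) {
  ext <- tools::file_ext(path)
  if (nzchar(ext)) {
    sub(paste0("\\.", ext, "$"), ".json", path)
  } else {
    paste0(path, ".json")
  }
}

#' Read a plate from a 16-bit PGM or TIFF file
#'
#' Convenience path for plates exported to standard lossless image
#' containers.  Only single-channel 16-bit images are accepted; the physical
#' metadata (pitch, bit depth, kind, latitude) is not stored by these formats
#' and must be supplied by the caller.
#'
#' @inheritParams plate_image
#' @param path a binary (P5) PGM with maxval > 255, or a single-channel
#'   16-bit TIFF.
#' @return a [plate_image()].
#' @export
read_image_file <- function(path, pixel_pitch_mm = 0.2, bit_depth = 12L,
                            kind = c("raw", "processed"), latitude = NULL) {
  kind <- match.arg(kind)
  ext <- tolower(tools::file_ext(path))
  pixels <- switch(ext,
    pgm = read_pgm16(path),
    tif = ,
    tiff = read_tiff16(path),
    crc_error("crc_format_error", sprintf(
      "unsupported image extension '.%s' (expected .pgm, .tif or .tiff)", ext))
  )
  plate_image(pixels, bit_depth = bit_depth, pixel_pitch_mm = pixel_pitch_mm,
              kind = kind, latitude = latitude)
}

#' @rdname read_image_file
#' @param image a [plate_image()] to export (PGM maxval is written as 65535;
#'   TIFF as 16 bits per sample).
#' @export
write_image_file <- function(image, path) {
  if (!is_plate_image(image)) {
    crc_error("crc_domain_error", "'image' must be a plate_image")
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    pgm = write_pgm16(image$pixels, path),
    tif = ,
    tiff = tiff::writeTIFF(image$pixels / 65535, path, bits.per.sample = 16L),
    crc_error("crc_format_error", sprintf(
      "unsupported image extension '.%s' (expected .pgm, .tif or .tiff)", ext))
  )
  invisible(path)
}

# Binary PGM (P5).  Header: magic, width, height, maxval as whitespace-
# separated ASCII tokens ('#' comments allowed); pixels follow as big-endian
# 16-bit words when maxval > 255.
read_pgm16 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- character(0)
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) {
        crc_error("crc_format_error", sprintf("truncated PGM header in %s", path))
      }
      if (ch == "#") {                          # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (length(tok)) break else next
      }
      tok <- c(tok, ch)
    }
    paste(tok, collapse = "")
  }
  if (read_token() != "P5") {
    crc_error("crc_format_error", sprintf("%s is not a binary (P5) PGM", path))
  }
  width <- as.integer(read_token())
  height <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (anyNA(c(width, height, maxval)) || width < 1L || height < 1L) {
    crc_error("crc_format_error", sprintf("malformed PGM header in %s", path))
  }
  if (maxval <= 255L) {
    crc_error("crc_format_error", sprintf(
      "%s has maxval %d; only 16-bit PGM (maxval > 255) is supported",
      path, maxval))
  }
  n <- width * height
  v <- readBin(con, "integer", n = n, size = 2L, signed = FALSE, endian = "big")
  if (length(v) < n) {
    crc_error("crc_format_error", sprintf("truncated PGM payload in %s", path))
  }
  matrix(v, nrow = height, ncol = width, byrow = TRUE)
}

write_pgm16 <- function(pixels, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n65535\n", ncol(pixels), nrow(pixels)),
            con, eos = NULL)
  v <- as.vector(t(pixels))
  v <- ifelse(v > 32767L, v - 65536L, v)
  writeBin(as.integer(v), con, size = 2L, endian = "big")
  invisible(path)
}

read_tiff16 <- function(path) {
  img <- tryCatch(tiff::readTIFF(path, as.is = TRUE, info = TRUE),
                  error = function(e) {
                    crc_error("crc_format_error", sprintf(
                      "cannot read TIFF %s: %s", path, conditionMessage(e)))
                  })
  if (length(dim(img)) != 2L) {
    crc_error("crc_format_error", sprintf(
      "%s is multi-channel; only single-channel 16-bit TIFF is supported", path))
  }
  bps <- attr(img, "bits.per.sample")
  if (!is.null(bps) && !identical(as.integer(bps), 16L)) {
    crc_error("crc_format_error", sprintf(
      "%s has %d bits per sample; only 16-bit TIFF is supported", path, bps))
  }
  matrix(as.integer(img), nrow = nrow(img))   # drop TIFF tag attributes
}

# ---- vendor adapter registry -------------------------------------------

the_adapters <- new.env(parent = emptyenv())

#' Pluggable readers for vendor plate formats
#'
#' Vendor raw containers (such as Fuji `*.std`) have undocumented binary
#' layouts; rather than guessing, the package exposes a registry keyed by
#' file extension.  An adapter is any function `function(path, ...)`
#' returning a [plate_image()], and must be explicit about its layout
#' assumptions (endianness, header size, value inversion).  [read_plate()]
#' dispatches on the extension: the native `.raw` container and `.pgm`,
#' `.tif`/`.tiff` are built in.
#'
#' @param extension file extension without the dot, e.g. `"std"`.
#' @param reader function of `(path, ...)` returning a [plate_image()], or
#'   `NULL` to remove the adapter.
#' @return `register_plate_reader()` invisibly returns the previous adapter
#'   for that extension (or `NULL`); `read_plate()` returns a [plate_image()].
#' @export
register_plate_reader <- function(extension, reader) {
  stopifnot(is.character(extension), length(extension) == 1L,
            is.function(reader) || is.null(reader))
  ext <- tolower(extension)
  prev <- if (exists(ext, envir = the_adapters)) get(ext, envir = the_adapters)
  if (is.null(reader)) {
    if (exists(ext, envir = the_adapters)) rm(list = ext, envir = the_adapters)
  } else {
    assign(ext, reader, envir = the_adapters)
  }
  invisible(prev)
}

#' @rdname register_plate_reader
#' @param path path to a plate file of any registered format.
#' @param ... passed through to the adapter (e.g. metadata for PGM/TIFF).
#' @export
read_plate <- function(path, ...) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "raw") return(read_raw_plate(path))
  if (ext %in% c("pgm", "tif", "tiff")) return(read_image_file(path, ...))
  if (exists(ext, envir = the_adapters)) {
    img <- get(ext, envir = the_adapters)(path, ...)
    if (!is_plate_image(img)) {
      crc_error("crc_format_error", sprintf(
        "adapter for '.%s' did not return a plate_image", ext))
    }
    return(img)
  }
  crc_error("crc_format_error", sprintf(
    "no reader for '.%s' files; register one with register_plate_reader()", ext))
}
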