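# Internal helpers: classed conditions and seeded RNG scoping.

# All user-facing errors carry a condition class so callers (and the CLI)
# can distinguish usage errors from data errors without string matching.
crc_error <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "crc_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == as.integer(x)
}

is_number <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x)
}
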