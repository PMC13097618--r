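# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Classed conditions so callers can distinguish configuration misuse,
# malformed input files, and bundle-loading problems.
x12_abort <- function(message, class, call. = FALSE) {
  stop(structure(
    class = c(class, "x12_error", "error", "condition"),
    list(message = message, call = NULL)
  ))
}

abort_config <- function(message) x12_abort(message, "x12_config_error")
abort_parse  <- function(message) x12_abort(message, "x12_parse_error")
abort_load   <- function(message) x12_abort(message, "x12_load_error")
abort_input  <- function(message) x12_abort(message, "x12_input_error")

# sample() interprets a length-1 numeric vector as 1:n; this never does.
resample <- function(x, size = 1L, replace = FALSE) {
  x[sample.int(length(x), size = size, replace = replace)]
}

# Uniform integer on [lo, hi] drawn from the current RNG stream.
runif_int <- function(lo, hi) {
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

is_scalar_chr <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == trunc(x)
}

# Random digit string of fixed width (leading zeros allowed unless
# first_nonzero, which keeps identifiers at their printed width).
random_digits <- function(width, first_nonzero = FALSE) {
  first <- if (first_nonzero) sample(1:9, 1L) else sample(0:9, 1L)
  rest <- if (width > 1L) sample(0:9, width - 1L, replace = TRUE) else integer()
  paste(c(first, rest), collapse = "")
}

# CCYYMMDD rendering used throughout the 837 payload.
format_ccyymmdd <- function(date) format(as.Date(date), "%Y%m%d")

parse_ccyymmdd <- function(x) as.Date(x, format = "%Y%m%d")

# Charges print without a trailing ".00" when integral (matching how whole
# dollar amounts appear on claim lines), else with up to 2 decimals.
format_charge <- function(x) {
  x <- round(as.numeric(x), 2)
  out <- ifelse(abs(x - round(x)) < 1e-9,
    format(round(x), scientific = FALSE, trim = TRUE),
    sub("0+$", "", format(x, nsmall = 2, scientific = FALSE, trim = TRUE))
  )
  out
}
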