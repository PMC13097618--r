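# Independent oracles and fixture helpers. These deliberately avoid the
# package's own code paths: the Luhn oracle works digit-table-wise, and the
# segment-count oracle counts lines of serialized text.

# Luhn check digit via the doubled-digit lookup table, summing left-to-right
# with parity fixed from the right.
oracle_luhn_check_digit <- function(payload) {
  doubled <- c(0L, 2L, 4L, 6L, 8L, 1L, 3L, 5L, 7L, 9L)
  digits <- as.integer(strsplit(payload, "")[[1]])
  n <- length(digits)
  total <- 0L
  for (j in seq_len(n)) {
    # position counted from the right; odd positions are doubled
    if ((n - j + 1L) %% 2L == 1L) {
      total <- total + doubled[digits[j] + 1L]
    } else {
      total <- total + digits[j]
    }
  }
  (10L - total %% 10L) %% 10L
}

oracle_valid_npi <- function(npi9) {
  paste0(npi9, oracle_luhn_check_digit(paste0("80840", npi9)))
}

# For newline-per-segment serializer output: segment counts per transaction,
# counted straight off the text lines.
oracle_transaction_counts <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  tags <- sub("[*|].*$", "", lines)
  st <- which(tags == "ST")
  se <- which(tags == "SE")
  stopifnot(length(st) == length(se))
  se - st + 1L
}

x12_lines <- function(text) strsplit(text, "\n", fixed = TRUE)[[1]]

x12_unlines <- function(lines) paste0(paste(lines, collapse = "\n"), "\n")

# Replace one element of the first segment matching `tag` (tag itself is
# element 0).
mutate_element <- function(text, tag, element, value) {
  lines <- x12_lines(text)
  i <- which(startsWith(lines, paste0(tag, "*")))[1]
  stopifnot(!is.na(i))
  body <- sub("~$", "", lines[i])
  parts <- strsplit(body, "*", fixed = TRUE)[[1]]
  parts[element + 1L] <- value
  lines[i] <- paste0(paste(parts, collapse = "*"), "~")
  x12_unlines(lines)
}

drop_segment <- function(text, prefix, occurrence = 1L) {
  lines <- x12_lines(text)
  i <- which(startsWith(lines, prefix))[occurrence]
  stopifnot(!is.na(i))
  x12_unlines(lines[-i])
}

swap_adjacent <- function(text, prefix) {
  lines <- x12_lines(text)
  i <- which(startsWith(lines, prefix))[1]
  stopifnot(!is.na(i), i > 1L)
  lines[c(i - 1L, i)] <- lines[c(i, i - 1L)]
  x12_unlines(lines)
}

# A writable copy of the packaged bundle directory, for corruption tests.
copy_bundle_dir <- function() {
  src <- system.file("extdata", "refbundle", package = "x12claims")
  dst <- withr::local_tempdir(.local_envir = parent.frame())
  file.copy(list.files(src, full.names = TRUE), dst)
  dst
}

test_bundle <- function() load_reference_bundle()
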