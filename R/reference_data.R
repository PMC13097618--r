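# Reference tables the generator samples from: diagnosis and procedure code
# sets, provider organizations, payer products, and revenue codes. The
# packaged bundle is synthetic and nonidentifiable: every table is
# organization- or code-level, never person-level.

ICD10_PATTERN <- "^[A-Z][0-9][0-9A-Z]{1,5}$"
HCPCS_PATTERN <- "^[0-9A-Z]{5}$"

#' Compute the NPI check digit
#'
#' The National Provider Identifier is a 10-digit identifier whose final
#' digit is a Luhn check digit computed over the card-issuer prefix `80840`
#' followed by the first nine digits.
#'
#' @param npi9 A string of exactly nine decimal digits (the NPI without its
#'   check digit).
#' @return A single integer in 0-9, the check digit that makes the full
#'   10-digit NPI Luhn-valid.
#' @examples
#' npi_check_digit("154808342")
#' @seealso [npi_is_valid()]
#' @export
npi_check_digit <- function(npi9) {
  if (!is_scalar_chr(npi9) || !grepl("^[0-9]{9}$", npi9)) {
    abort_input("npi9 must be a string of exactly 9 decimal digits")
  }
  digits <- as.integer(strsplit(paste0("80840", npi9), "")[[1]])
  # Luhn: walking right-to-left over the payload, double every digit in an
  # odd position (the position adjacent to the check digit first).
  n <- length(digits)
  total <- 0L
  for (i in seq_len(n)) {
    d <- digits[n - i + 1L]
    if (i %% 2L == 1L) {
      d <- d * 2L
      if (d > 9L) d <- d - 9L
    }
    total <- total + d
  }
  (10L - total %% 10L) %% 10L
}

#' Check an NPI's Luhn check digit
#'
#' @param npi A string of exactly ten decimal digits.
#' @return `TRUE` if the tenth digit equals the Luhn check digit of
#'   `80840` + the first nine digits, else `FALSE`.
#' @examples
#' npi_is_valid("1548083421") # TRUE
#' npi_is_valid("1548083420") # FALSE
#' @export
npi_is_valid <- function(npi) {
  if (!is_scalar_chr(npi) || !grepl("^[0-9]{10}$", npi)) {
    abort_input("npi must be a string of exactly 10 decimal digits")
  }
  npi_check_digit(substr(npi, 1L, 9L)) == as.integer(substr(npi, 10L, 10L))
}

bundle_tables <- c("diagnoses", "procedures", "providers", "payers", "revenue_codes")

read_bundle_table <- function(dir, name) {
  path <- file.path(dir, paste0(name, ".csv"))
  if (!file.exists(path)) {
    abort_load(sprintf("reference bundle table '%s' is missing (expected %s)", name, path))
  }
  df <- utils::read.csv(path, colClasses = "character", comment.char = "#",
                        strip.white = TRUE)
  if (nrow(df) == 0L) {
    abort_load(sprintf("reference bundle table '%s' is empty", name))
  }
  df
}

#' Load a reference bundle
#'
#' Reads the five comma-delimited lookup tables (`diagnoses.csv`,
#' `procedures.csv`, `providers.csv`, `payers.csv`, `revenue_codes.csv`)
#' that the claim generator samples from, and checks their integrity. With
#' no argument the small synthetic bundle shipped with the package is used;
#' pass a directory to substitute full-size code sets with the same columns.
#'
#' The packaged bundle contains no person-level fields of any kind: codes,
#' organization names, and product catalogs only. Provider NPIs in it are
#' synthetic but carry valid Luhn check digits.
#'
#' @param path Optional directory containing the five CSV tables. `NULL`
#'   (default) loads the packaged synthetic bundle.
#' @return An object of class `reference_bundle`: a list with elements
#'   `diagnoses`, `procedures` (data frames with `code`, `description`,
#'   `system`), `providers` (`npi`, `org_name`, `taxonomy`, `street`,
#'   `city`, `state`, `zip`), `payers` (`hios_id`, `product_name`,
#'   `payer_type`) and `revenue_codes` (character vector).
#' @examples
#' bundle <- load_reference_bundle()
#' nrow(bundle$diagnoses)
#' @export
load_reference_bundle <- function(path = NULL) {
  dir <- path %||% system.file("extdata", "refbundle", package = "x12claims")
  if (!nzchar(dir) || !dir.exists(dir)) {
    abort_load(sprintf("reference bundle directory not found: '%s'", dir))
  }
  tabs <- lapply(stats::setNames(bundle_tables, bundle_tables),
                 function(nm) read_bundle_table(dir, nm))

  diagnoses <- tabs$diagnoses
  procedures <- tabs$procedures
  diagnoses$system <- "ICD10CM"
  procedures$system <- "HCPCS"

  bad_dx <- diagnoses$code[!grepl(ICD10_PATTERN, diagnoses$code)]
  if (length(bad_dx)) {
    abort_load(sprintf("diagnoses: malformed ICD-10-CM code(s): %s",
                       paste(utils::head(bad_dx, 3), collapse = ", ")))
  }
  bad_px <- procedures$code[!grepl(HCPCS_PATTERN, procedures$code)]
  if (length(bad_px)) {
    abort_load(sprintf("procedures: malformed HCPCS code(s): %s",
                       paste(utils::head(bad_px, 3), collapse = ", ")))
  }
  if (anyDuplicated(diagnoses$code)) abort_load("diagnoses: duplicate codes")
  if (anyDuplicated(procedures$code)) abort_load("procedures: duplicate codes")

  providers <- tabs$providers
  if (anyDuplicated(providers$npi)) {
    abort_load(sprintf("providers: duplicate NPI(s): %s",
                       paste(unique(providers$npi[duplicated(providers$npi)]), collapse = ", ")))
  }
  bad_npi <- providers$npi[!vapply(providers$npi, function(n)
    grepl("^[0-9]{10}$", n) && npi_is_valid(n), logical(1))]
  if (length(bad_npi)) {
    abort_load(sprintf("providers: NPI(s) failing the Luhn check: %s",
                       paste(utils::head(bad_npi, 3), collapse = ", ")))
  }
  if (any(!grepl("^[A-Z]{2}$", providers$state))) {
    abort_load("providers: state must be 2 uppercase letters")
  }

  payers <- tabs$payers
  if (any(!grepl("^[0-9]{5}$", payers$hios_id))) {
    abort_load("payers: hios_id must be 5 digits")
  }
  if (any(!nzchar(payers$product_name))) abort_load("payers: empty product_name")
  if (any(!payers$payer_type %in% c("MEDICARE", "MEDICAID", "COMMERCIAL"))) {
    abort_load("payers: payer_type must be MEDICARE, MEDICAID or COMMERCIAL")
  }

  revenue_codes <- tabs$revenue_codes$code
  if (any(!grepl("^[0-9]{4}$", revenue_codes))) {
    abort_load("revenue_codes: codes must be 4 digits")
  }

  # Privacy contract: nothing person-level may enter the bundle schema.
  person_fields <- c("member_id", "patient_name", "first_name", "last_name",
                     "subscriber_id", "dob", "birth_date", "ssn")
  seen <- unlist(lapply(tabs, names), use.names = FALSE)
  leak <- intersect(tolower(seen), person_fields)
  if (length(leak)) {
    abort_load(sprintf("reference bundle must not carry person-level fields: %s",
                       paste(leak, collapse = ", ")))
  }

  structure(
    list(diagnoses = diagnoses, procedures = procedures,
         providers = providers, payers = payers,
         revenue_codes = revenue_codes),
    class = "reference_bundle"
  )
}

#' @export
print.reference_bundle <- function(x, ...) {
  cat("<reference_bundle>\n")
  cat(sprintf("  diagnoses:     %d ICD-10-CM codes\n", nrow(x$diagnoses)))
  cat(sprintf("  procedures:    %d HCPCS codes\n", nrow(x$procedures)))
  cat(sprintf("  providers:     %d organizations\n", nrow(x$providers)))
  cat(sprintf("  payers:        %d products\n", nrow(x$payers)))
  cat(sprintf("  revenue codes: %d\n", length(x$revenue_codes)))
  invisible(x)
}

#' Draw one provider organization from a bundle
#'
#' Uniform draw from the current RNG stream; identical seeds give identical
#' draws.
#'
#' @param bundle A [load_reference_bundle()] result.
#' @return A one-row list with fields `npi`, `org_name`, `taxonomy`,
#'   `street`, `city`, `state`, `zip`.
#' @export
sample_provider <- function(bundle) {
  stopifnot(inherits(bundle, "reference_bundle"))
  if (nrow(bundle$providers) == 0L) abort_input("provider table is empty")
  as.list(bundle$providers[sample.int(nrow(bundle$providers), 1L), ])
}

#' Draw one payer product from a bundle
#'
#' @inheritParams sample_provider
#' @return A one-row list with fields `hios_id`, `product_name`, `payer_type`.
#' @export
sample_payer <- function(bundle) {
  stopifnot(inherits(bundle, "reference_bundle"))
  if (nrow(bundle$payers) == 0L) abort_input("payer table is empty")
  as.list(bundle$payers[sample.int(nrow(bundle$payers), 1L), ])
}

#' Draw one HCPCS procedure code from a bundle
#'
#' @inheritParams sample_provider
#' @return A single HCPCS code string.
#' @export
sample_procedure <- function(bundle) {
  stopifnot(inherits(bundle, "reference_bundle"))
  resample(bundle$procedures$code)
}

#' Draw an ordered diagnosis set
#'
#' Draws `k` distinct ICD-10-CM codes; the first element is the designated
#' principal diagnosis. Claim complexity is bounded at 12 diagnoses, the
#' configurable ceiling for institutional claims here.
#'
#' @inheritParams sample_provider
#' @param k Number of diagnoses, an integer in 1-12.
#' @return A character vector of `k` distinct codes, principal first.
#' @export
sample_diagnosis_set <- function(bundle, k) {
  stopifnot(inherits(bundle, "reference_bundle"))
  if (!is_count(k) || k < 1 || k > 12) {
    abort_config("diagnosis count k must be an integer between 1 and 12")
  }
  avail <- nrow(bundle$diagnoses)
  if (k > avail) {
    abort_input(sprintf("requested %d diagnoses but bundle holds only %d", k, avail))
  }
  bundle$diagnoses$code[sample.int(avail, k)]
}
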