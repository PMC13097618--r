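# Domain model for 837 institutional claims, shared by the generator, the
# serializer/parser, and the validator. Constructors check invariants at
# build time; validate_claim() re-checks a whole claim and returns the
# violations instead of raising, so callers can collect complete reports.

#' Delimiter set for X12 serialization and parsing
#'
#' X12 text is delimited, not fixed-format (except the ISA header): one
#' character each for element separation, component (sub-element)
#' separation, repetition, and segment termination. All four must be
#' pairwise distinct and must not collide with payload characters, so
#' digits and uppercase letters are rejected.
#'
#' @param element_sep,component_sep,repetition_sep,segment_term Single
#'   characters. Defaults are the widely used `*`, `:`, `^`, `~`.
#' @return An object of class `delimiter_set`.
#' @examples
#' delimiter_set()
#' delimiter_set(element_sep = "|")
#' @export
delimiter_set <- function(element_sep = "*", component_sep = ":",
                          repetition_sep = "^", segment_term = "~") {
  chars <- c(element_sep = element_sep, component_sep = component_sep,
             repetition_sep = repetition_sep, segment_term = segment_term)
  if (any(nchar(chars) != 1L)) {
    abort_config("all delimiters must be single characters")
  }
  if (anyDuplicated(chars)) {
    abort_config("delimiters must be pairwise distinct")
  }
  if (any(grepl("[0-9A-Z]", chars))) {
    abort_config("delimiters must not be digits or uppercase letters")
  }
  structure(as.list(chars), class = "delimiter_set")
}

#' @export
print.delimiter_set <- function(x, ...) {
  cat(sprintf("<delimiter_set> element '%s'  component '%s'  repetition '%s'  terminator '%s'\n",
              x$element_sep, x$component_sep, x$repetition_sep, x$segment_term))
  invisible(x)
}

#' Interchange envelope metadata
#'
#' Fields that populate the ISA/GS envelope and seed per-transaction
#' control numbers. Dates and times default to fixed constants rather than
#' the wall clock so that identical seeds always yield byte-identical
#' files.
#'
#' @param sender_id,receiver_id Interchange sender/receiver IDs (at most 15
#'   characters; padded to 15 inside the fixed-width ISA).
#' @param interchange_control_number 9-digit string; repeated on the IEA
#'   trailer.
#' @param group_control_number Positive integer; repeated on the GE trailer.
#' @param interchange_date,interchange_time The ISA/GS timestamp.
#' @param usage_indicator `"T"` (test) or `"P"` (production).
#' @return An object of class `envelope_meta`.
#' @export
envelope_meta <- function(sender_id = "SYNTHSENDER",
                          receiver_id = "SYNTHRECVR",
                          interchange_control_number = "000044146",
                          group_control_number = 1L,
                          interchange_date = as.Date("2024-06-01"),
                          interchange_time = "0830",
                          usage_indicator = "T") {
  if (nchar(sender_id) > 15L || nchar(receiver_id) > 15L) {
    abort_config("sender_id and receiver_id must be at most 15 characters")
  }
  if (!grepl("^[0-9]{9}$", interchange_control_number)) {
    abort_config("interchange_control_number must be a 9-digit string")
  }
  if (!is_count(group_control_number)) {
    abort_config("group_control_number must be a positive integer")
  }
  if (!usage_indicator %in% c("T", "P")) {
    abort_config("usage_indicator must be 'T' or 'P'")
  }
  if (!grepl("^[0-9]{4}$", interchange_time)) {
    abort_config("interchange_time must be 4 digits HHMM")
  }
  structure(
    list(sender_id = sender_id, receiver_id = receiver_id,
         interchange_control_number = interchange_control_number,
         group_control_number = as.integer(group_control_number),
         interchange_date = as.Date(interchange_date),
         interchange_time = interchange_time,
         usage_indicator = usage_indicator),
    class = "envelope_meta"
  )
}

#' Subscriber (the insured member) on a claim
#'
#' @param first_name,last_name Name parts, nonempty.
#' @param member_id Digit string, 5-9 digits.
#' @param payer A payer record (list with `hios_id`, `product_name`,
#'   `payer_type`), e.g. from [sample_payer()].
#' @param birth_date A date.
#' @param gender One of `"M"`, `"F"`, `"U"`.
#' @return An object of class `subscriber`.
#' @export
subscriber <- function(first_name, last_name, member_id, payer,
                       birth_date = as.Date("1980-01-01"), gender = "U") {
  if (!nzchar(first_name) || !nzchar(last_name)) {
    abort_config("subscriber names must be nonempty")
  }
  if (!grepl("^[0-9]{5,9}$", member_id)) {
    abort_config("member_id must be a 5-9 digit string")
  }
  if (!gender %in% c("M", "F", "U")) abort_config("gender must be M, F or U")
  structure(
    list(first_name = first_name, last_name = last_name,
         member_id = member_id, payer = payer,
         birth_date = as.Date(birth_date), gender = gender),
    class = "subscriber"
  )
}

#' One diagnosis on a claim
#'
#' @param code ICD-10-CM code (no dot).
#' @param ordinal Position on the claim, 1-12; ordinal 1 is the principal
#'   diagnosis.
#' @param qualifier `"ABK"` (principal) or `"ABF"` (other diagnosis).
#' @param poa Present-on-admission indicator: `Y`, `N`, `U`, `W` or `1`.
#' @return An object of class `diagnosis_entry`.
#' @export
diagnosis_entry <- function(code, ordinal, qualifier = if (ordinal == 1L) "ABK" else "ABF",
                            poa = "Y") {
  if (!grepl(ICD10_PATTERN, code)) {
    abort_config(sprintf("'%s' is not a valid dotless ICD-10-CM code", code))
  }
  if (!is_count(ordinal) || ordinal > 12) abort_config("ordinal must be in 1..12")
  if (!qualifier %in% c("ABK", "ABF")) abort_config("qualifier must be ABK or ABF")
  if (!poa %in% c("Y", "N", "U", "W", "1")) abort_config("poa must be one of Y,N,U,W,1")
  structure(
    list(qualifier = qualifier, code = code, poa = poa,
         ordinal = as.integer(ordinal)),
    class = "diagnosis_entry"
  )
}

#' One service line on a claim
#'
#' @param line_number Position on the claim, 1-50.
#' @param procedure_code HCPCS code (5 characters); serialized with the
#'   `HC` qualifier.
#' @param charge Non-negative line charge (at most 2 decimal places).
#' @param quantity Positive integer unit count (unit basis `UN`).
#' @param diagnosis_pointers 1-4 distinct integers, each pointing at a
#'   diagnosis ordinal on the same claim; stored sorted ascending.
#' @param service_date Date of service.
#' @param revenue_code 4-digit institutional revenue code.
#' @return An object of class `service_line`.
#' @export
service_line <- function(line_number, procedure_code, charge, quantity = 1L,
                         diagnosis_pointers = 1L,
                         service_date = as.Date("2018-04-28"),
                         revenue_code = "0300") {
  if (!is_count(line_number) || line_number > 50) {
    abort_config("line_number must be in 1..50")
  }
  if (!grepl(HCPCS_PATTERN, procedure_code)) {
    abort_config(sprintf("'%s' is not a valid HCPCS code", procedure_code))
  }
  if (!is.numeric(charge) || length(charge) != 1L || charge < 0) {
    abort_config("charge must be a non-negative number")
  }
  if (abs(charge * 100 - round(charge * 100)) > 1e-6) {
    abort_config("charge must have at most 2 decimal places")
  }
  if (!is_count(quantity)) abort_config("quantity must be a positive integer")
  dp <- as.integer(diagnosis_pointers)
  if (length(dp) < 1L || length(dp) > 4L || anyDuplicated(dp) ||
      any(dp < 1L) || any(dp > 12L)) {
    abort_config("diagnosis_pointers must be 1-4 distinct integers in 1..12")
  }
  if (!grepl("^[0-9]{4}$", revenue_code)) {
    abort_config("revenue_code must be 4 digits")
  }
  structure(
    list(line_number = as.integer(line_number), procedure_qualifier = "HC",
         procedure_code = procedure_code, charge = round(charge, 2),
         unit = "UN", quantity = as.integer(quantity),
         diagnosis_pointers = sort(dp),
         service_date = as.Date(service_date), revenue_code = revenue_code),
    class = "service_line"
  )
}

#' Assemble an institutional claim
#'
#' Builds the full 837i claim object: billing provider (2000A), subscriber
#' (2000B), claim-level data (2300) with its ordered diagnosis list, and
#' service lines (2400) whose diagnosis pointers reference diagnosis
#' ordinals. The total charge is derived from the lines.
#'
#' @param claim_id Digit-string claim identifier (default width 10).
#' @param transaction_control_number Digit string echoed on ST02/SE02.
#' @param provider A provider record (list with `npi`, `org_name`,
#'   `taxonomy`, `street`, `city`, `state`, `zip`).
#' @param subscriber A [subscriber()] object.
#' @param diagnoses List of [diagnosis_entry()] objects, ordinals
#'   consecutive from 1, at most 12.
#' @param service_lines List of [service_line()] objects, line numbers
#'   consecutive from 1, at most 50.
#' @param facility_type_code 2-digit facility type (default `"11"`).
#' @param claim_frequency_code 1-digit frequency (default `"1"`, original
#'   claim).
#' @return An object of class `institutional_claim`. Construction does not
#'   raise on cross-field violations; use [validate_claim()] to collect
#'   them.
#' @export
institutional_claim <- function(claim_id, transaction_control_number,
                                provider, subscriber, diagnoses, service_lines,
                                facility_type_code = "11",
                                claim_frequency_code = "1") {
  total <- round(sum(vapply(service_lines, function(l) l$charge, numeric(1))), 2)
  structure(
    list(claim_id = claim_id,
         transaction_control_number = transaction_control_number,
         provider = provider, subscriber = subscriber,
         diagnoses = diagnoses, service_lines = service_lines,
         total_charge = total,
         facility_type_code = facility_type_code,
         claim_frequency_code = claim_frequency_code),
    class = "institutional_claim"
  )
}

#' @export
print.institutional_claim <- function(x, ...) {
  cat(sprintf("<institutional_claim> %s\n", x$claim_id))
  cat(sprintf("  billing provider: %s (NPI %s), %s %s\n",
              x$provider$org_name, x$provider$npi, x$provider$city, x$provider$state))
  cat(sprintf("  subscriber: %s %s (ID %s)\n",
              x$subscriber$first_name, x$subscriber$last_name, x$subscriber$member_id))
  cat(sprintf("  %d diagnoses, %d service lines, total charge %s\n",
              length(x$diagnoses), length(x$service_lines),
              format_charge(x$total_charge)))
  invisible(x)
}

#' Validate an institutional claim
#'
#' Checks every cross-field invariant of the claim model and returns the
#' violations as messages (an empty character vector means the claim is
#' well formed). Nothing is raised: the point is a complete report.
#'
#' Checked: claim and control identifiers digit-shaped; 1-12 diagnoses
#' with distinct codes and ordinals consecutive from 1 (exactly one
#' principal); 1-50 service lines numbered consecutively from 1; every
#' diagnosis pointer inside `[1, number of diagnoses]`; total charge equal
#' to the sum of line charges; provider NPI Luhn-valid.
#'
#' @param claim An [institutional_claim()].
#' @return Character vector of violation messages (possibly empty).
#' @examples
#' validate_claim(worked_example_claim())
#' @export
validate_claim <- function(claim) {
  v <- character()
  add <- function(msg) v <<- c(v, msg)

  if (!grepl("^[0-9]+$", claim$claim_id %||% "")) {
    add("claim_id must be a digit string")
  }
  if (!grepl("^[0-9]+$", claim$transaction_control_number %||% "")) {
    add("transaction_control_number must be a digit string")
  }
  if (!grepl("^[0-9]{10}$", claim$provider$npi %||% "") ||
      !npi_is_valid(claim$provider$npi)) {
    add(sprintf("provider NPI '%s' fails the Luhn check", claim$provider$npi))
  }

  ndx <- length(claim$diagnoses)
  if (ndx < 1L || ndx > 12L) {
    add(sprintf("claim must carry 1-12 diagnoses, found %d", ndx))
  }
  if (ndx >= 1L) {
    ords <- vapply(claim$diagnoses, function(d) d$ordinal, integer(1))
    if (!identical(ords, seq_len(ndx))) {
      add("diagnosis ordinals must be consecutive from 1")
    }
    codes <- vapply(claim$diagnoses, function(d) d$code, character(1))
    if (anyDuplicated(codes)) add("diagnosis codes must be distinct within a claim")
    if (sum(ords == 1L) != 1L) add("exactly one diagnosis must have ordinal 1")
  }

  nln <- length(claim$service_lines)
  if (nln < 1L || nln > 50L) {
    add(sprintf("claim must carry 1-50 service lines, found %d", nln))
  }
  if (nln >= 1L) {
    lns <- vapply(claim$service_lines, function(l) l$line_number, integer(1))
    if (!identical(lns, seq_len(nln))) {
      add("service line numbers must be consecutive from 1")
    }
    for (l in claim$service_lines) {
      bad <- l$diagnosis_pointers[l$diagnosis_pointers < 1L |
                                  l$diagnosis_pointers > ndx]
      if (length(bad)) {
        add(sprintf("line %d: diagnosis pointer(s) %s outside [1, %d]",
                    l$line_number, paste(bad, collapse = ", "), ndx))
      }
      if (is.unsorted(l$diagnosis_pointers, strictly = TRUE)) {
        add(sprintf("line %d: diagnosis pointers must be strictly ascending",
                    l$line_number))
      }
    }
    total <- round(sum(vapply(claim$service_lines, function(l) l$charge, numeric(1))), 2)
    if (abs(total - claim$total_charge) > 1e-6) {
      add(sprintf("total charge %s does not equal sum of line charges %s",
                  format_charge(claim$total_charge), format_charge(total)))
    }
  }
  v
}

#' The worked-example claim
#'
#' A fixed single-claim fixture: institutional claim 4742333269 billed by
#' HSA GLENWOOD, LLC (NPI 1548083421, Glendale CA) for subscriber Jonathan
#' Mendez (member ID 3191511), carrying six diagnoses and three service
#' lines dated 2018-04-28. Useful as a stable, human-checkable example for
#' teaching the loop structure and for round-trip tests.
#'
#' The diagnosis qualifier is stored as `ABK` on all six rows, exactly as
#' this fixture is conventionally tabulated; randomly generated claims
#' instead follow the X12 convention of `ABK` for the principal diagnosis
#' and `ABF` for the rest. Fields that the tabulation does not pin down
#' (addresses, birth date, revenue codes, POA flags) are fixed synthetic
#' values.
#'
#' @return An [institutional_claim()]; every call returns an identical
#'   object.
#' @examples
#' worked_example_claim()
#' @export
worked_example_claim <- function() {
  provider <- list(
    npi = "1548083421", org_name = "HSA GLENWOOD, LLC",
    taxonomy = "282N00000X", street = "1420 GLENOAKS BLVD",
    city = "GLENDALE", state = "CA", zip = "91201"
  )
  payer <- list(hios_id = "40513", product_name = "Sierra Gold Choice PPO",
                payer_type = "COMMERCIAL")
  sub <- subscriber("Jonathan", "Mendez", "3191511", payer,
                    birth_date = as.Date("1985-03-14"), gender = "M")
  dx_codes <- c("T82330A", "S62665A", "Z13811", "S72141Q", "S61431A", "H61301")
  diagnoses <- lapply(seq_along(dx_codes), function(i)
    diagnosis_entry(dx_codes[i], ordinal = i, qualifier = "ABK", poa = "Y"))
  svc_date <- as.Date("2018-04-28")
  lines <- list(
    service_line(1L, "97605",  76, 1L, c(1L),          svc_date, "0420"),
    service_line(2L, "67228",  33, 1L, c(2L, 4L, 6L),  svc_date, "0510"),
    service_line(3L, "92316", 107, 1L, c(6L),          svc_date, "0510")
  )
  institutional_claim(
    claim_id = "4742333269", transaction_control_number = "44146",
    provider = provider, subscriber = sub,
    diagnoses = diagnoses, service_lines = lines
  )
}

#' Generator configuration
#'
#' Bounds and knobs for random claim generation. Diagnosis counts are
#' limited to 1-12 and service-line counts to 1-50 — the configurable
#' complexity range of the institutional claim model — and values outside
#' those ranges are rejected up front, before any sampling.
#'
#' @param n_claims Number of claims to generate (positive integer; no
#'   library-level ceiling — the CLI's web profile caps a session at 25).
#' @param dx_min,dx_max Diagnosis-count range, each in 1-12.
#' @param line_min,line_max Service-line-count range, each in 1-50.
#' @param max_pointers_per_line Maximum diagnosis pointers per line, 1-4.
#' @param seed Integer seed; the single source of randomness.
#' @param service_year_range Two years (inclusive) that service dates are
#'   drawn from.
#' @param claim_id_width,member_id_width Identifier widths in digits.
#' @return An object of class `generator_config`.
#' @examples
#' generator_config(n_claims = 5, seed = 42)
#' @export
generator_config <- function(n_claims = 1L, dx_min = 1L, dx_max = 12L,
                             line_min = 1L, line_max = 50L,
                             max_pointers_per_line = 4L, seed = 1L,
                             service_year_range = c(2018L, 2024L),
                             claim_id_width = 10L, member_id_width = 7L) {
  if (!is_count(n_claims)) abort_config("n_claims must be a positive integer")
  for (nm in c("dx_min", "dx_max")) {
    val <- get(nm)
    if (!is_count(val) || val > 12) {
      abort_config(sprintf("%s must be an integer in [1, 12]", nm))
    }
  }
  for (nm in c("line_min", "line_max")) {
    val <- get(nm)
    if (!is_count(val) || val > 50) {
      abort_config(sprintf("%s must be an integer in [1, 50]", nm))
    }
  }
  if (dx_min > dx_max) abort_config("dx_min must not exceed dx_max")
  if (line_min > line_max) abort_config("line_min must not exceed line_max")
  if (!is_count(max_pointers_per_line) || max_pointers_per_line > 4) {
    abort_config("max_pointers_per_line must be an integer in [1, 4]")
  }
  if (length(service_year_range) != 2L ||
      service_year_range[1] > service_year_range[2]) {
    abort_config("service_year_range must be two non-decreasing years")
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort_config("seed must be a single integer")
  }
  if (!is_count(member_id_width) || member_id_width < 5 || member_id_width > 9) {
    abort_config("member_id_width must be in [5, 9]")
  }
  if (!is_count(claim_id_width) || claim_id_width < 5 || claim_id_width > 15) {
    abort_config("claim_id_width must be in [5, 15]")
  }
  structure(
    list(n_claims = as.integer(n_claims),
         dx_min = as.integer(dx_min), dx_max = as.integer(dx_max),
         line_min = as.integer(line_min), line_max = as.integer(line_max),
         max_pointers_per_line = as.integer(max_pointers_per_line),
         seed = as.integer(seed),
         service_year_range = as.integer(service_year_range),
         claim_id_width = as.integer(claim_id_width),
         member_id_width = as.integer(member_id_width)),
    class = "generator_config"
  )
}
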