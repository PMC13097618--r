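# X12 5010 837i serialization and parsing.
#
# Dialect constants (bit-exact): the ISA header is fixed-width (106
# characters including its terminator); ISA01/ISA03 are "00" with
# blank-padded authorization/security fields; both ID qualifiers are "ZZ";
# ISA12 is "00501"; GS01 is "HC"; GS08 and ST03 carry the implementation
# convention reference "005010X223A2"; ST01 is "837"; BHT01 is "0019".
#
# File-format note — diagnosis pointers: the institutional service line
# (SV2) has no standard diagnosis-pointer element, but this package's
# relational outputs carry per-line pointers, so the serializer writes them
# as a component-separated composite in SV2 element 7 (SV206, unit rate, is
# left empty) and the parser reads that same position. This is a documented
# deviation from the bare implementation guide.

X12_VERSION  <- "00501"
X12_IC_REF   <- "005010X223A2"
ISA_LEN      <- 106L

seg_join <- function(elements, d, trim = TRUE) {
  elements <- as.character(elements)
  if (trim) {
    while (length(elements) > 1L && !nzchar(elements[length(elements)])) {
      elements <- elements[-length(elements)]
    }
  }
  paste(elements, collapse = d$element_sep)
}

pad <- function(x, width) formatC(x, width = -width, flag = " ")

claim_filing_code <- function(payer_type) {
  switch(payer_type, MEDICARE = "MA", MEDICAID = "MC", "CI")
}

build_isa <- function(envelope, d) {
  fields <- c(
    "00", pad("", 10), "00", pad("", 10),
    "ZZ", pad(envelope$sender_id, 15), "ZZ", pad(envelope$receiver_id, 15),
    format(envelope$interchange_date, "%y%m%d"), envelope$interchange_time,
    d$repetition_sep, X12_VERSION,
    envelope$interchange_control_number, "0", envelope$usage_indicator,
    d$component_sep
  )
  paste0("ISA", d$element_sep, paste(fields, collapse = d$element_sep))
}

hi_composite <- function(dx, d) {
  paste(c(dx$qualifier, dx$code, rep("", 6), dx$poa),
        collapse = d$component_sep)
}

# All segments of one claim's ST...SE transaction, SE count filled in last.
build_transaction <- function(claim, envelope, d) {
  cs <- d$component_sep
  segs <- c(
    seg_join(c("ST", "837", claim$transaction_control_number, X12_IC_REF), d),
    seg_join(c("BHT", "0019", "00", claim$claim_id,
               format_ccyymmdd(envelope$interchange_date),
               envelope$interchange_time, "CH"), d),
    seg_join(c("NM1", "41", "2", "SYNTH CLAIMS SUBMITTER", "", "", "", "",
               "46", envelope$sender_id), d),
    seg_join(c("NM1", "40", "2", "SYNTH CLAIMS RECEIVER", "", "", "", "",
               "46", envelope$receiver_id), d),
    # 2000A billing provider loop
    seg_join(c("HL", "1", "", "20", "1"), d),
    seg_join(c("NM1", "85", "2", claim$provider$org_name, "", "", "", "",
               "XX", claim$provider$npi), d),
    seg_join(c("N3", claim$provider$street), d),
    seg_join(c("N4", claim$provider$city, claim$provider$state,
               claim$provider$zip), d),
    seg_join(c("REF", "EI", paste0("75", substr(claim$provider$npi, 1, 7))), d),
    # 2000B subscriber loop
    seg_join(c("HL", "2", "1", "22", "0"), d),
    seg_join(c("SBR", "P", "18", rep("", 6),
               claim_filing_code(claim$subscriber$payer$payer_type)), d),
    seg_join(c("NM1", "IL", "1", claim$subscriber$last_name,
               claim$subscriber$first_name, "", "", "", "MI",
               claim$subscriber$member_id), d),
    seg_join(c("DMG", "D8", format_ccyymmdd(claim$subscriber$birth_date),
               claim$subscriber$gender), d),
    seg_join(c("NM1", "PR", "2", claim$subscriber$payer$product_name,
               "", "", "", "", "PI", claim$subscriber$payer$hios_id), d),
    # 2300 claim loop
    seg_join(c("CLM", claim$claim_id, format_charge(claim$total_charge),
               "", "",
               paste(claim$facility_type_code, "A", claim$claim_frequency_code,
                     sep = cs),
               "Y", "A", "Y", "Y"), d),
    seg_join(c("DTP", "434", "RD8",
               paste(format_ccyymmdd(claim$service_lines[[1]]$service_date),
                     format_ccyymmdd(claim$service_lines[[1]]$service_date),
                     sep = "-")), d)
  )
  # HI packing: the principal diagnosis in its own HI, the remaining
  # diagnoses (up to 11 composites) in a second HI.
  segs <- c(segs, seg_join(c("HI", hi_composite(claim$diagnoses[[1]], d)), d))
  if (length(claim$diagnoses) > 1L) {
    rest <- vapply(claim$diagnoses[-1], hi_composite, character(1), d = d)
    segs <- c(segs, seg_join(c("HI", rest), d))
  }
  for (l in claim$service_lines) {
    segs <- c(segs,
      seg_join(c("LX", l$line_number), d),
      seg_join(c("SV2", l$revenue_code,
                 paste(l$procedure_qualifier, l$procedure_code, sep = cs),
                 format_charge(l$charge), l$unit, l$quantity, "",
                 paste(l$diagnosis_pointers, collapse = cs)), d),
      seg_join(c("DTP", "472", "D8", format_ccyymmdd(l$service_date)), d)
    )
  }
  n_segs <- length(segs) + 1L  # ST through SE inclusive
  c(segs, seg_join(c("SE", n_segs, claim$transaction_control_number), d))
}

#' Serialize claims to X12 837i text
#'
#' Writes one interchange: the fixed-width ISA header, one GS functional
#' group, one ST...SE transaction per claim (BHT, submitter/receiver names,
#' the 2000A billing-provider loop, the 2000B subscriber loop, the 2300
#' claim loop with HI diagnosis composites and POA indicators, and a 2400
#' LX/SV2/DTP group per service line), then the GE and IEA trailers. SE01
#' carries the transaction's segment count (ST through SE inclusive); GE01
#' the transaction count; IEA01 the group count; trailer control numbers
#' repeat their header counterparts.
#'
#' @param claims A single claim or list of [institutional_claim()] objects;
#'   each must pass [validate_claim()].
#' @param envelope An [envelope_meta()].
#' @param delimiters A [delimiter_set()].
#' @param newline Insert a newline after each segment terminator (default;
#'   one segment per line reads well in class). `FALSE` emits one
#'   uninterrupted stream.
#' @return A single string of X12 837i text.
#' @examples
#' txt <- serialize_interchange(worked_example_claim(), envelope_meta())
#' substr(txt, 1, 3)
#' @export
serialize_interchange <- function(claims, envelope = envelope_meta(),
                                  delimiters = delimiter_set(),
                                  newline = TRUE) {
  if (inherits(claims, "institutional_claim")) claims <- list(claims)
  if (length(claims) == 0L) abort_input("cannot serialize an empty claim list")
  stopifnot(inherits(envelope, "envelope_meta"),
            inherits(delimiters, "delimiter_set"))
  for (i in seq_along(claims)) {
    viol <- validate_claim(claims[[i]])
    if (length(viol)) {
      abort_input(sprintf("claim %d is invalid: %s", i, viol[1]))
    }
  }
  d <- delimiters
  gs <- seg_join(c("GS", "HC", trimws(envelope$sender_id),
                   trimws(envelope$receiver_id),
                   format_ccyymmdd(envelope$interchange_date),
                   envelope$interchange_time, envelope$group_control_number,
                   "X", X12_IC_REF), d)
  body <- unlist(lapply(claims, build_transaction, envelope = envelope, d = d))
  ge <- seg_join(c("GE", length(claims), envelope$group_control_number), d)
  iea <- seg_join(c("IEA", "1", envelope$interchange_control_number), d)
  segs <- c(build_isa(envelope, d), gs, body, ge, iea)
  sep <- if (newline) paste0(d$segment_term, "\n") else d$segment_term
  paste0(paste(segs, collapse = sep), d$segment_term, if (newline) "\n" else "")
}

#' Detect the delimiter set of X12 text
#'
#' The ISA header is fixed-width, so the separators sit at fixed byte
#' offsets: the element separator immediately after `ISA`, the repetition
#' separator in ISA11, the component separator in ISA16, and the segment
#' terminator right after it.
#'
#' @param text X12 text beginning with `ISA`.
#' @return A [delimiter_set()].
#' @examples
#' detect_delimiters(serialize_interchange(worked_example_claim()))
#' @export
detect_delimiters <- function(text) {
  if (!is_scalar_chr(text) || nchar(text) < ISA_LEN || substr(text, 1, 3) != "ISA") {
    abort_parse("not an X12 interchange: text must start with a 106-character ISA segment")
  }
  ch <- function(i) substr(text, i + 1L, i + 1L)  # 0-based offsets
  tryCatch(
    delimiter_set(element_sep = ch(3L), component_sep = ch(104L),
                  repetition_sep = ch(82L), segment_term = ch(105L)),
    x12_config_error = function(e) {
      abort_parse(paste0("invalid delimiters in ISA header: ",
                         conditionMessage(e)))
    }
  )
}

# Split X12 text into segments; newlines and carriage returns after a
# terminator are cosmetic and dropped. Returns tag, raw elements, and the
# 1-based segment index.
split_segments <- function(text, d) {
  chunks <- strsplit(text, d$segment_term, fixed = TRUE)[[1]]
  chunks <- gsub("^[\r\n[:space:]]+", "", chunks)
  chunks <- chunks[nzchar(chunks)]
  lapply(seq_along(chunks), function(i) {
    el <- strsplit(chunks[i], d$element_sep, fixed = TRUE)[[1]]
    list(tag = el[1], elements = el[-1], index = i)
  })
}

el <- function(seg, i) {
  if (length(seg$elements) >= i) seg$elements[i] else ""
}

components <- function(value, d) strsplit(value, d$component_sep, fixed = TRUE)[[1]]

comp <- function(value, i, d) {
  parts <- components(value, d)
  if (length(parts) >= i) parts[i] else ""
}

parse_claim_from_segments <- function(segs, d, tcn, bht_ref) {
  rec <- list(
    claim_id = NA_character_, transaction_control_number = tcn,
    bht_reference = bht_ref,
    provider = list(npi = NA_character_, org_name = NA_character_,
                    street = NA_character_, city = NA_character_,
                    state = NA_character_, zip = NA_character_),
    subscriber = list(first_name = NA_character_, last_name = NA_character_,
                      member_id = NA_character_, payer_name = NA_character_,
                      payer_id = NA_character_, birth_date = as.Date(NA),
                      gender = NA_character_),
    facility_type_code = NA_character_, claim_frequency_code = NA_character_,
    total_charge = NA_real_,
    diagnoses = NULL, service_lines = NULL
  )
  dx_qual <- character(); dx_code <- character(); dx_poa <- character()
  ln_no <- integer(); ln_code <- character(); ln_charge <- numeric()
  ln_qty <- integer(); ln_rev <- character(); ln_date <- character()
  ln_ptrs <- list()
  in_provider_n3 <- FALSE
  cur_line <- NA_integer_

  for (seg in segs) {
    tag <- seg$tag
    if (tag == "NM1") {
      kind <- el(seg, 1)
      if (kind == "85") {
        rec$provider$org_name <- el(seg, 3)
        rec$provider$npi <- el(seg, 9)
        in_provider_n3 <- TRUE
      } else if (kind == "IL") {
        rec$subscriber$last_name <- el(seg, 3)
        rec$subscriber$first_name <- el(seg, 4)
        rec$subscriber$member_id <- el(seg, 9)
      } else if (kind == "PR") {
        rec$subscriber$payer_name <- el(seg, 3)
        rec$subscriber$payer_id <- el(seg, 9)
      }
    } else if (tag == "N3" && in_provider_n3) {
      rec$provider$street <- el(seg, 1)
    } else if (tag == "N4" && in_provider_n3) {
      rec$provider$city <- el(seg, 1)
      rec$provider$state <- el(seg, 2)
      rec$provider$zip <- el(seg, 3)
      in_provider_n3 <- FALSE
    } else if (tag == "DMG") {
      rec$subscriber$birth_date <- parse_ccyymmdd(el(seg, 2))
      rec$subscriber$gender <- el(seg, 3)
    } else if (tag == "CLM") {
      rec$claim_id <- el(seg, 1)
      rec$total_charge <- suppressWarnings(as.numeric(el(seg, 2)))
      rec$facility_type_code <- comp(el(seg, 5), 1, d)
      rec$claim_frequency_code <- comp(el(seg, 5), 3, d)
    } else if (tag == "HI") {
      for (val in seg$elements) {
        parts <- components(val, d)
        if (length(parts) >= 2L) {
          dx_qual <- c(dx_qual, parts[1])
          dx_code <- c(dx_code, parts[2])
          dx_poa <- c(dx_poa, if (length(parts) >= 9L) parts[9] else "")
        }
      }
    } else if (tag == "LX") {
      cur_line <- suppressWarnings(as.integer(el(seg, 1)))
      ln_no <- c(ln_no, cur_line)
      ln_code <- c(ln_code, NA_character_)
      ln_charge <- c(ln_charge, NA_real_)
      ln_qty <- c(ln_qty, NA_integer_)
      ln_rev <- c(ln_rev, NA_character_)
      ln_date <- c(ln_date, NA_character_)
      ln_ptrs <- c(ln_ptrs, list(integer()))
    } else if (tag == "SV2" && length(ln_no)) {
      i <- length(ln_no)
      ln_rev[i] <- el(seg, 1)
      ln_code[i] <- comp(el(seg, 2), 2, d)
      ln_charge[i] <- suppressWarnings(as.numeric(el(seg, 3)))
      ln_qty[i] <- suppressWarnings(as.integer(el(seg, 5)))
      ptr_raw <- el(seg, 7)
      if (nzchar(ptr_raw)) {
        ln_ptrs[[i]] <- as.integer(components(ptr_raw, d))
      }
    } else if (tag == "DTP" && el(seg, 1) == "472" && length(ln_no)) {
      ln_date[length(ln_no)] <- el(seg, 3)
    }
  }

  if (length(dx_code)) {
    rec$diagnoses <- data.frame(
      qualifier = dx_qual, code = dx_code, poa = dx_poa,
      ordinal = seq_along(dx_code), stringsAsFactors = FALSE
    )
  } else {
    rec$diagnoses <- data.frame(qualifier = character(), code = character(),
                                poa = character(), ordinal = integer())
  }
  rec$service_lines <- data.frame(
    line_number = ln_no, procedure_code = ln_code, charge = ln_charge,
    unit = rep("UN", length(ln_no)), quantity = ln_qty,
    service_date = ln_date, revenue_code = ln_rev, stringsAsFactors = FALSE
  )
  rec$service_lines$diagnosis_pointers <- ln_ptrs
  rec
}

render_pointers <- function(ptrs) {
  paste0("[", paste(ptrs, collapse = ", "), "]")
}

#' Parse X12 837i text into structured records
#'
#' Splits the text into segments under the delimiters detected from the
#' ISA header, checks the envelope arithmetic (each SE01 must equal the
#' transaction's segment count; every ST needs its SE, every GS its GE,
#' and the interchange must close with IEA), and extracts one claim record
#' per CLM together with three relational projections: header rows (one
#' per claim), diagnosis rows (one per claim x diagnosis), and service-line
#' rows (one per claim x line). Segments it does not model are preserved
#' in the segment list but ignored for the tables.
#'
#' @param text X12 837i text (a single string).
#' @return An object of class `parsed_interchange`: delimiters, envelope
#'   metadata, the raw `segments`, structured `claims`, and the
#'   `header_rows` / `diagnosis_rows` / `service_line_rows` data frames.
#' @examples
#' parsed <- parse_interchange(serialize_interchange(worked_example_claim()))
#' parsed$header_rows$subscriber_name
#' @export
parse_interchange <- function(text) {
  d <- detect_delimiters(text)
  segs <- split_segments(text, d)
  tags <- vapply(segs, function(s) s$tag, character(1))

  if (tags[1] != "ISA") abort_parse("segment 1: expected ISA")
  isa <- segs[[1]]
  envelope <- list(
    sender_id = trimws(el(isa, 6)), receiver_id = trimws(el(isa, 8)),
    interchange_control_number = el(isa, 13),
    usage_indicator = el(isa, 15),
    group_control_number = NA_character_,
    version = el(isa, 12)
  )
  if (!"IEA" %in% tags) abort_parse("unterminated interchange: no IEA trailer")
  gs_i <- which(tags == "GS")
  if (length(gs_i) < 1L) abort_parse("unbalanced envelopes: no GS segment")
  if (!"GE" %in% tags) {
    abort_parse(sprintf("unbalanced envelopes: GS at segment %d has no GE trailer",
                        gs_i[1]))
  }
  envelope$group_control_number <- el(segs[[gs_i[1]]], 6)

  st_i <- which(tags == "ST")
  se_i <- which(tags == "SE")
  if (length(st_i) != length(se_i)) {
    abort_parse(sprintf("unbalanced envelopes: %d ST but %d SE segments (segment %d)",
                        length(st_i), length(se_i),
                        if (length(st_i)) st_i[length(st_i)] else 1L))
  }

  claims <- list()
  for (k in seq_along(st_i)) {
    lo <- st_i[k]; hi <- se_i[k]
    if (hi < lo) abort_parse(sprintf("unbalanced envelopes: SE at segment %d precedes its ST", hi))
    st <- segs[[lo]]; se <- segs[[hi]]
    tcn <- el(st, 2)
    n_expected <- suppressWarnings(as.integer(el(se, 1)))
    n_actual <- hi - lo + 1L
    if (is.na(n_expected) || n_expected != n_actual) {
      abort_parse(sprintf(
        "SE count mismatch at segment %d: SE01 says %s segments, counted %d",
        hi, el(se, 1), n_actual))
    }
    body <- segs[(lo + 1L):(hi - 1L)]
    bht <- Filter(function(s) s$tag == "BHT", body)
    bht_ref <- if (length(bht)) el(bht[[1]], 3) else ""
    clm_idx <- which(vapply(body, function(s) s$tag, character(1)) == "CLM")
    if (length(clm_idx) == 0L) next
    bounds <- c(clm_idx, length(body) + 1L)
    for (ci in seq_along(clm_idx)) {
      # each claim: provider/subscriber context precedes the CLM; the claim
      # loop runs to the next CLM (or transaction end)
      ctx_start <- if (ci == 1L) 1L else bounds[ci]
      claim_segs <- body[ctx_start:(bounds[ci + 1L] - 1L)]
      if (ci > 1L) claim_segs <- c(body[1:(clm_idx[1] - 1L)], claim_segs)
      claims[[length(claims) + 1L]] <-
        parse_claim_from_segments(claim_segs, d, tcn, bht_ref)
    }
  }

  header_rows <- do.call(rbind, c(list(
    data.frame(transaction_set_id = character(), control_number = character(),
               isa_sender = character(), isa_receiver = character(),
               gs_control_number = character(), bht_reference = character(),
               billing_provider = character(), provider_npi = character(),
               provider_city = character(), provider_state = character(),
               subscriber_name = character(), subscriber_id = character(),
               stringsAsFactors = FALSE)),
    lapply(claims, function(cl) data.frame(
      transaction_set_id = "837",
      control_number = cl$transaction_control_number,
      isa_sender = envelope$sender_id, isa_receiver = envelope$receiver_id,
      gs_control_number = envelope$group_control_number,
      bht_reference = cl$bht_reference,
      billing_provider = cl$provider$org_name,
      provider_npi = cl$provider$npi,
      provider_city = cl$provider$city, provider_state = cl$provider$state,
      subscriber_name = paste(cl$subscriber$first_name, cl$subscriber$last_name),
      subscriber_id = cl$subscriber$member_id, stringsAsFactors = FALSE))))

  diagnosis_rows <- do.call(rbind, c(list(
    data.frame(claim_id = character(), diagnosis_type = character(),
               diagnosis_code = character(), pointer = integer(),
               stringsAsFactors = FALSE)),
    lapply(claims, function(cl) {
      if (nrow(cl$diagnoses) == 0L) return(NULL)
      data.frame(claim_id = cl$claim_id, diagnosis_type = cl$diagnoses$qualifier,
                 diagnosis_code = cl$diagnoses$code,
                 pointer = cl$diagnoses$ordinal, stringsAsFactors = FALSE)
    })))

  service_line_rows <- do.call(rbind, c(list(
    data.frame(claim_id = character(), line_number = integer(),
               procedure_code = character(), charge = character(),
               unit = character(), qty = integer(),
               diagnosis_pointers = character(), service_date = character(),
               stringsAsFactors = FALSE)),
    lapply(claims, function(cl) {
      sl <- cl$service_lines
      if (nrow(sl) == 0L) return(NULL)
      data.frame(claim_id = cl$claim_id, line_number = sl$line_number,
                 procedure_code = paste0("HC:", sl$procedure_code),
                 charge = format_charge(sl$charge), unit = sl$unit,
                 qty = sl$quantity,
                 diagnosis_pointers = vapply(sl$diagnosis_pointers,
                                             render_pointers, character(1)),
                 service_date = sl$service_date, stringsAsFactors = FALSE)
    })))

  structure(
    list(delimiters = d, envelope = envelope, segments = segs,
         claims = claims, header_rows = header_rows,
         diagnosis_rows = diagnosis_rows,
         service_line_rows = service_line_rows),
    class = "parsed_interchange"
  )
}

#' @export
print.parsed_interchange <- function(x, ...) {
  cat("<parsed_interchange>\n")
  cat(sprintf("  sender %s -> receiver %s (ICN %s)\n",
              x$envelope$sender_id, x$envelope$receiver_id,
              x$envelope$interchange_control_number))
  cat(sprintf("  %d segments, %d claims, %d diagnosis rows, %d service-line rows\n",
              length(x$segments), length(x$claims),
              nrow(x$diagnosis_rows), nrow(x$service_line_rows)))
  invisible(x)
}

#' Write the three relational CSV outputs
#'
#' Projects a parsed interchange to `header.csv` (one row per claim:
#' transaction metadata, billing provider, subscriber), `diagnoses.csv`
#' (claim ID, diagnosis qualifier, code, pointer ordinal) and
#' `service_lines.csv` (claim ID, line number, qualifier-prefixed
#' procedure code, charge, unit, quantity, bracketed pointer list, service
#' date). UTF-8, header row, RFC 4180 quoting on fields that can carry
#' commas.
#'
#' @param parsed A [parse_interchange()] result.
#' @param outdir Output directory (created if absent).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_csv_outputs <- function(parsed, outdir) {
  stopifnot(inherits(parsed, "parsed_interchange"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) abort_input(sprintf("cannot create directory '%s'", outdir))
  paths <- c(header = file.path(outdir, "header.csv"),
             diagnoses = file.path(outdir, "diagnoses.csv"),
             service_lines = file.path(outdir, "service_lines.csv"))
  # quote only the free-text columns that can legitimately contain commas
  utils::write.table(parsed$header_rows, paths["header"], sep = ",",
                     row.names = FALSE, quote = c(7L, 11L), qmethod = "double",
                     fileEncoding = "UTF-8")
  utils::write.table(parsed$diagnosis_rows, paths["diagnoses"], sep = ",",
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  utils::write.table(parsed$service_line_rows, paths["service_lines"], sep = ",",
                     row.names = FALSE, quote = 7L, qmethod = "double",
                     fileEncoding = "UTF-8")
  invisible(paths)
}

#' Read an X12 file from disk as one string
#'
#' @param path Path to a plain-text X12 file.
#' @return The file contents as a single string.
#' @export
read_x12_file <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("input file not found: '%s'", path))
  paste(readLines(path, warn = FALSE), collapse = "\n")
}
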