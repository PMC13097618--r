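# Structural validation of 837i text. Collect-all, never fail-fast: a
# report listing every defect is the point, so findings accumulate and are
# returned sorted by segment index.
#
# Rule catalog:
#   DEL-001  delimiters not pairwise distinct
#   DEL-002  ISA header malformed (missing, short, or not fixed-width)
#   ENV-001  interchange not terminated by IEA
#   ENV-002  IEA02 does not repeat ISA13
#   ENV-003  GS/GE pairing or control-number disagreement
#   ENV-004  GE01 does not equal the transaction count
#   ENV-005  IEA01 does not equal the group count
#   ENV-006  ST/SE pairing or control-number disagreement
#   ENV-007  SE01 does not equal the counted segment total
#   SEQ-001  segment out of order within the transaction
#            (ST < BHT < 2000A < 2000B < 2300 < 2400)
#   SEQ-002  LX line numbering not consecutive from 1
#   SEQ-003  SV2 not directly following its LX
#   LOOP-001 2000A incomplete (NM1*85 missing, or missing N3/N4)
#   LOOP-002 2000B incomplete (SBR missing or without NM1*IL)
#   LOOP-003 2300 incomplete (HI before CLM, or CLM without HI)
#   LOOP-004 2400 incomplete (LX without SV2)
#   PTR-001  service-line diagnosis pointer outside [1, #diagnoses]
#   UNK-001  unknown segment tag (WARNING; ignored for the tables)

KNOWN_TAGS <- c("ISA", "GS", "ST", "BHT", "NM1", "HL", "N3", "N4", "REF",
                "SBR", "DMG", "CLM", "DTP", "HI", "LX", "SV2", "SE", "GE", "IEA")

new_report <- function(findings) {
  findings <- findings[order(findings$segment_index), , drop = FALSE]
  rownames(findings) <- NULL
  structure(
    list(findings = findings,
         error_count = sum(findings$severity == "ERROR"),
         warning_count = sum(findings$severity == "WARNING")),
    class = "validation_report"
  )
}

#' Validate the structure of X12 837i text
#'
#' Applies the structural rule catalog — envelope pairing and control-number
#' arithmetic (ISA/IEA, GS/GE, ST/SE, the SE01 segment count), segment
#' sequencing within a transaction, loop completeness for the
#' 2000A/2000B/2300/2400 hierarchy, delimiter well-formedness, and
#' diagnosis-pointer range — and returns every finding. Nothing is raised:
#' any text is accepted and all problems come back as findings, so a
#' report lists every defect in a hand-edited file, not just the first.
#'
#' @param text X12 text (any string).
#' @return An object of class `validation_report`: a `findings` data frame
#'   (`segment_index` — 1-based, 0 for file-level —, `rule_code`,
#'   `severity`, `message`) plus `error_count` and `warning_count`.
#' @examples
#' report <- validate_structure(serialize_interchange(worked_example_claim()))
#' report$error_count
#' @export
validate_structure <- function(text) {
  idx <- integer(); code <- character(); sev <- character(); msg <- character()
  add <- function(i, rule, severity, message) {
    idx <<- c(idx, i); code <<- c(code, rule)
    sev <<- c(sev, severity); msg <<- c(msg, message)
  }
  done <- function() new_report(data.frame(
    segment_index = idx, rule_code = code, severity = sev, message = msg,
    stringsAsFactors = FALSE))

  if (!is_scalar_chr(text) || nchar(text) < ISA_LEN ||
      substr(text, 1, 3) != "ISA") {
    add(0L, "DEL-002", "ERROR",
        "file does not begin with a 106-character fixed-width ISA header")
    return(done())
  }
  d <- tryCatch(detect_delimiters(text), x12_parse_error = function(e) {
    add(0L, "DEL-001", "ERROR",
        paste0("delimiter fault: ", conditionMessage(e)))
    NULL
  })
  if (is.null(d)) return(done())

  segs <- split_segments(text, d)
  tags <- vapply(segs, function(s) s$tag, character(1))
  isa <- segs[[1]]

  for (s in segs) {
    if (!s$tag %in% KNOWN_TAGS) {
      add(s$index, "UNK-001", "WARNING",
          sprintf("unknown segment '%s' ignored", s$tag))
    }
  }

  # --- envelope arithmetic -------------------------------------------------
  iea_i <- which(tags == "IEA")
  if (length(iea_i) == 0L) {
    add(0L, "ENV-001", "ERROR", "unterminated interchange: no IEA trailer")
  } else {
    iea <- segs[[iea_i[length(iea_i)]]]
    if (el(iea, 2) != el(isa, 13)) {
      add(iea$index, "ENV-002", "ERROR",
          sprintf("IEA02 '%s' does not repeat ISA13 '%s'",
                  el(iea, 2), el(isa, 13)))
    }
    n_groups <- sum(tags == "GS")
    if (suppressWarnings(as.integer(el(iea, 1))) %in% n_groups == FALSE) {
      add(iea$index, "ENV-005", "ERROR",
          sprintf("IEA01 says %s group(s), counted %d", el(iea, 1), n_groups))
    }
  }
  gs_i <- which(tags == "GS"); ge_i <- which(tags == "GE")
  if (length(gs_i) != length(ge_i)) {
    add(if (length(gs_i)) gs_i[1] else 0L, "ENV-003", "ERROR",
        sprintf("%d GS segment(s) but %d GE trailer(s)",
                length(gs_i), length(ge_i)))
  } else if (length(gs_i)) {
    for (k in seq_along(gs_i)) {
      gs <- segs[[gs_i[k]]]; ge <- segs[[ge_i[k]]]
      if (el(gs, 6) != el(ge, 2)) {
        add(ge$index, "ENV-003", "ERROR",
            sprintf("GE02 '%s' does not repeat GS06 '%s'",
                    el(ge, 2), el(gs, 6)))
      }
      n_st <- sum(tags == "ST")
      if (suppressWarnings(as.integer(el(ge, 1))) %in% n_st == FALSE) {
        add(ge$index, "ENV-004", "ERROR",
            sprintf("GE01 says %s transaction(s), counted %d", el(ge, 1), n_st))
      }
    }
  }

  st_i <- which(tags == "ST"); se_i <- which(tags == "SE")
  if (length(st_i) != length(se_i)) {
    add(if (length(st_i)) st_i[1] else 0L, "ENV-006", "ERROR",
        sprintf("%d ST segment(s) but %d SE trailer(s)",
                length(st_i), length(se_i)))
  }

  # --- per-transaction checks ---------------------------------------------
  n_tx <- min(length(st_i), length(se_i))
  for (k in seq_len(n_tx)) {
    lo <- st_i[k]; hi <- se_i[k]
    st <- segs[[lo]]; se <- segs[[hi]]
    if (hi < lo) {
      add(hi, "ENV-006", "ERROR", "SE trailer precedes its ST header")
      next
    }
    if (el(se, 2) != el(st, 2)) {
      add(se$index, "ENV-006", "ERROR",
          sprintf("SE02 '%s' does not repeat ST02 '%s'", el(se, 2), el(st, 2)))
    }
    n_actual <- hi - lo + 1L
    n_claimed <- suppressWarnings(as.integer(el(se, 1)))
    if (is.na(n_claimed) || n_claimed != n_actual) {
      add(se$index, "ENV-007", "ERROR",
          sprintf("SE01 says %s segments, counted %d from ST through SE",
                  el(se, 1), n_actual))
    }

    body <- segs[lo:hi]
    btags <- vapply(body, function(s) s$tag, character(1))
    pos <- function(p) if (length(p)) p[1] else NA_integer_
    first_at <- function(pred) pos(which(pred))

    p_bht <- first_at(btags == "BHT")
    p_85  <- first_at(btags == "NM1" &
                        vapply(body, function(s) el(s, 1) == "85", logical(1)))
    p_sbr <- first_at(btags == "SBR")
    p_il  <- first_at(btags == "NM1" &
                        vapply(body, function(s) el(s, 1) == "IL", logical(1)))
    p_clm <- first_at(btags == "CLM")
    p_hi  <- first_at(btags == "HI")
    p_lx  <- first_at(btags == "LX")

    seq_chain <- list(
      c("BHT", p_bht), c("2000A billing provider (NM1*85)", p_85),
      c("2000B subscriber (SBR)", p_sbr), c("2300 claim (CLM)", p_clm),
      c("2400 service line (LX)", p_lx)
    )
    last_pos <- 1L; last_name <- "ST"
    for (step in seq_chain) {
      p <- suppressWarnings(as.integer(step[2]))
      if (!is.na(p)) {
        if (p < last_pos) {
          add(lo + p - 1L, "SEQ-001", "ERROR",
              sprintf("%s appears before %s", step[1], last_name))
        } else {
          last_pos <- p; last_name <- step[1]
        }
      }
    }

    # loop completeness
    if (is.na(p_85)) {
      add(st$index, "LOOP-001", "ERROR",
          "2000A loop incomplete: no billing provider NM1*85")
    } else {
      after85 <- btags[(p_85 + 1L):min(length(btags), p_85 + 6L)]
      if (!"N3" %in% after85 || !"N4" %in% after85) {
        add(lo + p_85 - 1L, "LOOP-001", "ERROR",
            "2000A loop incomplete: NM1*85 not followed by N3 and N4")
      }
    }
    if (is.na(p_sbr)) {
      add(st$index, "LOOP-002", "ERROR", "2000B loop incomplete: no SBR")
    } else if (is.na(p_il) || p_il < p_sbr) {
      add(lo + p_sbr - 1L, "LOOP-002", "ERROR",
          "2000B loop incomplete: SBR without a following NM1*IL")
    }
    if (!is.na(p_hi) && is.na(p_clm)) {
      add(lo + p_hi - 1L, "LOOP-003", "ERROR", "HI diagnoses without a CLM")
    } else if (!is.na(p_hi) && p_hi < p_clm) {
      add(lo + p_hi - 1L, "LOOP-003", "ERROR", "HI diagnoses precede CLM")
    } else if (!is.na(p_clm) && is.na(p_hi)) {
      add(lo + p_clm - 1L, "LOOP-003", "ERROR", "CLM without HI diagnoses")
    }

    # service-line loops: LX numbering, SV2 adjacency, pointer range
    n_dx <- 0L
    for (s in body) {
      if (s$tag == "HI") {
        n_dx <- n_dx + sum(vapply(s$elements, function(v)
          length(components(v, d)) >= 2L, logical(1)))
      }
    }
    lx_pos <- which(btags == "LX")
    lx_nums <- vapply(body[lx_pos], function(s)
      suppressWarnings(as.integer(el(s, 1))), integer(1))
    if (length(lx_nums) && !identical(lx_nums, seq_along(lx_nums))) {
      bad <- which(is.na(lx_nums) | lx_nums != seq_along(lx_nums))[1]
      add(lo + lx_pos[bad] - 1L, "SEQ-002", "ERROR",
          sprintf("LX numbering not consecutive: expected %d, found %s",
                  bad, lx_nums[bad]))
    }
    for (p in which(btags == "SV2")) {
      if (p == 1L || btags[p - 1L] != "LX") {
        add(lo + p - 1L, "SEQ-003", "ERROR",
            "SV2 does not directly follow its LX")
      }
      ptr_raw <- el(body[[p]], 7)
      if (nzchar(ptr_raw)) {
        ptrs <- suppressWarnings(as.integer(components(ptr_raw, d)))
        bad <- is.na(ptrs) | ptrs < 1L | ptrs > n_dx
        if (any(bad)) {
          add(lo + p - 1L, "PTR-001", "ERROR",
              sprintf("diagnosis pointer(s) %s outside [1, %d]",
                      paste(components(ptr_raw, d)[bad], collapse = ", "),
                      n_dx))
        }
      }
    }
    for (p in lx_pos) {
      if (p == length(btags) || btags[p + 1L] != "SV2") {
        add(lo + p - 1L, "LOOP-004", "ERROR", "LX without a following SV2")
      }
    }
  }

  done()
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d error(s), %d warning(s)\n",
              x$error_count, x$warning_count))
  if (nrow(x$findings)) {
    for (i in seq_len(nrow(x$findings))) {
      f <- x$findings[i, ]
      cat(sprintf("  [%s] %s at segment %d: %s\n",
                  f$severity, f$rule_code, f$segment_index, f$message))
    }
  } else {
    cat("  clean: no findings\n")
  }
  invisible(x)
}

#' Write a validation report as CSV
#'
#' @param report A [validate_structure()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  utils::write.table(report$findings, path, sep = ",", row.names = FALSE,
                     quote = 4L, qmethod = "double", fileEncoding = "UTF-8")
  invisible(path)
}
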