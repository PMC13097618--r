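test_that("delimiters are detected from the fixed-width ISA header", {
  txt <- serialize_interchange(worked_example_claim())
  expect_identical(nchar(x12_lines(txt)[1]), 106L)
  d <- detect_delimiters(txt)
  expect_identical(d$element_sep, "*")
  expect_identical(d$component_sep, ":")
  expect_identical(d$repetition_sep, "^")
  expect_identical(d$segment_term, "~")

  alt <- serialize_interchange(worked_example_claim(),
                               delimiters = delimiter_set("|", ">", "!", "$"))
  d2 <- detect_delimiters(alt)
  expect_identical(d2$element_sep, "|")
  expect_identical(d2$segment_term, "$")

  expect_error(detect_delimiters("GS*HC*X~"), class = "x12_parse_error")
  expect_error(detect_delimiters(substr(txt, 1, 50)), class = "x12_parse_error")
  clash <- txt
  substr(clash, 106, 106) <- "*"  # terminator collides with element separator
  expect_error(detect_delimiters(clash), class = "x12_parse_error")
})

test_that("SE01 equals the independently counted transaction length", {
  bundle <- test_bundle()
  txt <- serialize_interchange(worked_example_claim())
  lines <- x12_lines(txt)
  se <- lines[startsWith(lines, "SE*")]
  claimed <- as.integer(strsplit(se, "*", fixed = TRUE)[[1]][2])
  expect_identical(claimed, oracle_transaction_counts(txt))

  for (seed in 1:5) {
    cfg <- generator_config(n_claims = 4, seed = seed)
    gtxt <- generate_interchange(cfg, bundle)
    glines <- x12_lines(gtxt)
    claimed <- vapply(glines[startsWith(glines, "SE*")], function(l)
      as.integer(strsplit(l, "*", fixed = TRUE)[[1]][2]), 0L,
      USE.NAMES = FALSE)
    expect_identical(claimed, oracle_transaction_counts(gtxt))
  }
})

test_that("the worked example round-trips to its tabulated relational rows", {
  parsed <- parse_interchange(serialize_interchange(worked_example_claim()))

  h <- parsed$header_rows
  expect_identical(nrow(h), 1L)
  expect_identical(h$transaction_set_id, "837")
  expect_identical(h$control_number, "44146")
  expect_identical(h$billing_provider, "HSA GLENWOOD, LLC")
  expect_identical(h$provider_npi, "1548083421")
  expect_identical(h$provider_city, "GLENDALE")
  expect_identical(h$provider_state, "CA")
  expect_identical(h$subscriber_name, "Jonathan Mendez")
  expect_identical(h$subscriber_id, "3191511")

  dx <- parsed$diagnosis_rows
  expect_identical(dx$claim_id, rep("4742333269", 6))
  expect_identical(dx$diagnosis_type, rep("ABK", 6))
  expect_identical(dx$diagnosis_code,
                   c("T82330A", "S62665A", "Z13811", "S72141Q", "S61431A",
                     "H61301"))
  expect_identical(dx$pointer, 1:6)

  sl <- parsed$service_line_rows
  expect_identical(sl$line_number, 1:3)
  expect_identical(sl$procedure_code, c("HC:97605", "HC:67228", "HC:92316"))
  expect_identical(sl$charge, c("76", "33", "107"))
  expect_identical(sl$unit, rep("UN", 3))
  expect_identical(sl$qty, rep(1L, 3))
  expect_identical(sl$diagnosis_pointers, c("[1]", "[2, 4, 6]", "[6]"))
  expect_identical(sl$service_date, rep("20180428", 3))
})

test_that("random claims round-trip exactly, under default and alternate delimiters", {
  bundle <- test_bundle()
  delim_sets <- list(delimiter_set(), delimiter_set(element_sep = "|",
                                                    segment_term = "!"))
  for (d in delim_sets) {
    cfg <- generator_config(n_claims = 25, seed = 31)
    claims <- generate_batch(cfg, bundle)
    parsed <- parse_interchange(serialize_interchange(claims, envelope_meta(), d))
    expect_length(parsed$claims, 25)
    for (i in seq_along(claims)) {
      orig <- claims[[i]]; got <- parsed$claims[[i]]
      expect_identical(got$claim_id, orig$claim_id)
      expect_identical(got$provider$npi, orig$provider$npi)
      expect_identical(got$diagnoses$code,
                       vapply(orig$diagnoses, `[[`, "", "code"))
      expect_identical(got$diagnoses$qualifier,
                       vapply(orig$diagnoses, `[[`, "", "qualifier"))
      expect_identical(got$diagnoses$poa,
                       vapply(orig$diagnoses, `[[`, "", "poa"))
      expect_identical(got$diagnoses$ordinal,
                       vapply(orig$diagnoses, `[[`, 0L, "ordinal"))
      expect_identical(got$service_lines$line_number,
                       vapply(orig$service_lines, `[[`, 0L, "line_number"))
      expect_identical(got$service_lines$procedure_code,
                       vapply(orig$service_lines, `[[`, "", "procedure_code"))
      expect_identical(got$service_lines$charge,
                       vapply(orig$service_lines, `[[`, 0, "charge"))
      expect_identical(got$service_lines$diagnosis_pointers,
                       lapply(orig$service_lines, `[[`, "diagnosis_pointers"))
      expect_identical(got$service_lines$service_date,
                       vapply(orig$service_lines, function(l)
                         format(l$service_date, "%Y%m%d"), ""))
    }
  }
})

test_that("parsing is strict about envelope arithmetic", {
  txt <- serialize_interchange(worked_example_claim())
  expect_identical(length(parse_interchange(serialize_interchange(
    generate_batch(generator_config(n_claims = 5, seed = 2), test_bundle())
  ))$claims), 5L)

  truncated <- x12_unlines(head(x12_lines(txt), -1))
  expect_error(parse_interchange(truncated), "unterminated interchange",
               class = "x12_parse_error")

  off_by_one <- mutate_element(txt, "SE", 1, "29")
  expect_error(parse_interchange(off_by_one), "SE count",
               class = "x12_parse_error")

  no_se <- drop_segment(txt, "SE*")
  expect_error(parse_interchange(no_se), class = "x12_parse_error")
})

test_that("serialization refuses empty batches and invalid claims", {
  expect_error(serialize_interchange(list()), class = "x12_input_error")
  bad <- worked_example_claim()
  bad$service_lines[[2]]$diagnosis_pointers <- c(7L, 9L)
  expect_error(serialize_interchange(bad), "pointer", class = "x12_input_error")
})

test_that("CSV outputs carry the documented columns and renderings", {
  parsed <- parse_interchange(serialize_interchange(worked_example_claim()))
  outdir <- withr::local_tempdir()
  paths <- write_csv_outputs(parsed, file.path(outdir, "csv"))
  expect_true(all(file.exists(paths)))

  sl_lines <- readLines(paths[["service_lines"]])
  expect_identical(sl_lines[2], '4742333269,1,HC:97605,76,UN,1,"[1]",20180428')
  expect_identical(sl_lines[3],
                   '4742333269,2,HC:67228,33,UN,1,"[2, 4, 6]",20180428')

  header <- read.csv(paths[["header"]], colClasses = "character")
  expect_identical(names(header),
                   c("transaction_set_id", "control_number", "isa_sender",
                     "isa_receiver", "gs_control_number", "bht_reference",
                     "billing_provider", "provider_npi", "provider_city",
                     "provider_state", "subscriber_name", "subscriber_id"))
  expect_identical(header$subscriber_name, "Jonathan Mendez")
  expect_identical(header$billing_provider, "HSA GLENWOOD, LLC")

  dx <- read.csv(paths[["diagnoses"]], colClasses = "character")
  expect_identical(names(dx),
                   c("claim_id", "diagnosis_type", "diagnosis_code", "pointer"))
  expect_identical(nrow(dx), 6L)
})
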