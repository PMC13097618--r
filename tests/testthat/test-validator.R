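test_that("validator is clean on serializer output across a seed sweep", {
  bundle <- test_bundle()
  txt <- serialize_interchange(worked_example_claim())
  expect_identical(validate_structure(txt)$error_count, 0L)
  for (seed in 1:8) {
    cfg <- generator_config(n_claims = 5, seed = seed)
    rep <- validate_structure(generate_interchange(cfg, bundle))
    expect_identical(rep$error_count, 0L)
  }
})

test_that("each documented structural mutation triggers its rule code", {
  txt <- serialize_interchange(worked_example_claim())
  clash <- txt
  substr(clash, 105, 105) <- "*"  # ISA16 component sep collides with element sep

  mutations <- list(
    list(name = "drop provider N3",        rule = "LOOP-001",
         mutated = drop_segment(txt, "N3*")),
    list(name = "drop subscriber NM1*IL",  rule = "LOOP-002",
         mutated = drop_segment(txt, "NM1*IL*")),
    list(name = "drop CLM",                rule = "LOOP-003",
         mutated = drop_segment(txt, "CLM*")),
    list(name = "drop SV2 of line 2",      rule = "LOOP-004",
         mutated = drop_segment(txt, "SV2*", occurrence = 2)),
    list(name = "SV2 swapped before LX",   rule = "SEQ-003",
         mutated = swap_adjacent(txt, "SV2*")),
    list(name = "LX renumbered 1,5,3",     rule = "SEQ-002",
         mutated = sub("LX*2~", "LX*5~", txt, fixed = TRUE)),
    list(name = "SE01 off by one",         rule = "ENV-007",
         mutated = mutate_element(txt, "SE", 1, "29")),
    list(name = "SE dropped",              rule = "ENV-006",
         mutated = drop_segment(txt, "SE*")),
    list(name = "GE dropped",              rule = "ENV-003",
         mutated = drop_segment(txt, "GE*")),
    list(name = "IEA02 corrupted",         rule = "ENV-002",
         mutated = mutate_element(txt, "IEA", 2, "999999999")),
    list(name = "pointer beyond diagnosis count", rule = "PTR-001",
         mutated = mutate_element(txt, "SV2", 7, "9")),
    list(name = "delimiter collision",     rule = "DEL-001",
         mutated = clash)
  )
  for (m in mutations) {
    rep <- validate_structure(m$mutated)
    expect_gte(rep$error_count, 1)
    expect_true(m$rule %in% rep$findings$rule_code,
                label = sprintf("mutation '%s' raised %s (found: %s)",
                                m$name, m$rule,
                                paste(unique(rep$findings$rule_code),
                                      collapse = ", ")))
  }
})

test_that("SE01 mismatch findings name expected and counted totals", {
  txt <- serialize_interchange(worked_example_claim())
  rep <- validate_structure(mutate_element(txt, "SE", 1, "29"))
  f <- rep$findings[rep$findings$rule_code == "ENV-007", ]
  expect_identical(nrow(f), 1L)
  expect_match(f$message, "29")
  expect_match(f$message, as.character(oracle_transaction_counts(txt)))
})

test_that("reports tally severities exactly and sort findings by segment", {
  txt <- serialize_interchange(worked_example_claim())
  lines <- x12_lines(txt)
  # inject an unknown segment (warning) plus a pointer fault (error)
  lines <- append(lines, "ZZZ*1~", after = which(startsWith(lines, "CLM*")))
  broken <- mutate_element(x12_unlines(lines), "SV2", 7, "9")
  rep <- validate_structure(broken)

  expect_identical(rep$error_count,
                   sum(rep$findings$severity == "ERROR"))
  expect_identical(rep$warning_count,
                   sum(rep$findings$severity == "WARNING"))
  expect_gte(rep$warning_count, 1)
  expect_true("UNK-001" %in% rep$findings$rule_code)
  expect_false(is.unsorted(rep$findings$segment_index))

  # report serializes as CSV with the documented columns
  path <- withr::local_tempfile(fileext = ".csv")
  write_validation_report(rep, path)
  csv <- read.csv(path)
  expect_identical(names(csv),
                   c("segment_index", "rule_code", "severity", "message"))
  expect_identical(nrow(csv), nrow(rep$findings))
})

test_that("non-X12 text yields a file-level finding, never an exception", {
  rep <- validate_structure("this is not an interchange")
  expect_identical(rep$error_count, 1L)
  expect_identical(rep$findings$rule_code, "DEL-002")
  expect_identical(rep$findings$segment_index, 0L)
})
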