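test_that("delimiter sets enforce distinctness and payload safety", {
  d <- delimiter_set()
  expect_identical(d$element_sep, "*")
  expect_identical(d$segment_term, "~")
  expect_error(delimiter_set(element_sep = "~"), class = "x12_config_error")
  expect_error(delimiter_set(element_sep = "A"), class = "x12_config_error")
  expect_error(delimiter_set(component_sep = "7"), class = "x12_config_error")
  alt <- delimiter_set(element_sep = "|")
  expect_identical(alt$element_sep, "|")
})

test_that("the worked-example claim carries its tabulated values and is stable", {
  cl <- worked_example_claim()
  expect_identical(cl$provider$npi, "1548083421")
  expect_identical(cl$provider$org_name, "HSA GLENWOOD, LLC")
  expect_identical(cl$provider$city, "GLENDALE")
  expect_identical(cl$provider$state, "CA")
  expect_identical(cl$subscriber$member_id, "3191511")
  expect_identical(cl$claim_id, "4742333269")
  expect_identical(cl$transaction_control_number, "44146")

  expect_length(cl$diagnoses, 6)
  expect_identical(cl$diagnoses[[2]]$code, "S62665A")
  expect_identical(cl$diagnoses[[2]]$ordinal, 2L)
  expect_identical(vapply(cl$diagnoses, `[[`, "", "qualifier"), rep("ABK", 6))

  expect_length(cl$service_lines, 3)
  expect_identical(cl$service_lines[[3]]$charge, 107)
  expect_identical(cl$service_lines[[2]]$diagnosis_pointers, c(2L, 4L, 6L))
  expect_identical(cl$total_charge, 216)
  expect_identical(format(cl$service_lines[[1]]$service_date, "%Y%m%d"),
                   "20180428")

  expect_length(validate_claim(cl), 0)
  expect_identical(worked_example_claim(), worked_example_claim())
})

test_that("claim validation returns complete, named violation lists", {
  cl <- worked_example_claim()

  bad_ptr <- cl
  bad_ptr$service_lines[[3]]$diagnosis_pointers <- 7L
  v <- validate_claim(bad_ptr)
  expect_length(v, 1)
  expect_match(v, "pointer")
  expect_match(v, "7")

  no_lines <- cl
  no_lines$service_lines <- list()
  no_lines$total_charge <- 0
  expect_match(validate_claim(no_lines), "service lines", all = FALSE)

  wrong_total <- cl
  wrong_total$total_charge <- 999
  expect_match(validate_claim(wrong_total), "total charge", all = FALSE)

  gap_ord <- cl
  gap_ord$diagnoses[[3]]$ordinal <- 9L
  expect_match(validate_claim(gap_ord), "consecutive", all = FALSE)

  bad_npi <- cl
  bad_npi$provider$npi <- "1548083420"
  expect_match(validate_claim(bad_npi), "Luhn", all = FALSE)
})

test_that("entity constructors reject out-of-range fields", {
  expect_error(diagnosis_entry("T82330A", ordinal = 13),
               class = "x12_config_error")
  expect_error(diagnosis_entry("BAD", ordinal = 1), class = "x12_config_error")
  expect_error(diagnosis_entry("T82330A", 1, poa = "X"),
               class = "x12_config_error")
  expect_error(service_line(51, "97605", 10), class = "x12_config_error")
  expect_error(service_line(1, "97605", -1), class = "x12_config_error")
  expect_error(service_line(1, "97605", 10, diagnosis_pointers = 1:5),
               class = "x12_config_error")
  expect_error(service_line(1, "97605", 10, diagnosis_pointers = c(2, 2)),
               class = "x12_config_error")
  expect_error(subscriber("", "Mendez", "3191511", list()),
               class = "x12_config_error")
  expect_error(subscriber("Jon", "Mendez", "1234", list()),
               class = "x12_config_error")
  # pointers are stored sorted even when supplied unsorted
  l <- service_line(1, "97605", 10, diagnosis_pointers = c(6, 2, 4))
  expect_identical(l$diagnosis_pointers, c(2L, 4L, 6L))
})

test_that("generator configuration accepts 1-12 diagnoses and 1-50 lines only", {
  expect_s3_class(generator_config(dx_min = 1, dx_max = 12,
                                   line_min = 1, line_max = 50),
                  "generator_config")
  expect_error(generator_config(dx_max = 13), class = "x12_config_error")
  expect_error(generator_config(dx_min = 0), class = "x12_config_error")
  expect_error(generator_config(line_max = 51), class = "x12_config_error")
  expect_error(generator_config(line_min = 0), class = "x12_config_error")
  expect_error(generator_config(dx_min = 5, dx_max = 2),
               class = "x12_config_error")
  expect_error(generator_config(n_claims = 0), class = "x12_config_error")
  expect_error(generator_config(max_pointers_per_line = 5),
               class = "x12_config_error")
})
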