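Package: x12claims
Title: Synthetic X12 837i Institutional Claims: Generation, Parsing, and
    Structural Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates fully synthetic X12 5010 837 institutional (837i)
    health-care claim files for education and testing, parses 837i text into
    three relational CSV tables (headers, diagnoses, service lines), and
    validates envelope structure, loop hierarchy, segment sequencing and
    diagnosis-pointer linkage. Claims are built from packaged,
    nonidentifiable synthetic reference tables (ICD-10-CM and HCPCS shaped
    code sets, Luhn-valid provider NPIs, payer products with HIOS IDs); no
    patient-level data are ingested or produced. All randomness is seed
    deterministic, so identical configurations yield byte-identical files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
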