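# x12claims

Synthetic X12 5010 **837 institutional (837i)** health-care claims for
education and testing: a seed-deterministic **generator**, an EDI →
relational-CSV **parser**, and a structural **validator**, in one R
package with a small command-line front end.

Real claims data cannot be used in classrooms or shared test suites, yet
revenue-cycle, coding, and health-data-analyst roles all require
fluency with raw 837i files. `x12claims` closes that gap: it builds
structurally authentic claim files — proper ISA/GS/ST envelopes, the
2000A (billing provider) / 2000B (subscriber) / 2300 (claim) / 2400
(service line) loop hierarchy, present-on-admission indicators, and
diagnosis pointers linking each service line to the diagnoses that
justify it — from packaged, nonidentifiable synthetic reference tables.
No patient-level data are ingested or produced; every identity is
generated de novo from the seed.

At the core:

* **Claim model.** A claim carries 1–12 ordered diagnoses (ordinal 1 =
  principal, qualifier `ABK`; others `ABF`) and 1–50 numbered service
  lines, each with 1–4 distinct *diagnosis pointers* into the diagnosis
  ordinals, a HCPCS procedure code, revenue code, and charge; the claim
  total is the exact sum of line charges.
* **NPI check.** Provider identifiers satisfy the NPI Luhn rule: the
  10th digit is the Luhn check digit of `80840` + the first nine digits.
* **Envelope arithmetic.** SE01 equals the transaction's segment count
  (ST through SE inclusive); GE01 the transaction count; IEA01 the group
  count; trailer control numbers repeat their headers.

## Worked example

```r
library(x12claims)

claim <- worked_example_claim()
claim
#> <institutional_claim> 4742333269
#>   billing provider: HSA GLENWOOD, LLC (NPI 1548083421), GLENDALE CA
#>   subscriber: Jonathan Mendez (ID 3191511)
#>   6 diagnoses, 3 service lines, total charge 216

txt <- serialize_interchange(claim)
cat(substr(txt, 1, 236))
#> ISA*00*          *00*          *ZZ*SYNTHSENDER    *ZZ*SYNTHRECVR     *240601*0830*^*00501*000044146*0*T*:~
#> GS*HC*SYNTHSENDER*SYNTHRECVR*20240601*0830*1*X*005010X223A2~
#> ST*837*44146*005010X223A2~
#> BHT*0019*00*4742333269*20240601*0830*CH~

parsed <- parse_interchange(txt)
write_csv_outputs(parsed, "csv")
readLines("csv/service_lines.csv")[2:4]
#> [1] "4742333269,1,HC:97605,76,UN,1,\"[1]\",20180428"
#> [2] "4742333269,2,HC:67228,33,UN,1,\"[2, 4, 6]\",20180428"
#> [3] "4742333269,3,HC:92316,107,UN,1,\"[6]\",20180428"

validate_structure(txt)
#> <validation_report> 0 error(s), 0 warning(s)
#>   clean: no findings
```

Line 2 (procedure `HC:67228`, charge 33) is justified by diagnoses 2, 4,
and 6 via its pointers — the linkage students cross-reference between
`service_lines.csv` and `diagnoses.csv` when learning adjudication
logic.

Random generation is fully seed-deterministic:

```r
bundle <- load_reference_bundle()
cfg <- generator_config(n_claims = 5, dx_min = 1, dx_max = 12,
                        line_min = 1, line_max = 50, seed = 42)
identical(generate_interchange(cfg, bundle),
          generate_interchange(cfg, bundle))
#> [1] TRUE
```

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("scripts", "x12claims", package = "x12claims"))')
Rscript $CLI generate --count 5 --seed 1 --out claims.txt
Rscript $CLI parse    --in claims.txt --outdir csv/
Rscript $CLI validate --in claims.txt --report findings.csv
```

Exit codes: 0 success/valid, 1 runtime or validation failure, 2 usage
error. `--profile web` mirrors an interactive session and caps `--count`
at 25; `--profile batch` (default) is uncapped. `--config FILE` supplies
`key=value` defaults that explicit flags override.

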