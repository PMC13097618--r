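---
title: "Synthetic 837i claims: model, file dialect, and validation rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic 837i claims: model, file dialect, and validation rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(x12claims)
```

## Why synthetic claims

Institutional health-care claims travel as X12 837i EDI transactions, but
privacy rules keep real claim files out of classrooms and test suites.
`x12claims` produces files that are structurally authentic — correct
envelopes, loop hierarchy, diagnosis-pointer linkage — while containing
zero protected health information: every patient-facing value (names,
member IDs, claim numbers, dates) is drawn de novo from a seeded random
stream, and the only real-world-shaped inputs are nonidentifiable code
sets and organization-level directories.

## The claim model

An institutional claim here is:

* a **billing provider** (2000A loop): organization name, a 10-digit NPI
  whose last digit is a Luhn check digit over `80840` plus the first nine
  digits, and an address;
* a **subscriber** (2000B loop): a generated identity with a 5–9 digit
  member ID and a payer product identified by a 5-digit HIOS issuer ID;
* a **claim loop** (2300): claim ID, total charge (always the exact sum
  of line charges), facility type and frequency codes, and an ordered
  list of 1–12 diagnoses. Diagnosis 1 is the principal diagnosis; each
  diagnosis carries a present-on-admission indicator;
* **service lines** (2400 loops): 1–50 lines numbered consecutively from
  1, each with a revenue code, an HCPCS procedure code, a charge, a unit
  count, a service date, and 1–4 *diagnosis pointers* — integers that
  reference diagnosis ordinals and justify the billed procedure.

`validate_claim()` re-checks all cross-field invariants and returns the
violations as messages rather than raising, so a defective object yields
a complete report.

### Diagnosis qualifiers: ABK vs ABF

X12 convention marks the principal diagnosis `ABK` and the remaining
diagnoses `ABF`. The generator follows that convention. The fixed
`worked_example_claim()` fixture instead stores `ABK` on all six of its
diagnoses, exactly as that example is conventionally tabulated; the codec
is deliberately agnostic — it serializes whatever qualifier each entry
carries and the parser reproduces the file's qualifiers verbatim. This
keeps parse output faithful to hand-edited classroom files rather than
silently "correcting" them.

## The generator's defaults and what they emulate

`generator_config()` fixes the study conditions:

* diagnosis counts uniform on `[dx_min, dx_max]` within the hard 1–12
  bound; line counts uniform on `[line_min, line_max]` within 1–50.
  Values outside those bounds are rejected before any sampling;
* line 1 always points at the principal diagnosis; later lines draw 1–4
  distinct pointers uniformly;
* charges are whole dollars, log-uniform on \[10, 5000\]: a heavy mass of
  small charges with occasional large facility charges. Unit quantity is
  always 1. Neither choice models any observed charge distribution — they
  are plain, documented defaults;
* all lines of one claim share one service date, drawn uniformly from
  `service_year_range` (default 2018–2024);
* subscriber names come from a packaged ~60×60 first/last-name lexicon;
  present-on-admission indicators favor `Y` with occasional
  `N`/`U`/`W`/`1`;
* identifier widths default to a 10-digit claim ID and 7-digit member ID
  (both configurable).

Reproducibility is strict: `generate_batch()` seeds R's RNG from
`config$seed` (restoring the caller's RNG state afterwards), and the
envelope timestamps default to fixed constants rather than the wall
clock, so one configuration always produces byte-identical files. The
CLI's *web* profile caps a session at 25 claims — an interface preset,
not a library limit; the *batch* profile is uncapped.

The packaged reference bundle is a small synthetic stand-in (~200
ICD-10-CM-shaped diagnosis codes, 50 HCPCS-shaped procedure codes, 50
provider organizations with synthetic Luhn-valid NPIs, 10 payer
products, 10 revenue codes). It keeps the package self-contained and
testable offline; `load_reference_bundle(path)` accepts a directory of
full-size tables with the same columns. Sampling is uniform and
independent across tables — no diagnosis–procedure category pairing is
modeled, so generated claims are structurally but not clinically
coherent. Passing tests therefore demonstrate format fidelity, not
clinical plausibility, and none of the erratic human error found in
production files.

## The file dialect

Serialization is bit-exact in its constants: a 106-character fixed-width
ISA header (`ISA12 = 00501`), `GS01 = HC`, implementation convention
reference `005010X223A2` on GS08 and ST03, `ST01 = 837`, `BHT01 = 0019`.
Default delimiters are `*` (element), `:` (component), `^` (repetition),
`~` (terminator), with one segment per line for readability
(`newline = FALSE` streams without newlines). Delimiters are
parametric — `delimiter_set()` accepts any four distinct characters that
are not digits or uppercase letters — and the parser re-detects them
from the ISA header's fixed offsets.

Two deliberate dialect choices:

* **Diagnosis pointers on SV2.** The standard institutional service line
  has no pointer element, but the relational outputs carry per-line
  pointers, so the serializer writes them as a component-separated
  composite in SV2 element 7 (leaving SV206 empty) and the parser reads
  the same position. This is a documented deviation from the bare
  implementation guide.
* **HI packing.** The principal diagnosis occupies its own HI segment;
  the remaining diagnoses (up to 11 composites) share a second HI. Each
  composite is `qualifier:code:::::::poa` — POA in the ninth component.

`HL` segments mark the 2000A/2000B hierarchy. A `DMG` segment carries
the subscriber's birth date and gender so a parse loses nothing the
model holds.

## Parsing and the three CSV tables

`parse_interchange()` is permissive about unknown segments (kept in the
segment list, ignored for the tables) but strict about envelope
arithmetic: every ST needs its SE, SE01 must equal the counted segment
total, and a missing IEA is an "unterminated interchange" error. The
three projections mirror relational claims data:

* `header.csv` — one row per claim: transaction metadata, billing
  provider, subscriber;
* `diagnoses.csv` — one row per diagnosis: claim ID, qualifier, code,
  pointer ordinal;
* `service_lines.csv` — one row per line: qualifier-prefixed procedure
  code (`HC:97605`), charge, unit, quantity, bracketed pointer list
  (`[2, 4, 6]`), service date.

Charges render without a trailing `.00` when integral, matching how
whole-dollar amounts appear in the tables.

## The validator's rule catalog

`validate_structure()` accepts any text and never raises; it collects
every finding (sorted by segment index) so a report lists all defects in
a hand-edited file. Rules fall into five families:

| family | checks |
|--------|--------|
| `DEL`  | fixed-width ISA present; four distinct delimiters |
| `ENV`  | ISA/IEA, GS/GE, ST/SE pairing; trailer control numbers repeat headers; GE01/IEA01/SE01 arithmetic |
| `SEQ`  | section order ST < BHT < 2000A < 2000B < 2300 < 2400; LX numbered consecutively from 1; SV2 directly after its LX |
| `LOOP` | NM1\*85 with N3/N4; SBR with NM1\*IL; CLM paired with HI |
| `PTR`  | every service-line pointer within `[1, #diagnoses]` (ERROR severity — pointer linkage is core adjudication logic) |

Unknown segment tags are WARNING-level (`UNK-001`). Code-set membership
is out of scope: codes are checked for shape, not against any annual
release, and no equivalence with commercial EDI validators is claimed.

```{r}
txt <- serialize_interchange(worked_example_claim())
validate_structure(txt)
broken <- sub("LX*2~", "LX*7~", txt, fixed = TRUE)
validate_structure(broken)
```

## Verification strategy and problem sizes

The test suite checks the NPI check digit against an independent
table-driven Luhn oracle (200 random NPIs plus fixed cases), SE01
against an independent line-count oracle, pointer draws over 10,000
samples, claim validity over 150 full-complexity generations, round-trip
exactness over 500 random claims under two delimiter sets, validator
cleanliness over a 1,000-claim seed sweep, and sensitivity to ten
single-segment corruptions. Those sizes keep the full suite under a
minute on one CPU while making coverage failures (a provider never
sampled, a pointer subset never drawn) astronomically unlikely.

## Known limitations

* Structural realism only: no clinical code pairing, no payer-specific
  adjudication, no intentional error injection, no longitudinal patient
  history.
* 837i only — no professional (837p) or remittance (835) transactions;
  repetition-separator payloads are not used.
* The segment inventory is the minimal set the loop hierarchy implies
  (plus `HL`, `DMG`, `REF`); production files from other systems may
  carry additional segments, which parse as preserved-but-ignored and
  validate as warnings.
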