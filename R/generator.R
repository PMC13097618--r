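# Random claim generation. Everything flows from one seed: generate_batch()
# seeds the RNG locally (restoring the caller's stream afterwards) and all
# sampling — identities, codes, charges, dates, pointers — draws from it.

# Packaged name lexicon for de-novo subscriber identities; no external name
# service, no real person lists.
FIRST_NAMES <- c(
  "Jonathan", "Maria", "David", "Aisha", "Carlos", "Emily", "Wei", "Fatima",
  "Michael", "Sofia", "James", "Priya", "Robert", "Hannah", "Luis", "Grace",
  "Thomas", "Amara", "Daniel", "Olivia", "Kevin", "Nadia", "Brian", "Elena",
  "Marcus", "Leila", "Andre", "Chloe", "Victor", "Ingrid", "Samuel", "Rosa",
  "Peter", "Yuki", "Omar", "Clara", "Felix", "Naomi", "Hector", "Ivy",
  "George", "Tara", "Dmitri", "Alice", "Raj", "Monica", "Sean", "Bianca",
  "Tyler", "Zoe", "Adam", "Ruth", "Noah", "Esther", "Liam", "Paula",
  "Ethan", "Dana", "Oscar", "Mei", "Hugo", "Sara", "Ivan", "Julia"
)
LAST_NAMES <- c(
  "Mendez", "Smith", "Johnson", "Williams", "Brown", "Jones", "Garcia",
  "Miller", "Davis", "Rodriguez", "Martinez", "Hernandez", "Lopez",
  "Gonzalez", "Wilson", "Anderson", "Thomas", "Taylor", "Moore", "Jackson",
  "Martin", "Lee", "Perez", "Thompson", "White", "Harris", "Sanchez",
  "Clark", "Ramirez", "Lewis", "Robinson", "Walker", "Young", "Allen",
  "King", "Wright", "Scott", "Torres", "Nguyen", "Hill", "Flores", "Green",
  "Adams", "Nelson", "Baker", "Hall", "Rivera", "Campbell", "Mitchell",
  "Carter", "Roberts", "Gomez", "Phillips", "Evans", "Turner", "Diaz",
  "Parker", "Cruz", "Edwards", "Collins", "Reyes", "Stewart", "Morris",
  "Morales"
)

# Run expr under a given seed, then restore whatever RNG state the caller
# had (including "no state yet").
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Draw diagnosis pointers for one service line
#'
#' Draws a sorted set of 1 to `max_per_line` distinct pointers, each
#' referencing a diagnosis ordinal in `[1, n_dx]`. These are the links
#' that justify a billed procedure by the diagnoses on the claim.
#'
#' @param n_dx Number of diagnoses on the claim, 1-12.
#' @param max_per_line Maximum pointers on one line, 1-4.
#' @param require_principal If `TRUE`, pointer 1 (the principal diagnosis)
#'   is always included — used for line 1 of generated claims.
#' @return Sorted integer vector of distinct pointers.
#' @examples
#' set.seed(1)
#' assign_diagnosis_pointers(n_dx = 6)
#' @export
assign_diagnosis_pointers <- function(n_dx, max_per_line = 4L,
                                      require_principal = FALSE) {
  if (!is_count(n_dx) || n_dx > 12) {
    abort_config("n_dx must be an integer in [1, 12]")
  }
  if (!is_count(max_per_line) || max_per_line > 4) {
    abort_config("max_per_line must be an integer in [1, 4]")
  }
  k <- runif_int(1L, min(max_per_line, n_dx))
  if (require_principal) {
    extra <- if (k > 1L && n_dx > 1L) resample(2:n_dx, k - 1L) else integer()
    sort(unique(c(1L, extra)))
  } else {
    sort(resample(seq_len(n_dx), k))
  }
}

generate_subscriber <- function(bundle, member_id_width) {
  payer <- sample_payer(bundle)
  first <- resample(FIRST_NAMES)
  last <- resample(LAST_NAMES)
  member_id <- random_digits(member_id_width, first_nonzero = TRUE)
  birth <- as.Date("1940-01-01") + runif_int(0L, 23740L)  # up to ~2004-12-31
  gender <- resample(c("M", "F", "U"))
  subscriber(first, last, member_id, payer, birth_date = birth, gender = gender)
}

# Whole-dollar charges, log-uniform on [10, 5000]: small office-level
# charges are common, large facility charges rare but present.
generate_charge <- function() {
  round(exp(stats::runif(1, log(10), log(5000))))
}

generate_service_date <- function(year_range) {
  lo <- as.Date(sprintf("%d-01-01", year_range[1]))
  hi <- as.Date(sprintf("%d-12-31", year_range[2]))
  lo + runif_int(0L, as.integer(hi - lo))
}

#' Generate one random institutional claim
#'
#' Draws provider, payer, subscriber identity, diagnosis set, and service
#' lines from the current RNG stream under the configuration's bounds.
#' Diagnosis and line counts are uniform on `[dx_min, dx_max]` and
#' `[line_min, line_max]`. All lines of a claim share one service date;
#' line 1 always points at the principal diagnosis. The result always
#' satisfies [validate_claim()].
#'
#' @param config A [generator_config()].
#' @param bundle A [load_reference_bundle()] result.
#' @param transaction_control_number Control number for the claim's
#'   transaction (assigned sequentially by [generate_batch()]).
#' @return An [institutional_claim()].
#' @export
generate_claim <- function(config, bundle, transaction_control_number = "0001") {
  stopifnot(inherits(config, "generator_config"),
            inherits(bundle, "reference_bundle"))
  n_dx <- runif_int(config$dx_min, config$dx_max)
  n_ln <- runif_int(config$line_min, config$line_max)

  provider <- sample_provider(bundle)
  sub <- generate_subscriber(bundle, config$member_id_width)
  dx_codes <- sample_diagnosis_set(bundle, n_dx)
  diagnoses <- lapply(seq_len(n_dx), function(i) {
    diagnosis_entry(dx_codes[i], ordinal = i,
                    poa = resample(c("Y", "Y", "Y", "N", "U", "W", "1")))
  })

  svc_date <- generate_service_date(config$service_year_range)
  lines <- lapply(seq_len(n_ln), function(i) {
    service_line(
      line_number = i,
      procedure_code = sample_procedure(bundle),
      charge = generate_charge(),
      quantity = 1L,
      diagnosis_pointers = assign_diagnosis_pointers(
        n_dx, config$max_pointers_per_line, require_principal = (i == 1L)),
      service_date = svc_date,
      revenue_code = resample(bundle$revenue_codes)
    )
  })

  institutional_claim(
    claim_id = random_digits(config$claim_id_width, first_nonzero = TRUE),
    transaction_control_number = transaction_control_number,
    provider = provider, subscriber = sub,
    diagnoses = diagnoses, service_lines = lines
  )
}

#' Generate a batch of claims
#'
#' Seeds the RNG from `config$seed` (restoring the caller's RNG state on
#' exit) and generates exactly `n_claims` claims with unique claim IDs and
#' sequential transaction control numbers. Identical configurations yield
#' identical batches, byte for byte once serialized.
#'
#' @inheritParams generate_claim
#' @return List of [institutional_claim()] objects, length
#'   `config$n_claims`.
#' @examples
#' bundle <- load_reference_bundle()
#' claims <- generate_batch(generator_config(n_claims = 3, seed = 7), bundle)
#' length(claims)
#' @export
generate_batch <- function(config, bundle) {
  stopifnot(inherits(config, "generator_config"),
            inherits(bundle, "reference_bundle"))
  with_seed(config$seed, {
    seen_ids <- character()
    lapply(seq_len(config$n_claims), function(i) {
      cl <- generate_claim(config, bundle, sprintf("%04d", i))
      while (cl$claim_id %in% seen_ids) {
        cl$claim_id <- random_digits(config$claim_id_width, first_nonzero = TRUE)
      }
      seen_ids <<- c(seen_ids, cl$claim_id)
      cl
    })
  })
}

#' Generate a batch and serialize it as one 837i interchange
#'
#' Convenience wrapper: [generate_batch()] then [serialize_interchange()]
#' with a deterministic envelope (interchange control number drawn from the
#' same seeded stream; fixed default timestamps so repeated runs are
#' byte-identical).
#'
#' @inheritParams generate_claim
#' @param delimiters A [delimiter_set()].
#' @param newline Insert a newline after each segment terminator (one
#'   segment per line; set `FALSE` for a single-stream file).
#' @return A single string of X12 837i text.
#' @examples
#' bundle <- load_reference_bundle()
#' txt <- generate_interchange(generator_config(n_claims = 1, seed = 1), bundle)
#' substr(txt, 1, 3)
#' @export
generate_interchange <- function(config, bundle, delimiters = delimiter_set(),
                                 newline = TRUE) {
  claims <- generate_batch(config, bundle)
  env <- with_seed(config$seed + 1L, envelope_meta(
    interchange_control_number = random_digits(9L),
    group_control_number = runif_int(1L, 999999L)
  ))
  serialize_interchange(claims, env, delimiters, newline = newline)
}
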