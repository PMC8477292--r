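# Hand-built fixture cohorts and independent label oracles used across the
# suite. Everything is constructed in code; no stored fixtures.

# One record row with sane defaults; counts are derived from the codes.
make_record <- function(record_id, person_id, date, claim_type = "outpatient",
                        codes = "", hospital_stay = 0L,
                        care_site_type = 0L, care_site_specialization = 0L,
                        care_site_rank = 0L, costs = rep(0, 5),
                        dead = FALSE) {
  cnt <- integer(5)
  if (nzchar(codes)) {
    parsed <- parse_codes(codes)
    cnt <- as.integer(table(factor(parsed$category,
                                   levels = code_categories())))
  }
  out <- data.frame(record_id = record_id, person_id = person_id,
                    date = date, claim_type = claim_type, codes = codes,
                    care_site_type = care_site_type,
                    care_site_specialization = care_site_specialization,
                    care_site_rank = care_site_rank,
                    hospital_stay = hospital_stay,
                    stringsAsFactors = FALSE)
  for (i in 1:5) out[[paste0("cost_", c("dx","px","med","test","other")[i])]] <- costs[i]
  for (i in 1:5) out[[paste0("count_", c("dx","px","med","test","other")[i])]] <- cnt[i]
  out$discharge_dead_or_critical <- dead
  out
}

make_persons <- function(ids, gender = "female", birth_year = 1950L) {
  data.frame(person_id = ids, gender = rep_len(gender, length(ids)),
             birth_year = rep_len(birth_year, length(ids)),
             stringsAsFactors = FALSE)
}

# cohort of one person from a list of make_record() rows
one_person_cohort <- function(records, person_id = "p1") {
  cohort(make_persons(person_id), do.call(rbind, records))
}

# Brute-force label oracles: double loop over (record, event) pairs testing
# the inclusive 1..30-day window. Independent of the package's vectorized
# labeling path.
oracle_mortality <- function(records) {
  n <- nrow(records)
  out <- integer(n)
  for (i in seq_len(n)) {
    if (records$discharge_dead_or_critical[i]) { out[i] <- 0L; next }
    for (j in seq_len(n)) {
      if (!records$discharge_dead_or_critical[j]) next
      gap <- records$date[j] - records$date[i]
      if (gap >= 1 && gap <= 30) out[i] <- 1L
    }
  }
  out
}

oracle_readmission <- function(records) {
  n <- nrow(records)
  out <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (records$claim_type[i] != "inpatient") next
    discharge <- records$date[i] + records$hospital_stay[i]
    out[i] <- 0L
    for (j in seq_len(n)) {
      if (j == i || records$claim_type[j] != "inpatient") next
      gap <- records$date[j] - discharge
      if (gap >= 1 && gap <= 30) out[i] <- 1L
    }
  }
  out
}

# small random cohort for property tests
random_cohort <- function(n_persons, seed, ...) {
  generate_cohort(generator_config(n_persons = n_persons, seed = seed, ...))
}

tiny_params <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(visit_embed_size = 12L, rnn_output_size = 8L,
                   code_embed_size = 8L, init_seed = seed)
  do.call(hvec_params, utils::modifyList(defaults, args))
}
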