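# Synthetic claims cohort generator. Emulates the statistical structure the
# model assumes -- persons with a geometric-like number of visits, rare
# cardiac-arrest records, extreme outcome imbalance -- with a single latent
# severity scalar per person linking codes, CA events and outcomes, so that
# learning is detectable downstream.

#' Generator configuration
#'
#' Parameters of the synthetic cohort generator. Defaults reflect the claims
#' cohort the model targets: a mean of 9.3 records per person, cardiac-arrest
#' procedure codes on roughly a tenth of records, and a CA-record mortality
#' rate near 0.53% -- the extreme-imbalance regime.
#'
#' @param n_persons Number of persons to generate.
#' @param mean_records_per_person Mean of the geometric-like per-person
#'   record count (must be >= 1).
#' @param code_vocab_size_per_category Vocabulary size per code category;
#'   the top 20% of each vocabulary is the "severe" sub-vocabulary.
#' @param ca_rate_per_record Baseline probability that a record is a
#'   cardiac-arrest record (log-odds shifted by severity).
#' @param severity_effect Log-odds coefficient of the latent severity scalar
#'   on mortality (and, halved, on readmission). 0 removes the planted
#'   signal.
#' @param base_mortality_rate Per-record probability that the record
#'   triggers a mortality event, at severity 0 for a non-CA record.
#' @param base_readmission_rate Per-discharge probability of a 1--30 day
#'   readmission, at severity 0.
#' @param ca_mortality_target_rate Per-record mortality-trigger probability
#'   for a CA record at severity 0; sets the CA task's imbalance regime.
#' @param inpatient_fraction Fraction of freely scheduled records that are
#'   inpatient.
#' @param mean_gap_days Mean day gap between consecutive records.
#' @param seed Integer seed; generation is a pure function of the full
#'   configuration including the seed.
#' @return A list of class `hvec_generator_config`.
#' @export
generator_config <- function(n_persons,
                             mean_records_per_person = 9.3,
                             code_vocab_size_per_category = 200L,
                             ca_rate_per_record = 0.10,
                             severity_effect = 1.5,
                             base_mortality_rate = 0.004,
                             base_readmission_rate = 0.15,
                             ca_mortality_target_rate = 0.0053,
                             inpatient_fraction = 0.30,
                             mean_gap_days = 30,
                             seed = 1L) {
  cfg <- list(n_persons = as.integer(n_persons),
              mean_records_per_person = mean_records_per_person,
              code_vocab_size_per_category =
                as.integer(code_vocab_size_per_category),
              ca_rate_per_record = ca_rate_per_record,
              severity_effect = severity_effect,
              base_mortality_rate = base_mortality_rate,
              base_readmission_rate = base_readmission_rate,
              ca_mortality_target_rate = ca_mortality_target_rate,
              inpatient_fraction = inpatient_fraction,
              mean_gap_days = mean_gap_days,
              seed = as.integer(seed))
  if (cfg$n_persons < 1L) stop("validation error: n_persons must be >= 1")
  if (cfg$mean_records_per_person < 1) {
    stop("validation error: mean_records_per_person must be >= 1")
  }
  for (p in c("ca_rate_per_record", "base_mortality_rate",
              "base_readmission_rate", "ca_mortality_target_rate",
              "inpatient_fraction")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop("validation error: ", p, " must be a probability in [0,1]")
    }
  }
  if (cfg$severity_effect < 0) {
    stop("validation error: severity_effect must be non-negative")
  }
  class(cfg) <- "hvec_generator_config"
  cfg
}

# Per-record probabilities plogis(a + shift) with the intercept a chosen so
# the mean over the given shifts equals the target rate; reduces to a
# constant rate when all shifts are equal (e.g. severity_effect = 0).
calibrated_rate <- function(target, shift) {
  if (length(shift) == 0L) return(numeric(0))
  if (target <= 0) return(rep(0, length(shift)))
  if (target >= 1) return(rep(1, length(shift)))
  if (diff(range(shift)) < 1e-12) return(rep(target, length(shift)))
  lo <- stats::qlogis(target) - max(shift) - 1
  hi <- stats::qlogis(target) - min(shift) + 1
  a <- stats::uniroot(function(a) mean(stats::plogis(a + shift)) - target,
                      c(lo, hi), tol = 1e-10)$root
  stats::plogis(a + shift)
}

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic claims cohort
#'
#' Draws a cohort from the generative model: each person carries a latent
#' severity `s ~ Normal(0, 1)`; record counts are `1 + Geometric` with the
#' configured mean; codes are drawn per category, with severe-sub-vocabulary
#' draws more likely at high severity; CA records occur with the configured
#' per-record rate, up-weighted by severity, and always carry a CA procedure
#' code on an inpatient record. Each record triggers a mortality event with
#' probability `plogis(qlogis(base) + severity_effect * s + ca_bump * is_ca)`;
#' a triggered event appends a terminal record 1--30 days later flagged
#' `discharge_dead_or_critical` and truncates the sequence. Inpatient
#' discharges draw a 1--30 day readmission with the configured base rate;
#' non-readmission inpatient admissions are scheduled at least 31 days after
#' the previous discharge so labels are exactly the generative draws.
#'
#' @param config A [generator_config()].
#' @return An [cohort()] object.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "hvec_generator_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_persons
  epoch_year <- 2002L
  person_id <- sprintf("p%06d", seq_len(n))
  gender <- ifelse(stats::runif(n) < 0.379, "male", "female")
  age <- pmin(pmax(round(stats::rnorm(n, 68.7, 19)), 0), 110)
  birth_year <- epoch_year - age
  s <- stats::rnorm(n)
  m <- cfg$mean_records_per_person
  n_rec <- 1L + stats::rgeom(n, prob = 1 / m)

  tot <- sum(n_rec)
  # Pre-drawn pools, one entry per potential record, consumed sequentially.
  u_type <- stats::runif(tot)
  u_ca <- stats::runif(tot)
  u_readm <- stats::runif(tot)
  gap <- 1L + stats::rpois(tot, max(cfg$mean_gap_days - 1, 0))
  stay <- 1L + stats::rpois(tot, 3)
  readmit_delay <- sample.int(30L, tot, replace = TRUE)
  push <- stats::rpois(tot, 5)

  p_ca <- stats::plogis(stats::qlogis(pmin(pmax(
    cfg$ca_rate_per_record, 1e-12), 1 - 1e-12)) + 0.5 * s)
  if (cfg$ca_rate_per_record == 0) p_ca[] <- 0
  if (cfg$ca_rate_per_record == 1) p_ca[] <- 1
  base_readm_lo <- if (cfg$base_readmission_rate > 0) {
    stats::qlogis(cfg$base_readmission_rate)
  } else -Inf

  # Phase 1: schedule the record skeleton (dates, claim types, CA flags,
  # stays) without outcomes. Scheduled readmissions occur 1-30 days after
  # discharge; other inpatient admissions are pushed at least 31 days past
  # the previous discharge so readmission labels are exactly the draws.
  cap <- tot + n  # room for materialized trailing readmissions
  o_person <- integer(cap)
  o_date <- integer(cap)
  o_inpat <- logical(cap)
  o_ca <- logical(cap)
  o_stay <- integer(cap)
  n_sched <- integer(n)  # scheduled records per person (incl. trailing)
  k <- 0L  # rows written
  pool <- 0L  # pool entries consumed

  for (i in seq_len(n)) {
    k_before <- k
    day <- gap[pool + 1L]  # first visit day for this person
    pending <- NA_integer_  # scheduled readmission day
    min_inpat <- 0L  # earliest allowed non-readmission inpatient day
    p_readm_i <- stats::plogis(base_readm_lo +
                                 0.5 * cfg$severity_effect * s[i])
    for (j in seq_len(n_rec[i])) {
      pool <- pool + 1L
      is_ca_j <- u_ca[pool] < p_ca[i]
      if (!is.na(pending)) {
        inpat <- TRUE
        date_j <- pending
        pending <- NA_integer_
      } else {
        inpat <- is_ca_j || u_type[pool] < cfg$inpatient_fraction
        date_j <- day
        if (inpat && date_j < min_inpat) date_j <- min_inpat + push[pool]
      }
      stay_j <- if (inpat) stay[pool] else 0L
      k <- k + 1L
      o_person[k] <- i
      o_date[k] <- date_j
      o_inpat[k] <- inpat
      o_ca[k] <- is_ca_j && inpat
      o_stay[k] <- stay_j
      if (inpat) {
        discharge <- date_j + stay_j
        if (u_readm[pool] < p_readm_i) {
          pending <- discharge + readmit_delay[pool]
        } else {
          min_inpat <- discharge + 31L
        }
        day <- discharge + gap[pool]
      } else {
        day <- date_j + gap[pool]
      }
    }
    if (!is.na(pending)) {
      # a drawn readmission always materializes, even after the last
      # scheduled record, so the empirical rate matches the draw rate
      k <- k + 1L
      o_person[k] <- i
      o_date[k] <- pending
      o_inpat[k] <- TRUE
      o_ca[k] <- FALSE
      o_stay[k] <- stay[pool]
    }
    n_sched[i] <- k - k_before
  }
  tot <- k
  o_person <- o_person[seq_len(tot)]
  o_date <- o_date[seq_len(tot)]
  o_inpat <- o_inpat[seq_len(tot)]
  o_ca <- o_ca[seq_len(tot)]
  o_stay <- o_stay[seq_len(tot)]

  # Phase 2: mortality triggers. Per-class log-odds intercepts are
  # calibrated against the drawn severities so that the mean trigger
  # probability over non-CA records equals base_mortality_rate and over CA
  # records equals ca_mortality_target_rate, whatever severity_effect is.
  p_trigger <- numeric(tot)
  p_trigger[!o_ca] <- calibrated_rate(cfg$base_mortality_rate,
                                      cfg$severity_effect *
                                        s[o_person[!o_ca]])
  if (any(o_ca)) {
    p_trigger[o_ca] <- calibrated_rate(cfg$ca_mortality_target_rate,
                                       cfg$severity_effect *
                                         s[o_person[o_ca]])
  }
  dies <- stats::runif(tot) < p_trigger
  death_delay <- sample.int(30L, tot, replace = TRUE)

  # Phase 3: a triggered death truncates the sequence after the trigger
  # record and appends a terminal outpatient mortality record 1-30 days
  # later (discharged dead or under critical condition).
  keep <- rep(TRUE, tot)
  pend <- cumsum(n_sched)  # last skeleton row of each person
  d_idx <- which(dies)
  first <- d_idx[!duplicated(o_person[d_idx])]  # first trigger per person
  term_person <- o_person[first]
  term_date <- o_date[first] + death_delay[first]
  for (j in seq_along(first)) {
    last <- pend[term_person[j]]
    if (first[j] < last) keep[(first[j] + 1L):last] <- FALSE
  }
  o_person <- c(o_person[keep], term_person)
  o_date <- c(o_date[keep], term_date)
  o_inpat <- c(o_inpat[keep], rep(FALSE, length(term_person)))
  o_ca <- c(o_ca[keep], rep(FALSE, length(term_person)))
  o_stay <- c(o_stay[keep], rep(0L, length(term_person)))
  o_dead <- c(rep(FALSE, sum(keep)), rep(TRUE, length(term_person)))
  ord <- order(o_person, o_date, method = "radix")
  o_person <- o_person[ord]; o_date <- o_date[ord]
  o_inpat <- o_inpat[ord]; o_ca <- o_ca[ord]
  o_stay <- o_stay[ord]; o_dead <- o_dead[ord]
  k <- length(o_person)
  idx <- seq_len(k)

  # Per-record code draws, biased toward the severe sub-vocabulary by
  # severity; CA records additionally carry a CA procedure code.
  V <- cfg$code_vocab_size_per_category
  n_severe <- max(1L, ceiling(0.2 * V))
  n_normal <- V - n_severe
  lambda <- c(diagnosis = 2, procedure = 1, medication = 2,
              test = 1, other = 0.7)
  prefixes <- c(diagnosis = "DX", procedure = "PX", medication = "RX",
                test = "LX", other = "OX")
  p_severe <- stats::plogis(-1 + s[o_person])
  counts <- matrix(0L, nrow = k, ncol = 5L,
                   dimnames = list(NULL, code_categories()))
  code_parts <- vector("list", 5L)
  for (c_i in seq_along(code_categories())) {
    cat_name <- code_categories()[c_i]
    kc <- stats::rpois(k, lambda[[cat_name]])
    counts[, c_i] <- kc
    rec_of_code <- rep.int(idx, kc)
    ncode <- length(rec_of_code)
    severe <- stats::runif(ncode) < p_severe[rec_of_code]
    code_idx <- ifelse(
      severe,
      n_normal + 1L + floor(stats::runif(ncode) * n_severe),
      1L + floor(stats::runif(ncode) * max(n_normal, 1L)))
    code_parts[[c_i]] <- data.frame(
      rec = rec_of_code,
      tok = sprintf("%s:%s%04d", cat_name, prefixes[[cat_name]], code_idx),
      stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, code_parts)
  # CA procedure code on CA records
  if (any(o_ca)) {
    ca_rec <- which(o_ca)
    ca_code <- sample(default_ca_codes(), length(ca_rec), replace = TRUE)
    long <- rbind(long, data.frame(
      rec = ca_rec, tok = paste0("procedure:", ca_code),
      stringsAsFactors = FALSE))
    counts[ca_rec, "procedure"] <- counts[ca_rec, "procedure"] + 1L
  }
  codes_col <- character(k)
  if (nrow(long)) {
    long <- long[order(long$rec, long$tok, method = "radix"), ]
    agg <- vapply(split(long$tok, long$rec), paste, character(1),
                  collapse = "|")
    codes_col[as.integer(names(agg))] <- agg
  }

  # Lognormal costs increasing in severity and code count; zero when the
  # category is empty.
  costs <- matrix(0, nrow = k, ncol = 5L)
  for (c_i in 1:5) {
    nz <- counts[, c_i] > 0L
    costs[nz, c_i] <- round(stats::rlnorm(
      sum(nz),
      meanlog = 3 + 0.3 * s[o_person[nz]] + 0.2 * counts[nz, c_i],
      sdlog = 0.5), 2)
  }

  records <- data.frame(
    record_id = sprintf("p%06d-r%03d", o_person,
                        stats::ave(o_person, o_person, FUN = seq_along)),
    person_id = person_id[o_person],
    date = o_date,
    claim_type = ifelse(o_inpat, "inpatient", "outpatient"),
    codes = codes_col,
    care_site_type = sample.int(21L, k, replace = TRUE) - 1L,
    care_site_specialization = sample.int(5L, k, replace = TRUE) - 1L,
    care_site_rank = sample.int(17L, k, replace = TRUE) - 1L,
    hospital_stay = o_stay,
    stringsAsFactors = FALSE)
  cost_df <- as.data.frame(costs)
  names(cost_df) <- paste0("cost_", category_suffixes())
  count_df <- as.data.frame(counts)
  names(count_df) <- paste0("count_", category_suffixes())
  records <- cbind(records, cost_df, count_df,
                   discharge_dead_or_critical = o_dead)

  persons <- data.frame(person_id = person_id, gender = gender,
                        birth_year = birth_year, stringsAsFactors = FALSE)
  out <- cohort(persons, records, epoch_year = epoch_year)
  attr(out, "severity") <- stats::setNames(s, person_id)
  out
}

#' Summarize a cohort
#'
#' Reports cohort size, record-count moments, the CA-record fraction, and
#' the per-task positive rates (ALL/CA x mortality/readmission). Rates over
#' an empty record subset are `NA`, never 0.
#'
#' @param x An `hvec_cohort`.
#' @param labels Optional precomputed [label_cohort()] table.
#' @return One-row data frame of summary statistics.
#' @export
cohort_summary <- function(x, labels = NULL) {
  stopifnot(inherits(x, "hvec_cohort"), nrow(x$records) > 0L)
  if (is.null(labels)) labels <- label_cohort(x)
  per_person <- table(factor(x$records$person_id,
                             levels = x$persons$person_id))
  rate <- function(v) if (length(v) == 0L) NA_real_ else mean(v)
  elig <- !is.na(labels$readmission_30d)
  data.frame(
    n_persons = nrow(x$persons),
    n_records = nrow(x$records),
    mean_records_per_person = mean(per_person),
    sd_records_per_person = if (length(per_person) < 2L) 0 else
      stats::sd(per_person),
    ca_record_fraction = mean(x$records$is_ca),
    rate_all_mortality = rate(labels$mortality_30d),
    rate_ca_mortality = rate(labels$mortality_30d[labels$is_ca]),
    rate_all_readmission = rate(labels$readmission_30d[elig]),
    rate_ca_readmission = rate(labels$readmission_30d[elig & labels$is_ca]))
}
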