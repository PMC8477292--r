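# 30-day outcome labeling. A record is mortality-positive iff the person's
# mortality event falls 1..30 days (inclusive) after the record; the record
# carrying the mortality flag itself is always negative (anti-leakage).
# Readmission is defined from hospital discharge and only for inpatient
# records; outpatient records are NA and excluded from loss and metrics.

#' Label 30-day mortality for one person
#'
#' The mortality event day is the date of the (at most one) record flagged
#' `discharge_dead_or_critical`. A record is positive iff the event falls
#' 1--30 days after it; the flagged record itself is negative regardless
#' (anti-leakage: terminal-record features must not predict their own
#' event).
#'
#' @param records Data frame of one person's records, sorted by
#'   `(date, record_id)`, with columns `date` and
#'   `discharge_dead_or_critical`.
#' @return Integer 0/1 vector, one label per record.
#' @export
label_mortality <- function(records) {
  flagged <- which(records$discharge_dead_or_critical)
  if (length(flagged) > 1L) {
    stop("integrity error: multiple mortality records for one person")
  }
  if (length(flagged) == 0L) return(integer(nrow(records)))
  gap <- records$date[flagged] - records$date
  out <- as.integer(gap >= 1L & gap <= 30L)
  out[flagged] <- 0L
  out
}

#' Label 30-day readmission for one person
#'
#' For each inpatient record with discharge day `date + hospital_stay`, the
#' label is 1 iff a later inpatient admission starts 1--30 days (inclusive)
#' after discharge, else 0. Outpatient records get `NA` (no discharge day is
#' defined for them). An admission at or before a discharge (overlapping
#' stays) never counts and triggers a warning.
#'
#' @param records Data frame of one person's records, sorted, with columns
#'   `date`, `claim_type`, `hospital_stay`.
#' @return Integer 0/1/NA vector, one label per record.
#' @export
label_readmission <- function(records) {
  n <- nrow(records)
  out <- rep(NA_integer_, n)
  inpat <- which(records$claim_type == "inpatient")
  if (!length(inpat)) return(out)
  adm <- sort(records$date[inpat])
  overlap <- FALSE
  for (i in inpat) {
    discharge <- records$date[i] + records$hospital_stay[i]
    # admissions with date in (discharge, discharge + 30], i.e. gap 1..30
    hits <- findInterval(discharge + 30L, adm) - findInterval(discharge, adm)
    out[i] <- as.integer(hits > 0L)
    later_leq <- findInterval(discharge, adm) -
      findInterval(records$date[i], adm)
    if (later_leq > 0L) overlap <- TRUE
  }
  if (overlap) {
    warning("overlapping inpatient stays: admissions at or before a ",
            "discharge do not count as readmission")
  }
  out
}

#' Label a cohort
#'
#' Applies [label_mortality()] and [label_readmission()] per person and
#' returns one row per record, in the cohort's record order.
#'
#' @param x An `hvec_cohort`.
#' @param drop_mortality_records If `TRUE`, rows for records flagged
#'   `discharge_dead_or_critical` are removed (the stricter exclusion
#'   reading); by default they are kept as mortality negatives.
#' @return Data frame with columns `record_id`, `person_id`, `date`,
#'   `is_ca`, `mortality_30d`, `readmission_30d` (NA for
#'   readmission-ineligible records).
#' @export
label_cohort <- function(x, drop_mortality_records = FALSE) {
  stopifnot(inherits(x, "hvec_cohort"))
  r <- x$records
  ndead <- tapply(r$discharge_dead_or_critical, r$person_id, sum)
  if (any(ndead > 1L)) {
    stop("integrity error: multiple mortality records for person ",
         names(ndead)[ndead > 1L][1L])
  }
  # vectorized mortality: event day per person joined back onto records
  dead_rows <- r$discharge_dead_or_critical
  event_day <- r$date[dead_rows]
  names(event_day) <- r$person_id[dead_rows]
  ed <- unname(event_day[r$person_id])
  gap <- ed - r$date
  mortality <- as.integer(!is.na(gap) & gap >= 1L & gap <= 30L)
  mortality[dead_rows] <- 0L

  readmission <- rep(NA_integer_, nrow(r))
  idx_by_person <- split(seq_len(nrow(r)), r$person_id)
  for (idx in idx_by_person) {
    readmission[idx] <- label_readmission(r[idx, , drop = FALSE])
  }
  out <- data.frame(record_id = r$record_id, person_id = r$person_id,
                    date = r$date, is_ca = r$is_ca,
                    mortality_30d = mortality,
                    readmission_30d = readmission,
                    stringsAsFactors = FALSE)
  if (drop_mortality_records) {
    out <- out[!dead_rows, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Build the four task subsets
#'
#' The two targets each define an ALL set and a CA subset: `ALL-mortality`
#' covers every labeled record, `CA-mortality` its CA records;
#' `ALL-readmission` covers readmission-eligible (inpatient) records,
#' `CA-readmission` its CA records. CA positives are by construction a
#' subset of ALL positives.
#'
#' @param labels A [label_cohort()] table.
#' @return Named list of four data frames with columns `record_id`, `label`.
#' @export
build_task_masks <- function(labels) {
  elig <- !is.na(labels$readmission_30d)
  list(
    "ALL-mortality" = data.frame(
      record_id = labels$record_id, label = labels$mortality_30d,
      stringsAsFactors = FALSE),
    "CA-mortality" = data.frame(
      record_id = labels$record_id[labels$is_ca],
      label = labels$mortality_30d[labels$is_ca],
      stringsAsFactors = FALSE),
    "ALL-readmission" = data.frame(
      record_id = labels$record_id[elig],
      label = labels$readmission_30d[elig],
      stringsAsFactors = FALSE),
    "CA-readmission" = data.frame(
      record_id = labels$record_id[elig & labels$is_ca],
      label = labels$readmission_30d[elig & labels$is_ca],
      stringsAsFactors = FALSE))
}
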