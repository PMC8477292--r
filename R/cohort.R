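#' @keywords internal
"_PACKAGE"

#' Medical code categories
#'
#' The five code categories carried by a clinical record: diagnoses,
#' procedures, medications, laboratory tests, and an opaque fifth "other"
#' category. Cost and count fields of a record are indexed in this order.
#'
#' @return Character vector of the five category names, in canonical order.
#' @export
code_categories <- function() {
  c("diagnosis", "procedure", "medication", "test", "other")
}

# Column suffixes used for per-category cost_*/count_* fields, aligned with
# code_categories().
category_suffixes <- function() c("dx", "px", "med", "test", "other")

#' Default cardiac-arrest procedure code set
#'
#' ICD-9 procedure codes identifying an in-hospital cardiac arrest record:
#' 99.60 (cardiopulmonary resuscitation, not otherwise specified) and 99.63
#' (closed-chest cardiac massage).
#'
#' @return Character vector of procedure codes.
#' @export
default_ca_codes <- function() c("99.60", "99.63")

records_columns <- function() {
  c("record_id", "person_id", "date", "claim_type", "codes",
    "care_site_type", "care_site_specialization", "care_site_rank",
    "hospital_stay",
    paste0("cost_", category_suffixes()),
    paste0("count_", category_suffixes()),
    "discharge_dead_or_critical")
}

#' Parse a serialized code list
#'
#' Codes are serialized as `category:code` tokens joined by `|`; an empty
#' string means no codes.
#'
#' @param codes Character vector of serialized code lists.
#' @return A data frame with columns `idx` (index into `codes`), `category`,
#'   `code`, one row per token.
#' @export
parse_codes <- function(codes) {
  nonempty <- which(!is.na(codes) & codes != "")
  toks <- strsplit(codes[nonempty], "|", fixed = TRUE)
  flat <- unlist(toks, use.names = FALSE)
  idx <- rep.int(nonempty, lengths(toks))
  sep <- regexpr(":", flat, fixed = TRUE)
  if (length(flat) && any(sep < 0L)) {
    stop("malformed code token (expected category:code): ",
         flat[sep < 0L][1L])
  }
  category <- substr(flat, 1L, sep - 1L)
  code <- substr(flat, sep + 1L, nchar(flat))
  bad <- !(category %in% code_categories()) | code == ""
  if (length(flat) && any(bad)) {
    stop("invalid code token: ", flat[bad][1L])
  }
  data.frame(idx = idx, category = category, code = code,
             stringsAsFactors = FALSE)
}

format_codes <- function(category, code) {
  if (length(category) == 0L) return("")
  paste(paste(category, code, sep = ":"), collapse = "|")
}

#' Flag cardiac-arrest records
#'
#' A record is a cardiac-arrest (CA) record iff it carries a *procedure* code
#' belonging to `ca_codes`. The same code appearing under another category
#' does not count.
#'
#' @param codes Character vector of serialized code lists (see
#'   [parse_codes()]).
#' @param ca_codes Character vector of CA procedure codes; defaults to
#'   [default_ca_codes()].
#' @return Logical vector, one element per record.
#' @export
flag_ca <- function(codes, ca_codes = default_ca_codes()) {
  stopifnot(length(ca_codes) >= 1L)
  out <- logical(length(codes))
  parsed <- parse_codes(codes)
  hit <- parsed$category == "procedure" & parsed$code %in% ca_codes
  out[unique(parsed$idx[hit])] <- TRUE
  out
}

#' Construct a cohort
#'
#' Bundles a persons table and a records table into a validated cohort
#' object. Records are sorted per person by `(date, record_id)` (a stable
#' total order), and the derived `is_ca` column is attached.
#'
#' @param persons Data frame with columns `person_id`, `gender`
#'   (`"male"`/`"female"`), `birth_year`.
#' @param records Data frame with the interchange columns (see
#'   [write_cohort()]).
#' @param epoch_year Calendar year of day index 0; dates are integer day
#'   offsets from this epoch.
#' @param ca_codes CA procedure code set used to derive `is_ca`.
#' @return An object of class `hvec_cohort`: a list with elements `persons`,
#'   `records`, `epoch_year`, `ca_codes`.
#' @export
cohort <- function(persons, records, epoch_year = 2002L,
                   ca_codes = default_ca_codes()) {
  persons <- as.data.frame(persons, stringsAsFactors = FALSE)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need_p <- c("person_id", "gender", "birth_year")
  if (!all(need_p %in% names(persons))) {
    stop("persons table must have columns: ", paste(need_p, collapse = ", "))
  }
  missing_cols <- setdiff(records_columns(), names(records))
  if (length(missing_cols)) {
    stop("records table missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  records <- records[records_columns()]
  if (anyDuplicated(persons$person_id)) {
    stop("integrity error: duplicate person_id in persons table")
  }
  # canonical column types so interchange round-trips are exact
  persons$person_id <- as.character(persons$person_id)
  persons$gender <- as.character(persons$gender)
  persons$birth_year <- as.integer(persons$birth_year)
  for (col in c("date", "care_site_type", "care_site_specialization",
                "care_site_rank", "hospital_stay",
                paste0("count_", category_suffixes()))) {
    records[[col]] <- as.integer(records[[col]])
  }
  for (col in paste0("cost_", category_suffixes())) {
    records[[col]] <- as.numeric(records[[col]])
  }
  records$record_id <- as.character(records$record_id)
  records$person_id <- as.character(records$person_id)
  records$claim_type <- as.character(records$claim_type)
  records$codes <- as.character(records$codes)
  records$discharge_dead_or_critical <-
    as.logical(records$discharge_dead_or_critical)
  obj <- structure(
    list(persons = persons, records = records,
         epoch_year = as.integer(epoch_year), ca_codes = ca_codes),
    class = "hvec_cohort")
  obj$records <- obj$records[order(obj$records$person_id,
                                   obj$records$date,
                                   obj$records$record_id,
                                   method = "radix"), , drop = FALSE]
  rownames(obj$records) <- NULL
  obj$records$is_ca <- flag_ca(obj$records$codes, ca_codes)
  validate_cohort(obj)
  obj
}

#' Validate cohort invariants
#'
#' Checks the structural invariants of a cohort: unique person ids, every
#' record's person known, non-negative integer dates, outpatient records with
#' zero hospital stay, per-category counts equal to the code tally, and at
#' most one mortality-flagged record per person.
#'
#' @param x An `hvec_cohort`.
#' @return `x`, invisibly; stops with an integrity error otherwise.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "hvec_cohort"))
  p <- x$persons
  r <- x$records
  if (anyDuplicated(p$person_id)) {
    stop("integrity error: duplicate person_id")
  }
  if (nrow(r)) {
    if (anyDuplicated(r$record_id)) {
      stop("integrity error: duplicate record_id")
    }
    if (!all(r$person_id %in% p$person_id)) {
      stop("integrity error: record with unknown person_id")
    }
    if (any(r$date < 0)) stop("integrity error: negative date")
    if (!all(r$claim_type %in% c("inpatient", "outpatient"))) {
      stop("integrity error: claim_type must be inpatient/outpatient")
    }
    if (any(r$hospital_stay < 0)) {
      stop("integrity error: negative hospital_stay")
    }
    if (any(r$claim_type == "outpatient" & r$hospital_stay != 0)) {
      stop("integrity error: outpatient record with nonzero hospital_stay")
    }
    cnt <- count_codes_by_category(r$codes)
    declared <- as.matrix(r[paste0("count_", category_suffixes())])
    if (!all(declared == cnt)) {
      bad <- which(rowSums(declared != cnt) > 0)[1L]
      stop("integrity error: counts do not match code tally for record ",
           r$record_id[bad])
    }
    ndead <- tapply(r$discharge_dead_or_critical, r$person_id, sum)
    if (any(ndead > 1L)) {
      stop("integrity error: multiple mortality records for person ",
           names(ndead)[ndead > 1L][1L])
    }
  }
  if (!all(p$gender %in% c("male", "female"))) {
    stop("integrity error: gender must be male/female")
  }
  invisible(x)
}

# n_records x 5 matrix of per-category code counts computed from the codes
# column.
count_codes_by_category <- function(codes) {
  out <- matrix(0L, nrow = length(codes), ncol = 5L,
                dimnames = list(NULL, code_categories()))
  parsed <- parse_codes(codes)
  if (nrow(parsed)) {
    tab <- table(factor(parsed$idx, levels = seq_along(codes)),
                 factor(parsed$category, levels = code_categories()))
    out[] <- as.integer(tab)
  }
  out
}

#' Write a cohort to the interchange format
#'
#' Writes `persons.csv` and `records.csv` (UTF-8, RFC-4180) into a
#' directory. Codes are serialized as `category:code` tokens joined by `|`;
#' the derived `is_ca` column is not serialized.
#'
#' @param x An `hvec_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "hvec_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(x$persons, file.path(dir, "persons.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  rec <- x$records[records_columns()]
  utils::write.csv(rec, file.path(dir, "records.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  meta <- data.frame(key = c("epoch_year", "ca_codes"),
                     value = c(as.character(x$epoch_year),
                               paste(x$ca_codes, collapse = "|")))
  utils::write.csv(meta, file.path(dir, "cohort.csv"), row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(dir)
}

#' Read a cohort from the interchange format
#'
#' Inverse of [write_cohort()]: reads `persons.csv`/`records.csv` (and
#' `cohort.csv` metadata when present), re-sorts records, re-derives `is_ca`,
#' and validates all invariants. Round-trips written cohorts field-by-field.
#'
#' @param dir Directory containing the interchange files.
#' @param epoch_year,ca_codes Defaults used when no `cohort.csv` is present.
#' @return An `hvec_cohort`.
#' @export
read_cohort <- function(dir, epoch_year = 2002L,
                        ca_codes = default_ca_codes()) {
  pfile <- file.path(dir, "persons.csv")
  rfile <- file.path(dir, "records.csv")
  if (!file.exists(pfile) || !file.exists(rfile)) {
    stop("parse error: missing persons.csv or records.csv in ", dir)
  }
  persons <- utils::read.csv(pfile, stringsAsFactors = FALSE,
                             colClasses = c(person_id = "character"))
  records <- utils::read.csv(
    rfile, stringsAsFactors = FALSE,
    colClasses = c(record_id = "character", person_id = "character",
                   codes = "character"))
  records$codes[is.na(records$codes)] <- ""
  tryCatch(parse_codes(records$codes), error = function(e) {
    bad <- which(vapply(records$codes, function(cd) {
      inherits(tryCatch(parse_codes(cd), error = identity), "error")
    }, logical(1)))[1L]
    stop("parse error at records.csv row ", bad, ": ",
         conditionMessage(e), call. = FALSE)
  })
  mfile <- file.path(dir, "cohort.csv")
  if (file.exists(mfile)) {
    meta <- utils::read.csv(mfile, stringsAsFactors = FALSE)
    epoch_year <- as.integer(meta$value[meta$key == "epoch_year"])
    ca_codes <- strsplit(meta$value[meta$key == "ca_codes"], "|",
                         fixed = TRUE)[[1L]]
  }
  cohort(persons, records, epoch_year = epoch_year, ca_codes = ca_codes)
}

#' @export
#' @method print hvec_cohort
print.hvec_cohort <- function(x, ...) {
  cat("Claims cohort:", nrow(x$persons), "persons,",
      nrow(x$records), "records\n")
  cat("  epoch year:", x$epoch_year,
      "| CA procedure codes:", paste(x$ca_codes, collapse = ", "), "\n")
  if (nrow(x$records)) {
    cat("  CA records:", sum(x$records$is_ca),
        sprintf("(%.2f%%)", 100 * mean(x$records$is_ca)), "\n")
  }
  invisible(x)
}
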