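# Featurization: each record maps to a fixed-layout real vector -- five
# 128-dim code-embedding sums, one-hot demographic/care-site context, and
# standardized record statistics plus 90/180/365/730-day history windows.
# With the default code-embedding size of 128 the layout is exactly 707
# wide.

#' Feature layout
#'
#' Named span lengths of the record vector, in concatenation order. With
#' `code_dim = 128` the spans sum to 707:
#' 5x128 + 2 + 1 + 2 + 21 + 5 + 17 + 1 + 5 + 5 + 4 + 4.
#'
#' @param code_dim Code-embedding dimension.
#' @return Named integer vector of span lengths.
#' @export
feature_layout <- function(code_dim = 128L) {
  c(diagnosis = code_dim, procedure = code_dim, medication = code_dim,
    test = code_dim, other = code_dim,
    claim_type = 2L, age = 1L, gender = 2L,
    care_site_type = 21L, care_site_specialization = 5L,
    care_site_rank = 17L,
    hospital_stay = 1L, total_cost = 5L, total_count = 5L,
    past_hospitalization_duration = 4L, past_admission_count = 4L)
}

# start/end column indices of each span
layout_spans <- function(layout) {
  ends <- cumsum(layout)
  starts <- ends - layout + 1L
  data.frame(span = names(layout), start = starts, end = ends,
             stringsAsFactors = FALSE, row.names = NULL)
}

span_cols <- function(layout, span) {
  sp <- layout_spans(layout)
  i <- match(span, sp$span)
  seq.int(sp$start[i], sp$end[i])
}

# 31-bit polynomial rolling hash of a string; deterministic across platforms.
stable_hash <- function(x) {
  vapply(x, function(s) {
    h <- 0
    for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

#' Build a deterministic code-embedding table
#'
#' Assigns every `(category, code)` pair a pseudo-random unit-variance
#' vector keyed by a stable string hash combined with the seed: the same
#' vocabulary and seed yield an identical table on any machine. This is a
#' deterministic embedding; no semantic similarity between related codes is
#' represented -- the signal carried is code identity.
#'
#' @param vocab Data frame with columns `category`, `code` (duplicates
#'   allowed and ignored).
#' @param dimension Embedding dimension (default 128).
#' @param seed Integer seed mixed into every vector's key.
#' @param unknown How to embed a code absent from the table:
#'   `"error"` (default) or `"zero"`.
#' @return An `hvec_embedding_table`: list with `dimension`, `vectors`
#'   (matrix with `category:code` rownames), `unknown`.
#' @export
make_embedding_table <- function(vocab, dimension = 128L, seed = 0L,
                                 unknown = c("error", "zero")) {
  stopifnot(dimension >= 1L)
  unknown <- match.arg(unknown)
  stopifnot(all(vocab$category %in% code_categories()))
  keys <- unique(paste(vocab$category, vocab$code, sep = ":"))
  keys <- sort(keys)
  h <- stable_hash(keys)
  vecs <- matrix(0, nrow = length(keys), ncol = dimension,
                 dimnames = list(keys, NULL))
  for (i in seq_along(keys)) {
    vecs[i, ] <- with_seed((h[i] + 97 * (seed %% 1000003)) %% 2147483647,
                           stats::rnorm(dimension))
  }
  structure(list(dimension = as.integer(dimension), vectors = vecs,
                 unknown = unknown),
            class = "hvec_embedding_table")
}

#' Sum the code embeddings of one category in a record
#'
#' Element-wise sum of the embedding vectors of all codes of `category`
#' present in the record (a multiset sum: a code listed twice contributes
#' twice); the zero vector when the category is empty.
#'
#' @param codes Serialized code list of one record (see [parse_codes()]).
#' @param category One of [code_categories()].
#' @param table An [make_embedding_table()] table.
#' @return Numeric vector of length `table$dimension`.
#' @export
embed_category <- function(codes, category, table) {
  stopifnot(inherits(table, "hvec_embedding_table"),
            category %in% code_categories())
  parsed <- parse_codes(codes)
  parsed <- parsed[parsed$category == category, , drop = FALSE]
  out <- numeric(table$dimension)
  if (!nrow(parsed)) return(out)
  keys <- paste(parsed$category, parsed$code, sep = ":")
  j <- match(keys, rownames(table$vectors))
  if (anyNA(j)) {
    if (table$unknown == "error") {
      stop("lookup error: unknown code ", keys[is.na(j)][1L])
    }
    j <- j[!is.na(j)]
  }
  if (length(j)) out <- colSums(table$vectors[j, , drop = FALSE])
  out
}

#' Historical hospitalization features
#'
#' For each record, over windows of 90/180/365/730 days strictly before the
#' record's date: total inpatient `hospital_stay` days of admissions falling
#' in the window (4 values) and the number of such admissions (4 values).
#'
#' @param records One person's records, sorted.
#' @return Matrix `nrow(records) x 8`; columns `dur_90 ... dur_730`,
#'   `cnt_90 ... cnt_730`.
#' @export
history_features <- function(records) {
  windows <- c(90L, 180L, 365L, 730L)
  n <- nrow(records)
  out <- matrix(0, nrow = n, ncol = 8L,
                dimnames = list(NULL, c(paste0("dur_", windows),
                                        paste0("cnt_", windows))))
  inpat <- records$claim_type == "inpatient"
  if (!any(inpat) || n < 2L) return(out)
  adm_date <- records$date[inpat]
  adm_stay <- records$hospital_stay[inpat]
  for (i in seq_len(n)) {
    for (w in seq_along(windows)) {
      hit <- adm_date >= records$date[i] - windows[w] &
        adm_date <= records$date[i] - 1L
      out[i, w] <- sum(adm_stay[hit])
      out[i, 4L + w] <- sum(hit)
    }
  }
  out
}

scalar_spans <- c("age", "hospital_stay", "total_cost", "total_count",
                  "past_hospitalization_duration", "past_admission_count")

#' Fit the feature scaler
#'
#' Column means and standard deviations of the scalar feature spans (age,
#' hospital stay, log1p costs, counts, history), computed on training rows
#' only. Applying a scaler never updates it.
#'
#' @param x Raw feature matrix from [feature_matrix()] with `scale = FALSE`.
#' @param rows Row indices to fit on (the training split).
#' @return An `hvec_scaler`.
#' @export
fit_scaler <- function(x, rows = seq_len(nrow(x))) {
  layout <- attr(x, "layout")
  cols <- unlist(lapply(scalar_spans, span_cols, layout = layout))
  mu <- colMeans(x[rows, cols, drop = FALSE])
  sd <- apply(x[rows, cols, drop = FALSE], 2L, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  structure(list(cols = cols, mean = mu, sd = sd), class = "hvec_scaler")
}

apply_scaler <- function(x, scaler) {
  stopifnot(inherits(scaler, "hvec_scaler"))
  x[, scaler$cols] <- sweep(sweep(x[, scaler$cols, drop = FALSE], 2L,
                                  scaler$mean, "-"),
                            2L, scaler$sd, "/")
  x
}

#' Featurize every record of a cohort
#'
#' Builds the full record-by-feature matrix in the [feature_layout()]
#' order: per-category code-embedding sums, one-hot claim type / gender /
#' care-site levels, age at the record date, hospital stay, per-category
#' log1p costs and counts, and the 8 history features. Scalar spans are
#' standardized with `scaler` when given (fit it on training rows only).
#'
#' @param x An `hvec_cohort`.
#' @param table An [make_embedding_table()] table covering the cohort's
#'   codes (or configured with `unknown = "zero"`).
#' @param scaler Optional [fit_scaler()] result.
#' @return Numeric matrix with rownames `record_id` and attribute `layout`.
#' @export
feature_matrix <- function(x, table, scaler = NULL) {
  stopifnot(inherits(x, "hvec_cohort"),
            inherits(table, "hvec_embedding_table"))
  r <- x$records
  n <- nrow(r)
  layout <- feature_layout(table$dimension)
  out <- matrix(0, nrow = n, ncol = sum(layout),
                dimnames = list(r$record_id, NULL))
  attr(out, "layout") <- layout
  if (n == 0L) return(out)

  # code-embedding sums via sparse count matrix x embedding matrix
  parsed <- parse_codes(r$codes)
  if (nrow(parsed)) {
    keys <- paste(parsed$category, parsed$code, sep = ":")
    j <- match(keys, rownames(table$vectors))
    if (anyNA(j) && table$unknown == "error") {
      stop("lookup error: unknown code ", keys[is.na(j)][1L])
    }
    keep <- !is.na(j)
    for (cat_name in code_categories()) {
      sel <- keep & parsed$category == cat_name
      if (!any(sel)) next
      counts <- Matrix::sparseMatrix(
        i = parsed$idx[sel], j = j[sel], x = 1,
        dims = c(n, nrow(table$vectors)))
      out[, span_cols(layout, cat_name)] <-
        as.matrix(counts %*% table$vectors)
    }
  }

  onehot <- function(level, k) {
    if (any(level < 0L | level >= k)) {
      stop("validation error: care-site level out of range 0..", k - 1L)
    }
    m <- matrix(0, nrow = n, ncol = k)
    m[cbind(seq_len(n), level + 1L)] <- 1
    m
  }
  out[, span_cols(layout, "claim_type")] <-
    onehot(as.integer(r$claim_type == "outpatient"), 2L)
  age <- (x$epoch_year + r$date %/% 365L) -
    x$persons$birth_year[match(r$person_id, x$persons$person_id)]
  out[, span_cols(layout, "age")] <- age
  gender <- x$persons$gender[match(r$person_id, x$persons$person_id)]
  out[, span_cols(layout, "gender")] <-
    onehot(as.integer(gender == "female"), 2L)
  out[, span_cols(layout, "care_site_type")] <- onehot(r$care_site_type, 21L)
  out[, span_cols(layout, "care_site_specialization")] <-
    onehot(r$care_site_specialization, 5L)
  out[, span_cols(layout, "care_site_rank")] <- onehot(r$care_site_rank, 17L)
  out[, span_cols(layout, "hospital_stay")] <- r$hospital_stay
  out[, span_cols(layout, "total_cost")] <-
    log1p(as.matrix(r[paste0("cost_", category_suffixes())]))
  out[, span_cols(layout, "total_count")] <-
    as.matrix(r[paste0("count_", category_suffixes())])

  hist_cols <- c(span_cols(layout, "past_hospitalization_duration"),
                 span_cols(layout, "past_admission_count"))
  for (idx in split(seq_len(n), r$person_id)) {
    out[idx, hist_cols] <- history_features(r[idx, , drop = FALSE])
  }

  if (!is.null(scaler)) out <- apply_scaler_keep(out, scaler)
  out
}

# apply_scaler preserving the layout attribute
apply_scaler_keep <- function(x, scaler) {
  layout <- attr(x, "layout")
  x <- apply_scaler(x, scaler)
  attr(x, "layout") <- layout
  x
}

#' Featurize a single record
#'
#' Convenience wrapper around [feature_matrix()] for one record; the history
#' features still use the person's full record sequence.
#'
#' @param x An `hvec_cohort`.
#' @param record_id The record to featurize.
#' @param table,scaler As in [feature_matrix()].
#' @return Named numeric vector (names `span.k`), with attribute `layout`.
#' @export
build_record_vector <- function(x, record_id, table, scaler = NULL) {
  fm <- feature_matrix(x, table, scaler)
  i <- match(record_id, rownames(fm))
  if (is.na(i)) stop("unknown record_id: ", record_id)
  v <- fm[i, ]
  layout <- attr(fm, "layout")
  names(v) <- unlist(lapply(seq_along(layout), function(k) {
    paste(names(layout)[k], seq_len(layout[k]), sep = ".")
  }))
  attr(v, "layout") <- layout
  v
}
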