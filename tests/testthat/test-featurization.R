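test_that("the default layout is exactly 707 wide with the documented spans", {
  layout <- feature_layout(128L)
  expect_equal(sum(layout), 707L)
  expect_equal(unname(layout[c("claim_type", "age", "gender")]),
               c(2L, 1L, 2L))
  expect_equal(unname(layout[c("care_site_type", "care_site_specialization",
                               "care_site_rank")]), c(21L, 5L, 17L))
  expect_equal(sum(layout[code_categories()]), 640L)
})

test_that("embedding tables are deterministic, unit-variance, collision-free", {
  vocab <- data.frame(category = rep(code_categories(), each = 40),
                      code = paste0("C", 1:200))
  t1 <- make_embedding_table(vocab, dimension = 64, seed = 3)
  t2 <- make_embedding_table(vocab, dimension = 64, seed = 3)
  expect_identical(t1$vectors, t2$vectors)
  t3 <- make_embedding_table(vocab, dimension = 64, seed = 4)
  expect_false(identical(t1$vectors, t3$vectors))
  # squared norms concentrate near the dimension (chi-squared mean)
  sqn <- rowSums(t1$vectors^2)
  expect_lt(abs(mean(sqn) - 64) / 64, 0.10)
  expect_equal(anyDuplicated(t1$vectors), 0L)
})

test_that("embed_category sums a multiset of code vectors", {
  vocab <- data.frame(category = "diagnosis", code = c("A", "B"))
  tab <- make_embedding_table(vocab, dimension = 16, seed = 1)
  ea <- embed_category("diagnosis:A", "diagnosis", tab)
  eb <- embed_category("diagnosis:B", "diagnosis", tab)
  expect_equal(embed_category("", "diagnosis", tab), numeric(16))
  expect_equal(embed_category("diagnosis:A|diagnosis:B", "diagnosis", tab),
               ea + eb)
  expect_equal(embed_category("diagnosis:B|diagnosis:A", "diagnosis", tab),
               ea + eb)
  # duplicated code contributes twice (multiset, not set, semantics)
  expect_equal(embed_category("diagnosis:A|diagnosis:A", "diagnosis", tab),
               2 * ea)
  # unknown code: error naming the code, or zero under the zero policy
  expect_error(embed_category("diagnosis:ZZ", "diagnosis", tab),
               "diagnosis:ZZ")
  tabz <- make_embedding_table(vocab, 16, 1, unknown = "zero")
  expect_equal(embed_category("diagnosis:ZZ", "diagnosis", tabz),
               numeric(16))
})

test_that("history features scan the four windows strictly before the record", {
  # first-ever record: all zeros
  co <- one_person_cohort(list(
    make_record("r1", "p1", 1000, claim_type = "inpatient",
                hospital_stay = 7L),
    make_record("r2", "p1", 1050),
    make_record("r3", "p1", 1400, claim_type = "inpatient",
                hospital_stay = 2L)))
  h <- history_features(co$records)
  expect_equal(unname(h[1, ]), rep(0, 8))
  # one admission 50 days back with stay 7: in every window
  expect_equal(unname(h[2, ]), c(7, 7, 7, 7, 1, 1, 1, 1))
  # 400 days back: only the 730-day window sees it
  expect_equal(unname(h[3, ]), c(0, 0, 0, 7, 0, 0, 0, 1))

  # oracle comparison on a random cohort
  co2 <- random_cohort(40, seed = 51)
  for (pid in unique(co2$records$person_id)[1:10]) {
    rp <- co2$records[co2$records$person_id == pid, ]
    h2 <- history_features(rp)
    for (i in seq_len(nrow(rp))) {
      for (wi in seq_along(c(90, 180, 365, 730))) {
        w <- c(90, 180, 365, 730)[wi]
        hit <- rp$claim_type == "inpatient" &
          rp$date >= rp$date[i] - w & rp$date <= rp$date[i] - 1
        expect_equal(unname(h2[i, wi]), sum(rp$hospital_stay[hit]))
        expect_equal(unname(h2[i, 4 + wi]), sum(hit))
      }
    }
  }
})

test_that("record vectors have the exact layout and localized encodings", {
  co <- random_cohort(30, seed = 53)
  vocab <- parse_codes(co$records$codes)[c("category", "code")]
  tab <- make_embedding_table(vocab, dimension = 128, seed = 1)
  v <- build_record_vector(co, co$records$record_id[1], tab)
  expect_length(v, 707L)

  # two records identical except gender differ only in the gender span
  recs <- rbind(make_record("r1", "pA", 10, codes = "diagnosis:DX1"),
                make_record("r2", "pB", 10, codes = "diagnosis:DX1"))
  pers <- rbind(make_persons("pA", gender = "male"),
                make_persons("pB", gender = "female"))
  co2 <- cohort(pers, recs)
  tab2 <- make_embedding_table(parse_codes(recs$codes)[c("category", "code")],
                               dimension = 8, seed = 1)
  fm <- feature_matrix(co2, tab2)
  layout <- attr(fm, "layout")
  gcols <- (cumsum(layout)[["gender"]] - 1L):cumsum(layout)[["gender"]]
  diffs <- which(fm["r1", ] != fm["r2", ])
  expect_true(all(diffs %in% gcols))
  # one-hot spans sum to 1
  for (span in c("claim_type", "gender", "care_site_type",
                 "care_site_specialization", "care_site_rank")) {
    ends <- cumsum(layout)
    cols <- (ends[[span]] - layout[[span]] + 1L):ends[[span]]
    expect_equal(unname(rowSums(fm[, cols, drop = FALSE])), c(1, 1))
  }

  # permuting the serialized code list leaves the vector unchanged
  recs3 <- rbind(
    make_record("r1", "pA", 10, codes = "diagnosis:DX1|diagnosis:DX2|test:LX1"),
    make_record("r2", "pA", 50, codes = "test:LX1|diagnosis:DX2|diagnosis:DX1"))
  co3 <- cohort(make_persons("pA"), recs3)
  tab3 <- make_embedding_table(parse_codes(recs3$codes)[c("category", "code")],
                               dimension = 16, seed = 2)
  fm3 <- feature_matrix(co3, tab3)
  # r2 differs from r1 only through date-dependent spans (age/history); codes
  # spans must be identical
  ccols <- 1:(5 * 16)
  expect_equal(fm3["r1", ccols], fm3["r2", ccols])
})

test_that("the scaler is fit on training rows and stays frozen", {
  co <- random_cohort(80, seed = 57)
  vocab <- parse_codes(co$records$codes)[c("category", "code")]
  tab <- make_embedding_table(vocab, dimension = 8, seed = 1)
  fm <- feature_matrix(co, tab)
  rows <- seq_len(floor(nrow(fm) / 2))
  sc <- fit_scaler(fm, rows)
  snapshot <- unserialize(serialize(sc, NULL))
  # scaled training rows have mean ~0 / sd ~1 on scalar columns
  scaled <- feature_matrix(co, tab, sc)
  expect_lt(max(abs(colMeans(scaled[rows, sc$cols]))), 1e-10)
  # applying to other data never updates the statistics
  co2 <- random_cohort(40, seed = 58)
  invisible(feature_matrix(co2, make_embedding_table(
    parse_codes(co2$records$codes)[c("category", "code")], 8, 1,
    unknown = "zero"), sc))
  expect_identical(sc, snapshot)
  # out-of-range care-site level is a validation error
  bad <- co
  bad$records$care_site_type[1] <- 30L
  expect_error(feature_matrix(bad, tab), "validation error")
})
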