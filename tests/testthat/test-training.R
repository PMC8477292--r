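# Direct re-implementation of the gated combination used as an oracle.
direct_combination <- function(G, V_list) {
  out <- G
  for (V in V_list) {
    den <- sqrt(sum(G^2)) * sqrt(sum(V^2))
    cosgv <- if (den == 0) 0 else sum(G * V) / den
    out <- out + max(0, cosgv) * V
  }
  out
}

test_that("the cosine gate passes aligned and blocks conflicting gradients", {
  G <- c(1, 0, 0)
  expect_equal(combine_gradients(G, list(c(0, 1, 0))), G)      # orthogonal
  expect_equal(combine_gradients(G, list(G)), 2 * G)           # aligned
  expect_equal(combine_gradients(G, list(-G)), G)              # anti-aligned
  expect_equal(combine_gradients(G, list()), G)                # single-task
  expect_equal(combine_gradients(G, list(numeric(3))), G)      # zero vector
  expect_equal(combine_gradients(numeric(3), list(c(1, 1, 1))), numeric(3))
  expect_error(combine_gradients(G, list(c(1, 2))), "length mismatch")
})

test_that("gated-out auxiliaries leave the combination unchanged", {
  set.seed(19)
  for (i in 1:20) {
    G <- stats::rnorm(40)
    V_keep <- lapply(1:2, function(j) stats::rnorm(40))
    V_conf <- -G * stats::runif(1, 0.5, 2) + stats::rnorm(40, sd = 1e-3)
    if (sum(G * V_conf) >= 0) next
    expect_equal(combine_gradients(G, c(V_keep, list(V_conf))),
                 combine_gradients(G, V_keep))
  }
})

test_that("combine_gradients matches the direct formula on random bundles", {
  set.seed(23)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    G <- stats::rnorm(n)
    V_list <- lapply(seq_len(sample(1:6, 1)), function(j) stats::rnorm(n))
    got <- combine_gradients(G, V_list)
    want <- direct_combination(G, V_list)
    expect_lt(max(abs(got - want)) / max(1, max(abs(want))), 1e-12)
  }
})

test_that("weighted loss is the weight-normalized sum", {
  l <- c(1, 2, 3, 4)
  ca <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(weighted_task_loss(l, ca, 1, 1), mean(l))
  # constant weights cancel through the normalization
  expect_equal(weighted_task_loss(l, rep(TRUE, 4), 5, 1), mean(l))
  # mixed batch equals the brute-force weighted mean
  w <- ifelse(ca, 5, 1)
  expect_equal(weighted_task_loss(l, ca, 5, 1), sum(w * l) / sum(w))
  set.seed(29)
  for (i in 1:20) {
    l <- stats::runif(10); ca <- stats::runif(10) < 0.3
    wp <- stats::runif(1, 1, 10)
    w <- ifelse(ca, wp, 1)
    expect_equal(weighted_task_loss(l, ca, wp, 1), sum(w * l) / sum(w))
  }
  expect_error(weighted_task_loss(numeric(0), logical(0), 1, 1), "empty")
})

test_that("upsampling replicates positive persons exactly rate times", {
  ids <- paste0("p", 1:20)
  pos <- c("p3", "p11")
  # rate 1: a permutation of the input
  expect_equal(sort(upsample_batch(ids, pos, 1, seed = 1)), sort(ids))
  out <- upsample_batch(ids, pos, 10, seed = 2)
  expect_length(out, 18 + 10 * 2)
  expect_equal(sum(out == "p3"), 10L)
  expect_equal(sum(out == "p11"), 10L)
  expect_equal(sum(out == "p1"), 1L)
  # counting identity for random rates
  set.seed(31)
  for (i in 1:10) {
    rate <- sample(1:12, 1)
    pos_i <- sample(ids, sample(0:5, 1))
    out_i <- upsample_batch(ids, pos_i, rate)
    expect_length(out_i, (20 - length(pos_i)) + rate * length(pos_i))
  }
})

test_that("split_cohort partitions persons 70/15/15", {
  ids <- paste0("p", 1:100)
  sp <- split_cohort(ids, seed = 7)
  expect_length(sp$train, 70L)
  expect_length(sp$validation, 15L)
  expect_length(sp$test, 15L)
  expect_equal(sort(c(sp$train, sp$validation, sp$test)), sort(ids))
  expect_length(intersect(sp$train, sp$validation), 0L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_length(intersect(sp$validation, sp$test), 0L)
  expect_error(split_cohort(paste0("p", 1:2)), "smaller than 3")
  # reproducible and seed-sensitive
  expect_identical(sp, split_cohort(ids, seed = 7))
  expect_false(identical(sp$train, split_cohort(ids, seed = 8)$train))
})

test_that("training descends on a convex problem with a random auxiliary", {
  # logistic regression as the main task; the gated combination with an
  # arbitrary auxiliary direction must still drive the main loss down
  set.seed(37)
  n <- 200
  X <- cbind(1, matrix(stats::rnorm(n * 3), n, 3))
  beta_true <- c(-0.5, 1, -2, 0.5)
  y <- stats::rbinom(n, 1, stats::plogis(X %*% beta_true))
  beta <- numeric(4)
  nll <- function(b) mean(log1p(exp(X %*% b)) - y * (X %*% b))
  losses <- numeric(60)
  for (it in 1:60) {
    p <- stats::plogis(X %*% beta)
    G <- crossprod(X, p - y) / n
    V <- stats::rnorm(4)
    beta <- beta - 0.5 * combine_gradients(as.numeric(G), list(V))
    losses[it] <- nll(beta)
  }
  expect_lt(losses[60], nll(numeric(4)))
  # eventual monotone trend: the last quarter is no worse than the first
  expect_lt(mean(tail(losses, 15)), mean(head(losses, 15)))
})

test_that("fits are bitwise reproducible under a fixed seed", {
  co <- random_cohort(120, seed = 61)
  f1 <- hvec(co, "mortality", multitask = TRUE, params = tiny_params(3),
             max_epochs = 2, batch_persons = 16, seed = 3)
  f2 <- hvec(co, "mortality", multitask = TRUE, params = tiny_params(3),
             max_epochs = 2, batch_persons = 16, seed = 3)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$fitted$score, f2$fitted$score)
  f3 <- hvec(co, "mortality", multitask = TRUE, params = tiny_params(4),
             max_epochs = 2, batch_persons = 16, seed = 4)
  expect_false(identical(coef(f1), coef(f3)))
})

test_that("upsampling and weighting touch only training batches", {
  co <- random_cohort(150, seed = 67)
  f <- hvec(co, "mortality", multitask = FALSE, upsampling_rate = 8,
            event_weight = 5, params = tiny_params(5), max_epochs = 1,
            batch_persons = 16, seed = 5)
  for (s in c("validation", "test")) {
    rows <- f$fitted[f$fitted$split == s, ]
    expect_equal(anyDuplicated(rows$record_id), 0L)
    expect_setequal(unique(rows$person_id), f$split[[
      if (s == "validation") "validation" else "test"]])
  }
  # no person straddles splits in the scored table
  tab <- table(f$fitted$person_id,
               f$fitted$split)
  expect_true(all(rowSums(tab > 0) == 1L))
})

test_that("the readmission task trains and scores only eligible records", {
  co <- random_cohort(150, seed = 71)
  f <- hvec(co, "readmission", multitask = FALSE, params = tiny_params(6),
            max_epochs = 1, batch_persons = 16, seed = 6)
  lab <- label_cohort(co)
  elig <- lab$record_id[!is.na(lab$readmission_30d)]
  scored <- f$fitted$record_id[!is.na(f$fitted$label)]
  expect_setequal(scored, elig)
  expect_true(all(f$metrics$n_records <=
                    c(length(elig), sum(lab$is_ca[!is.na(lab$readmission_30d)]))))
})
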