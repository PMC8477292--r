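# Network contracts: shapes, determinism, step/batch equivalence, causality,
# parameter audit, and exactness of the analytic gradients.

test_that("encoder and heads have the reference shapes", {
  params <- hvec_params()  # defaults: 707 -> 200 -> 128 -> heads
  w <- init_weights(params)
  x <- with_seed(1, stats::rnorm(707))
  e <- encode_record(x, w)
  expect_length(e, 200L)
  st <- step_person(list(hidden = numeric(128), cell = numeric(128)), e, w)
  expect_length(st$person_vector, 128L)
  heads <- predict_heads(st$person_vector, w)
  expect_length(heads, 8L)
  expect_length(heads$reconstruction_codes, 640L)
  expect_length(heads$reconstruction_context, 48L)
  expect_length(heads$reconstruction_history, 19L)
  # head spans partition the 707-dim input
  expect_equal(640L + 48L + 19L, 707L)
})

test_that("trainable parameter count equals the closed form", {
  params <- hvec_params()
  w <- init_weights(params)
  expected <- (707 + 1) * 200 +          # record encoder
    4 * (200 + 128 + 1) * 128 +          # LSTM gates
    (128 + 1) * (1 + 1 + 640 + 48 + 19 + 1 + 1 + 1)  # heads
  expect_equal(count_parameters(w), expected)

  p2 <- tiny_params()
  w2 <- init_weights(p2)
  d_in <- 5 * 8 + 67
  expect_equal(count_parameters(w2),
               (d_in + 1) * 12 + 4 * (12 + 8 + 1) * 8 +
                 (8 + 1) * (5 * 8 + 72))
})

test_that("evaluation mode is deterministic, training dropout is stochastic", {
  params <- tiny_params()
  w <- init_weights(params)
  x <- with_seed(2, stats::rnorm(5 * 8 + 67))
  expect_identical(encode_record(x, w), encode_record(x, w))
  outs <- with_seed(3, list(encode_record(x, w, training = TRUE),
                            encode_record(x, w, training = TRUE)))
  expect_false(identical(outs[[1]], outs[[2]]))
})

test_that("zero state, zero embedding and zero biases give a zero person vector", {
  params <- tiny_params()
  w <- init_weights(params)
  st <- step_person(list(hidden = numeric(8), cell = numeric(8)),
                    numeric(12), w)
  expect_equal(st$person_vector, rep(0, 8))
  expect_error(step_person(list(hidden = numeric(5), cell = numeric(8)),
                           numeric(12), w), "validation error")
})

test_that("a zero person vector exposes the head biases exactly", {
  params <- tiny_params()
  w <- init_weights(params)
  w$b_out <- seq_along(w$b_out) / 100
  heads <- predict_heads(numeric(8), w)
  expect_equal(heads$mortality_logit, 0.01)
  expect_equal(unname(unlist(heads, use.names = FALSE)),
               seq_along(w$b_out) / 100)
})

test_that("record-by-record stepping equals the batched forward pass", {
  params <- tiny_params()
  w <- init_weights(params)
  d_in <- 5 * 8 + 67
  X <- with_seed(5, matrix(stats::rnorm(9 * d_in), 9, d_in))
  seqs <- list(a = 1:4, b = 5:6, c = 7:9)
  cache <- forward_batch(X, seqs, w, training = FALSE)
  row <- 0L
  for (p in seq_along(seqs)) {
    st <- list(hidden = numeric(8), cell = numeric(8))
    for (i in seqs[[p]]) {
      e <- encode_record(X[i, ], w)
      st2 <- step_person(st, e, w)
      row <- row + 1L
      expect_equal(unname(cache$H_all[row, ]),
                   unname(st2$person_vector), tolerance = 1e-12)
      heads <- predict_heads(st2$person_vector, w)
      expect_equal(cache$Z[row, 1], heads$mortality_logit,
                   tolerance = 1e-12)
      st <- st2$state
    }
  }
})

test_that("predictions at record t ignore all later records", {
  params <- tiny_params()
  w <- init_weights(params)
  d_in <- 5 * 8 + 67
  X <- with_seed(6, matrix(stats::rnorm(6 * d_in), 6, d_in))
  full <- forward_batch(X, list(p = 1:6), w)
  X2 <- X
  X2[5:6, ] <- X2[5:6, ] + 10  # perturb the future
  pert <- forward_batch(X2, list(p = 1:6), w)
  expect_equal(full$Z[1:4, ], pert$Z[1:4, ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(full$Z[5, ], pert$Z[5, ])))
})

test_that("analytic gradients match central finite differences", {
  params <- hvec_params(visit_embed_size = 6, rnn_output_size = 5,
                        code_embed_size = 4, dropout_rate = 0,
                        init_seed = 9)
  w <- init_weights(params)
  d_in <- 5 * 4 + 67
  X <- with_seed(7, matrix(stats::rnorm(5 * d_in), 5, d_in))
  attr(X, "layout") <- feature_layout(4L)
  seqs <- list(a = 1:3, b = 4:5)
  y <- c(1, 0, 0, 1, 0)
  ca <- c(TRUE, FALSE, FALSE, FALSE, TRUE)
  wt <- ifelse(ca, 3, 1); wt <- wt / sum(wt)

  loss_of <- function(wts) {
    cache <- forward_batch(X, seqs, wts, training = FALSE)
    z <- cache$Z[, 1]
    sum(wt * (pmax(z, 0) - y * z + log1p(exp(-abs(z)))))
  }
  cache <- forward_batch(X, seqs, w, training = FALSE)
  z <- cache$Z[, 1]
  dz <- matrix(wt * (stats::plogis(z) - y), ncol = 1)
  G <- backward_task(cache, w, dz, 1L)

  flat <- hvec:::flatten_weights(w)
  set.seed(11)
  idx <- sort(sample(length(flat), 60))
  eps <- 1e-5
  for (i in idx) {
    up <- flat; up[i] <- up[i] + eps
    dn <- flat; dn[i] <- dn[i] - eps
    num <- (loss_of(hvec:::unflatten_weights(up, w)) -
              loss_of(hvec:::unflatten_weights(dn, w))) / (2 * eps)
    expect_equal(G[i], num, tolerance = 1e-5)
  }

  # reconstruction-head gradient too
  rin <- hvec:::recon_input_cols(feature_layout(4L))$recon_context
  cols <- hvec:::head_cols(4L, "recon_context")
  loss_rec <- function(wts) {
    cache <- forward_batch(X, seqs, wts, training = FALSE)
    pred <- cache$Z[, cols, drop = FALSE]
    sum(wt * rowMeans((pred - X[, rin, drop = FALSE])^2))
  }
  pred <- cache$Z[, cols, drop = FALSE]
  dzr <- (pred - X[, rin, drop = FALSE]) * (2 * wt / length(cols))
  Gr <- backward_task(cache, w, dzr, cols)
  for (i in idx[1:20]) {
    up <- flat; up[i] <- up[i] + eps
    dn <- flat; dn[i] <- dn[i] - eps
    num <- (loss_rec(hvec:::unflatten_weights(up, w)) -
              loss_rec(hvec:::unflatten_weights(dn, w))) / (2 * eps)
    expect_equal(Gr[i], num, tolerance = 1e-5)
  }
})

test_that("weight decay touches weight matrices, never biases", {
  params <- tiny_params()
  w <- init_weights(params)
  mask <- hvec:::weight_decay_mask(w)
  flat <- hvec:::flatten_weights(w)
  expect_length(mask, length(flat))
  # bias positions are exactly the zero-mask positions
  sizes <- vapply(unclass(w), length, numeric(1))
  is_bias <- rep(grepl("^b_", hvec:::weight_names), sizes[hvec:::weight_names])
  expect_equal(mask == 0, is_bias)
  # at zero task gradient the update direction is pure decay: biases fixed
  dir <- combine_gradients(numeric(length(flat)), list()) +
    params$l2_weight * mask * flat
  expect_true(all(dir[is_bias] == 0))
  expect_true(all(dir[!is_bias] == params$l2_weight * flat[!is_bias]))
})
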