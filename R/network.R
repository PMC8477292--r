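# The HVec network: a fully-connected record encoder producing a record
# embedding, an LSTM updating a per-person state record by record, and one
# affine head per task read off the person vector at every step. Forward and
# backward passes are written in base R matrix code; gradients are exact
# (verified against finite differences in the test suite).

#' Network hyperparameters
#'
#' Sizes and optimization constants of the HVec network. Defaults are the
#' reference configuration: visit embedding 200, recurrent output 128,
#' learning rate 1e-3, dropout 0.5, L2 weight 0.01, code embedding 128.
#'
#' @param visit_embed_size Record-encoder output size.
#' @param rnn_output_size LSTM hidden/person-vector size.
#' @param learning_rate Adam step size.
#' @param dropout_rate Dropout probability on the encoder output (training
#'   mode only).
#' @param l2_weight L2 penalty coefficient on weight matrices (never on
#'   biases).
#' @param code_embed_size Code-embedding dimension; fixes the input width
#'   `5 * code_embed_size + 67` (707 at the default 128).
#' @param init_seed Seed for weight initialization.
#' @return A list of class `hvec_params`.
#' @export
hvec_params <- function(visit_embed_size = 200L, rnn_output_size = 128L,
                        learning_rate = 1e-3, dropout_rate = 0.5,
                        l2_weight = 0.01, code_embed_size = 128L,
                        init_seed = 1L) {
  p <- list(visit_embed_size = as.integer(visit_embed_size),
            rnn_output_size = as.integer(rnn_output_size),
            learning_rate = learning_rate,
            dropout_rate = dropout_rate,
            l2_weight = l2_weight,
            code_embed_size = as.integer(code_embed_size),
            init_seed = as.integer(init_seed))
  stopifnot(p$visit_embed_size >= 1L, p$rnn_output_size >= 1L,
            p$code_embed_size >= 1L,
            p$dropout_rate >= 0, p$dropout_rate < 1,
            p$learning_rate > 0, p$l2_weight >= 0)
  class(p) <- "hvec_params"
  p
}

#' Head output layout
#'
#' Span lengths of the concatenated head outputs: the two main-task logits,
#' three reconstruction heads partitioning the input vector (code
#' embeddings / demographic + care-site context / statistics + history),
#' the two cost regressions, and the IHCA-record logit. At
#' `code_dim = 128`: 1 + 1 + 640 + 48 + 19 + 1 + 1 + 1.
#'
#' @param code_dim Code-embedding dimension.
#' @return Named integer vector of head span lengths.
#' @export
head_layout <- function(code_dim = 128L) {
  c(mortality = 1L, readmission = 1L,
    recon_codes = 5L * code_dim, recon_context = 48L, recon_history = 19L,
    cost_current = 1L, cost_future = 1L, ihca = 1L)
}

input_size <- function(code_dim) 5L * code_dim + 67L

head_cols <- function(code_dim, head) span_cols(head_layout(code_dim), head)

# input-vector column groups reconstructed by the three autoencoder heads
recon_input_cols <- function(layout) {
  list(recon_codes = unlist(lapply(code_categories(), span_cols,
                                   layout = layout)),
       recon_context = unlist(lapply(
         c("claim_type", "age", "gender", "care_site_type",
           "care_site_specialization", "care_site_rank"),
         span_cols, layout = layout)),
       recon_history = unlist(lapply(
         c("hospital_stay", "total_cost", "total_count",
           "past_hospitalization_duration", "past_admission_count"),
         span_cols, layout = layout)))
}

#' Initialize network weights
#'
#' Uniform Glorot initialization of all weight matrices, zero biases; fully
#' determined by `params$init_seed`.
#'
#' @param params An [hvec_params()].
#' @return Named list of parameter arrays (class `hvec_weights`).
#' @export
init_weights <- function(params) {
  d_in <- input_size(params$code_embed_size)
  V <- params$visit_embed_size
  H <- params$rnn_output_size
  P <- sum(head_layout(params$code_embed_size))
  glorot <- function(nr, nc) {
    r <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -r, r), nr, nc)
  }
  w <- with_seed(params$init_seed, list(
    W_enc = glorot(d_in, V), b_enc = numeric(V),
    W_x = glorot(V, 4L * H), W_h = glorot(H, 4L * H),
    b_lstm = numeric(4L * H),
    W_out = glorot(H, P), b_out = numeric(P)))
  attr(w, "params") <- params
  class(w) <- "hvec_weights"
  w
}

#' Count trainable parameters
#'
#' @param w An [init_weights()] result.
#' @return Total number of scalar parameters.
#' @export
count_parameters <- function(w) {
  sum(vapply(unclass(w), length, numeric(1)))
}

weight_names <- c("W_enc", "b_enc", "W_x", "W_h", "b_lstm", "W_out", "b_out")

flatten_weights <- function(w) {
  unlist(lapply(weight_names, function(nm) as.numeric(w[[nm]])),
         use.names = FALSE)
}

unflatten_weights <- function(v, template) {
  out <- template
  pos <- 0L
  for (nm in weight_names) {
    n <- length(template[[nm]])
    out[[nm]][] <- v[pos + seq_len(n)]
    pos <- pos + n
  }
  out
}

# 1 for entries of weight matrices, 0 for biases; L2 decay applies to the
# former only.
weight_decay_mask <- function(w) {
  unlist(lapply(weight_names, function(nm) {
    rep(as.numeric(is.matrix(w[[nm]])), length(w[[nm]]))
  }), use.names = FALSE)
}

sigmoid <- function(x) stats::plogis(x)

#' Encode one record
#'
#' The record encoder: a single affine map plus tanh nonlinearity, with
#' inverted dropout on the output in training mode.
#'
#' @param x Record feature vector (length `5 * code_embed_size + 67`).
#' @param w Network weights.
#' @param training Apply dropout? Evaluation mode is deterministic.
#' @return Record embedding of length `visit_embed_size`.
#' @export
encode_record <- function(x, w, training = FALSE) {
  params <- attr(w, "params")
  e <- tanh(drop(x %*% w$W_enc) + w$b_enc)
  if (training && params$dropout_rate > 0) {
    keep <- 1 - params$dropout_rate
    e <- e * (stats::runif(length(e)) < keep) / keep
  }
  e
}

#' Advance the person state by one record
#'
#' One LSTM step with standard gates (sigmoid input/forget/output, tanh
#' candidate). The emitted person vector is the new hidden state.
#'
#' @param state List with `hidden`, `cell` (zeros at sequence start), each
#'   of length `rnn_output_size`.
#' @param emb Record embedding from [encode_record()].
#' @param w Network weights.
#' @return List with `state` (updated) and `person_vector`.
#' @export
step_person <- function(state, emb, w) {
  H <- length(state$hidden)
  if (length(state$cell) != H || ncol(w$W_h) != 4L * H) {
    stop("validation error: state dimensions do not match weights")
  }
  a <- drop(emb %*% w$W_x) + drop(state$hidden %*% w$W_h) + w$b_lstm
  i <- sigmoid(a[seq_len(H)])
  f <- sigmoid(a[H + seq_len(H)])
  g <- tanh(a[2L * H + seq_len(H)])
  o <- sigmoid(a[3L * H + seq_len(H)])
  cell <- f * state$cell + i * g
  hidden <- o * tanh(cell)
  list(state = list(hidden = hidden, cell = cell), person_vector = hidden)
}

#' Apply all prediction heads
#'
#' Each head is an independent affine map from the person vector: logits
#' for the classification heads, linear outputs for reconstructions and
#' cost regressions.
#'
#' @param person_vector Hidden state from [step_person()].
#' @param w Network weights.
#' @return Named list: `mortality_logit`, `readmission_logit`,
#'   `reconstruction_codes`, `reconstruction_context`,
#'   `reconstruction_history`, `current_cost_pred`, `future_cost_pred`,
#'   `ihca_logit`.
#' @export
predict_heads <- function(person_vector, w) {
  params <- attr(w, "params")
  d <- params$code_embed_size
  z <- drop(person_vector %*% w$W_out) + w$b_out
  list(mortality_logit = unname(z[head_cols(d, "mortality")]),
       readmission_logit = unname(z[head_cols(d, "readmission")]),
       reconstruction_codes = unname(z[head_cols(d, "recon_codes")]),
       reconstruction_context = unname(z[head_cols(d, "recon_context")]),
       reconstruction_history = unname(z[head_cols(d, "recon_history")]),
       current_cost_pred = unname(z[head_cols(d, "cost_current")]),
       future_cost_pred = unname(z[head_cols(d, "cost_future")]),
       ihca_logit = unname(z[head_cols(d, "ihca")]))
}

# Batched forward pass over a batch of person sequences.
#
# X: feature matrix (rows indexable by seq_list); seq_list: per-person
# integer row indices in record order. Returns the cache needed for
# per-task backward passes. Record r of person p occupies output row
# offset[p] + r (person-major order).
forward_batch <- function(X, seq_list, w, training = FALSE) {
  params <- attr(w, "params")
  B <- length(seq_list)
  lens <- lengths(seq_list)
  rows <- unlist(seq_list, use.names = FALSE)
  offs <- cumsum(c(0L, lens[-B]))
  Nb <- length(rows)
  V <- params$visit_embed_size
  H <- params$rnn_output_size

  Xb <- X[rows, , drop = FALSE]
  E_pre <- tanh(Xb %*% w$W_enc + rep(w$b_enc, each = Nb))
  if (training && params$dropout_rate > 0) {
    keep <- 1 - params$dropout_rate
    mask <- matrix((stats::runif(Nb * V) < keep) / keep, Nb, V)
    E <- E_pre * mask
  } else {
    mask <- NULL
    E <- E_pre
  }

  Tmax <- max(lens)
  Hmat <- matrix(0, B, H)
  Cmat <- matrix(0, B, H)
  H_all <- matrix(0, Nb, H)
  steps <- vector("list", Tmax)
  for (t in seq_len(Tmax)) {
    act <- which(lens >= t)
    erow <- offs[act] + t
    A <- E[erow, , drop = FALSE] %*% w$W_x +
      Hmat[act, , drop = FALSE] %*% w$W_h +
      rep(w$b_lstm, each = length(act))
    i <- sigmoid(A[, seq_len(H), drop = FALSE])
    f <- sigmoid(A[, H + seq_len(H), drop = FALSE])
    g <- tanh(A[, 2L * H + seq_len(H), drop = FALSE])
    o <- sigmoid(A[, 3L * H + seq_len(H), drop = FALSE])
    steps[[t]] <- list(act = act, erow = erow,
                       H_prev = Hmat[act, , drop = FALSE],
                       C_prev = Cmat[act, , drop = FALSE],
                       i = i, f = f, g = g, o = o)
    cc <- f * steps[[t]]$C_prev + i * g
    tc <- tanh(cc)
    steps[[t]]$tanhc <- tc
    hh <- o * tc
    Cmat[act, ] <- cc
    Hmat[act, ] <- hh
    H_all[erow, ] <- hh
  }
  Z <- H_all %*% w$W_out + rep(w$b_out, each = Nb)
  list(Xb = Xb, E_pre = E_pre, E = E, mask = mask, steps = steps,
       H_all = H_all, Z = Z, lens = lens, offs = offs, B = B, Nb = Nb)
}

# Backward pass for one task: dZc is the gradient of the task loss w.r.t.
# the head columns `cols` of Z. Returns the flat gradient over all
# parameters (zeros outside the task's head columns of W_out/b_out).
backward_task <- function(cache, w, dZc, cols) {
  params <- attr(w, "params")
  H <- params$rnn_output_size
  Nb <- cache$Nb
  gW_out <- matrix(0, nrow = H, ncol = ncol(w$W_out))
  gb_out <- numeric(length(w$b_out))
  gW_out[, cols] <- crossprod(cache$H_all, dZc)
  gb_out[cols] <- colSums(dZc)
  dH_all <- dZc %*% t(w$W_out[, cols, drop = FALSE])

  B <- cache$B
  gW_x <- matrix(0, nrow(w$W_x), ncol(w$W_x))
  gW_h <- matrix(0, nrow(w$W_h), ncol(w$W_h))
  gb_lstm <- numeric(length(w$b_lstm))
  dE <- matrix(0, Nb, nrow(w$W_x))
  dH_acc <- matrix(0, B, H)
  dC_acc <- matrix(0, B, H)
  for (t in rev(seq_along(cache$steps))) {
    st <- cache$steps[[t]]
    act <- st$act
    dH <- dH_acc[act, , drop = FALSE] + dH_all[st$erow, , drop = FALSE]
    do <- dH * st$tanhc
    dC <- dC_acc[act, , drop = FALSE] + dH * st$o * (1 - st$tanhc^2)
    di <- dC * st$g
    df <- dC * st$C_prev
    dg <- dC * st$i
    dA <- cbind(di * st$i * (1 - st$i), df * st$f * (1 - st$f),
                dg * (1 - st$g^2), do * st$o * (1 - st$o))
    Et <- cache$E[st$erow, , drop = FALSE]
    gW_x <- gW_x + crossprod(Et, dA)
    gW_h <- gW_h + crossprod(st$H_prev, dA)
    gb_lstm <- gb_lstm + colSums(dA)
    dE[st$erow, ] <- dA %*% t(w$W_x)
    dH_acc[act, ] <- dA %*% t(w$W_h)
    dC_acc[act, ] <- dC * st$f
  }
  dE_pre <- if (is.null(cache$mask)) dE else dE * cache$mask
  da <- dE_pre * (1 - cache$E_pre^2)
  gW_enc <- crossprod(cache$Xb, da)
  gb_enc <- colSums(da)
  c(as.numeric(gW_enc), gb_enc, as.numeric(gW_x), as.numeric(gW_h),
    gb_lstm, as.numeric(gW_out), gb_out)
}
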