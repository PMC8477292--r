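# Multitask training: per batch, the main-task gradient G is combined with
# each auxiliary-task gradient V_i through a cosine gate -- an auxiliary
# gradient contributes only in proportion to max(0, cos(G, V_i)), so
# conflicting auxiliary directions are dropped entirely. Class imbalance is
# countered by replicating CA-positive persons inside training batches and
# weighting CA records in every task loss.

#' Cosine-gated gradient combination
#'
#' Returns `G + sum_i max(0, cos(G, V_i)) * V_i`: each auxiliary gradient is
#' scaled by its cosine similarity to the main-task gradient when the two
#' agree, and gated out entirely when they conflict (negative cosine) or are
#' orthogonal. The cosine with a zero vector is defined as 0. The caller
#' applies `theta <- theta - alpha * direction`.
#'
#' @param G Flat main-task gradient over all parameters.
#' @param V_list List of flat auxiliary-task gradients (same length as
#'   `G`); empty in single-task mode.
#' @return The combined update direction.
#' @export
combine_gradients <- function(G, V_list = list()) {
  out <- G
  nG <- sqrt(sum(G * G))
  for (V in V_list) {
    if (length(V) != length(G)) {
      stop("validation error: gradient length mismatch")
    }
    nV <- sqrt(sum(V * V))
    cosgv <- if (nG == 0 || nV == 0) 0 else sum(G * V) / (nG * nV)
    if (cosgv > 0) out <- out + cosgv * V
  }
  out
}

#' CA-weighted task loss
#'
#' Weighted mean of per-record losses with weight `w_pos` on CA records and
#' `w_neg` on the rest, normalized by the total weight: `sum(w*L)/sum(w)`.
#' Under equal weights this is the plain mean; on an all-CA batch the
#' normalization cancels the weight entirely.
#'
#' @param losses Per-record losses.
#' @param is_ca Logical CA-record indicator, aligned with `losses`.
#' @param w_pos,w_neg Weights of the CA (emphasized) and non-CA class;
#'   `w_neg` is fixed at 1 in the reference experiments.
#' @return Scalar loss.
#' @export
weighted_task_loss <- function(losses, is_ca, w_pos = 1, w_neg = 1) {
  if (length(losses) == 0L) stop("empty loss list")
  stopifnot(length(is_ca) == length(losses), w_pos > 0, w_neg > 0)
  w <- ifelse(is_ca, w_pos, w_neg)
  sum(w * losses) / sum(w)
}

#' Upsample CA-positive persons within a batch
#'
#' Persons in `positive_ids` appear `rate` times in the returned batch,
#' everyone else once; the result is shuffled. `rate = 1` returns a
#' permutation of the input (no upsampling).
#'
#' @param ids Person ids in the batch.
#' @param positive_ids Ids of persons carrying CA-positive records.
#' @param rate Integer replication factor (>= 1).
#' @param seed Optional seed; by default the current RNG stream is used.
#' @return Character vector of person ids, length
#'   `n_non_positive + rate * n_positive`.
#' @export
upsample_batch <- function(ids, positive_ids, rate = 1L, seed = NULL) {
  stopifnot(rate >= 1L)
  pos <- ids %in% positive_ids
  out <- c(ids[!pos], rep(ids[pos], each = as.integer(rate)))
  if (is.null(seed)) sample(out) else with_seed(seed, sample(out))
}

#' Person-level train/validation/test split
#'
#' Partitions persons (never records) into three disjoint sets with the
#' given proportions (sizes exact up to rounding; default 70/15/15).
#'
#' @param x An `hvec_cohort` or a vector of person ids.
#' @param fractions Three non-negative fractions summing to 1.
#' @param seed Shuffling seed.
#' @return Named list `train`, `validation`, `test` of person ids.
#' @export
split_cohort <- function(x, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  ids <- if (inherits(x, "hvec_cohort")) x$persons$person_id else x
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-8)
  n <- length(ids)
  if (n < 3L) stop("cohort smaller than 3 persons cannot be split")
  perm <- with_seed(seed, sample(ids))
  bounds <- round(cumsum(fractions) * n)
  take <- function(from, to) {
    if (from > to) character(0) else sort(perm[from:to])
  }
  list(train = take(1L, bounds[1L]),
       validation = take(bounds[1L] + 1L, bounds[2L]),
       test = take(bounds[2L] + 1L, n))
}

#' Training configuration
#'
#' @param multitask Combine the six auxiliary-task gradients with the main
#'   task via [combine_gradients()]? `FALSE` trains the main head alone.
#' @param upsampling_rate Per-batch replication factor for persons with
#'   CA-positive records (1 = off).
#' @param event_weight `w_pos`, the CA-record loss weight (`w_neg` is 1).
#' @param batch_persons Persons per batch.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience on validation AUROC of the main
#'   task.
#' @param main_task `"mortality"` or `"readmission"`.
#' @param seed Seed governing shuffling, upsampling and dropout.
#' @return A list of class `hvec_control`.
#' @export
hvec_control <- function(multitask = TRUE, upsampling_rate = 1L,
                         event_weight = 1, batch_persons = 64L,
                         max_epochs = 10L, patience = 5L,
                         main_task = c("mortality", "readmission"),
                         seed = 1L) {
  ctl <- list(multitask = isTRUE(as.logical(multitask)),
              upsampling_rate = as.integer(upsampling_rate),
              event_weight = event_weight,
              batch_persons = as.integer(batch_persons),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience),
              main_task = match.arg(main_task),
              seed = as.integer(seed))
  stopifnot(ctl$upsampling_rate >= 1L, ctl$event_weight > 0,
            ctl$batch_persons >= 1L, ctl$max_epochs >= 1L)
  class(ctl) <- "hvec_control"
  ctl
}

aux_task_names <- c("recon_codes", "recon_context", "recon_history",
                    "cost_current", "cost_future", "ihca")

# numerically stable binary cross-entropy from logits
bce_loss <- function(z, y) pmax(z, 0) - y * z + log1p(exp(-abs(z)))

# Per-task losses and head-column gradients for one batch.
#
# tgt: list with y_mort, y_readm (NA = ineligible), is_ca, cost_cur,
# cost_fut (per batch record, person-major order); Xb: the input rows
# (reconstruction targets). Gradients are of the CA-weighted mean loss.
batch_task_grads <- function(cache, tgt, w, w_pos, main_task, multitask) {
  d <- attr(w, "params")$code_embed_size
  Nb <- cache$Nb
  wt <- ifelse(tgt$is_ca, w_pos, 1)
  rin <- recon_input_cols(attr(cache$Xb, "layout"))

  bce_task <- function(head, y) {
    cols <- head_cols(d, head)
    keep <- !is.na(y)
    z <- cache$Z[, cols]
    wn <- ifelse(keep, wt, 0)
    wn <- wn / sum(wn)
    loss <- sum(wn[keep] * bce_loss(z[keep], y[keep]))
    dz <- matrix(0, Nb, 1L)
    dz[keep, 1L] <- wn[keep] * (sigmoid(z[keep]) - y[keep])
    list(loss = loss, dz = dz, cols = cols)
  }
  mse_vec_task <- function(head, target_cols) {
    cols <- head_cols(d, head)
    pred <- cache$Z[, cols, drop = FALSE]
    targ <- cache$Xb[, target_cols, drop = FALSE]
    k <- length(cols)
    wn <- wt / sum(wt)
    resid <- pred - targ
    loss <- sum(wn * rowMeans(resid^2))
    list(loss = loss, dz = resid * (2 * wn / k), cols = cols)
  }
  mse_scalar_task <- function(head, y) {
    cols <- head_cols(d, head)
    z <- cache$Z[, cols]
    wn <- wt / sum(wt)
    loss <- sum(wn * (z - y)^2)
    list(loss = loss, dz = matrix(wn * 2 * (z - y), Nb, 1L), cols = cols)
  }

  out <- list()
  out$main <- if (main_task == "mortality") {
    bce_task("mortality", tgt$y_mort)
  } else {
    bce_task("readmission", tgt$y_readm)
  }
  if (multitask) {
    out$recon_codes <- mse_vec_task("recon_codes", rin$recon_codes)
    out$recon_context <- mse_vec_task("recon_context", rin$recon_context)
    out$recon_history <- mse_vec_task("recon_history", rin$recon_history)
    out$cost_current <- mse_scalar_task("cost_current", tgt$cost_cur)
    out$cost_future <- mse_scalar_task("cost_future", tgt$cost_fut)
    out$ihca <- bce_task("ihca", as.numeric(tgt$is_ca))
  }
  out
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  state$delta <- lr * mhat / (sqrt(vhat) + eps)
  state
}

# Core training loop over featurized data. Runs under the caller's RNG
# stream (hvec() wraps it in with_seed). Returns best-validation weights
# and the per-epoch history.
train_loop <- function(X, seq_train, seq_val, tgt_all, w, ctl) {
  params <- attr(w, "params")
  decay_mask <- weight_decay_mask(w)
  opt <- adam_init(count_parameters(w))
  history <- NULL
  best <- list(auroc = -Inf, w = w, epoch = 0L)
  wait <- 0L
  train_ids <- names(seq_train)
  positive_ids <- tgt_all$positive_ids

  for (epoch in seq_len(ctl$max_epochs)) {
    order_ids <- upsample_batch(train_ids, positive_ids,
                                ctl$upsampling_rate)
    nb <- ceiling(length(order_ids) / ctl$batch_persons)
    loss_sums <- NULL
    for (b in seq_len(nb)) {
      bid <- order_ids[((b - 1L) * ctl$batch_persons + 1L):
                         min(b * ctl$batch_persons, length(order_ids))]
      seqs <- seq_train[bid]
      # longest sequences first to reduce per-step bookkeeping
      seqs <- seqs[order(lengths(seqs), decreasing = TRUE)]
      cache <- forward_batch(X, seqs, w, training = TRUE)
      attr(cache$Xb, "layout") <- attr(X, "layout")
      rows <- unlist(seqs, use.names = FALSE)
      tgt <- list(y_mort = tgt_all$y_mort[rows],
                  y_readm = tgt_all$y_readm[rows],
                  is_ca = tgt_all$is_ca[rows],
                  cost_cur = tgt_all$cost_cur[rows],
                  cost_fut = tgt_all$cost_fut[rows])
      tasks <- batch_task_grads(cache, tgt, w, ctl$event_weight,
                                ctl$main_task, ctl$multitask)
      G <- backward_task(cache, w, tasks$main$dz, tasks$main$cols)
      V_list <- lapply(tasks[setdiff(names(tasks), "main")], function(tk) {
        backward_task(cache, w, tk$dz, tk$cols)
      })
      direction <- combine_gradients(G, V_list)
      direction <- direction + params$l2_weight * decay_mask *
        flatten_weights(w)
      opt <- adam_step(opt, direction, params$learning_rate)
      w <- unflatten_weights(flatten_weights(w) - opt$delta, w)
      loss_b <- vapply(tasks, function(tk) tk$loss, numeric(1))
      loss_sums <- if (is.null(loss_sums)) loss_b else loss_sums + loss_b
    }
    val_scores <- predict_scores(X, seq_val, w, ctl$main_task)
    vrows <- unlist(seq_val, use.names = FALSE)
    vy <- if (ctl$main_task == "mortality") tgt_all$y_mort[vrows] else
      tgt_all$y_readm[vrows]
    keep <- !is.na(vy)
    val_auroc <- if (length(unique(vy[keep])) < 2L) NA_real_ else
      compute_auroc(val_scores[keep], vy[keep])
    hrow <- c(epoch = epoch, loss_sums / nb, val_auroc = val_auroc)
    history <- rbind(history, hrow)
    if (!is.na(val_auroc) && val_auroc > best$auroc) {
      best <- list(auroc = val_auroc, w = w, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= ctl$patience) break
    }
  }
  rownames(history) <- NULL
  if (best$epoch == 0L) {
    # validation AUROC never defined (degenerate split): keep final weights
    best <- list(auroc = NA_real_, w = w, epoch = nrow(history))
  }
  list(weights = best$w, history = as.data.frame(history),
       best_epoch = best$epoch, best_val_auroc = best$auroc,
       final_weights = w)
}

# main-task probabilities for a list of person sequences (evaluation mode)
predict_scores <- function(X, seq_list, w, main_task,
                           chunk_persons = 256L) {
  d <- attr(w, "params")$code_embed_size
  cols <- head_cols(d, main_task)
  n <- sum(lengths(seq_list))
  out <- numeric(n)
  pos <- 0L
  idx <- seq_along(seq_list)
  for (chunk in split(idx, ceiling(idx / chunk_persons))) {
    cache <- forward_batch(X, seq_list[chunk], w, training = FALSE)
    z <- cache$Z[, cols]
    out[pos + seq_along(z)] <- sigmoid(z)
    pos <- pos + length(z)
  }
  out
}
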