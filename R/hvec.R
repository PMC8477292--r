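#' Fit the hierarchical vectorizer model
#'
#' Trains the HVec network on a claims cohort for one main task (30-day
#' mortality or 30-day readmission). The pipeline: label the cohort, split
#' persons 70/15/15, build the deterministic code-embedding table from the
#' cohort vocabulary, featurize records (scaler fitted on the training split
#' only), then run the multitask training loop with cosine-gated auxiliary
#' gradients, per-batch upsampling of CA-positive persons, and CA record
#' weighting. Validation AUROC of the main task drives early stopping; the
#' best-validation weights are kept.
#'
#' @param cohort An [cohort()] object (e.g. from [generate_cohort()]).
#' @param task Main task: `"mortality"` or `"readmission"`.
#' @param multitask Train with the six auxiliary tasks (reconstructions,
#'   cost regressions, IHCA classification)? `FALSE` trains the main head
#'   alone.
#' @param upsampling_rate Per-batch replication of persons with CA-positive
#'   records (1 = off); applied to training batches only.
#' @param event_weight CA-record loss weight `w_pos` (`w_neg` = 1); applied
#'   to training losses only.
#' @param params An [hvec_params()]; `init_seed` defaults to `seed`.
#' @param max_epochs,patience,batch_persons Training-loop controls, see
#'   [hvec_control()].
#' @param drop_mortality_records Exclude mortality-flagged records from the
#'   analysis set instead of keeping them as negatives.
#' @param seed Seed governing the split, embeddings, initialization,
#'   shuffling, upsampling and dropout; fits are reproducible bit-for-bit.
#' @return An object of class `hvec` with `print`, `summary`, `coef`,
#'   `predict`, `plot`, `fitted` and `residuals` methods.
#' @examples
#' cohort <- generate_cohort(generator_config(n_persons = 120, seed = 7))
#' fit <- hvec(cohort, task = "mortality", multitask = FALSE,
#'             params = hvec_params(visit_embed_size = 16,
#'                                  rnn_output_size = 8,
#'                                  code_embed_size = 8),
#'             max_epochs = 1, seed = 7)
#' fit
#' @export
hvec <- function(cohort, task = c("mortality", "readmission"),
                 multitask = TRUE, upsampling_rate = 1L, event_weight = 1,
                 params = NULL, max_epochs = 10L, patience = 5L,
                 batch_persons = 64L, drop_mortality_records = FALSE,
                 seed = 1L) {
  stopifnot(inherits(cohort, "hvec_cohort"))
  task <- match.arg(task)
  if (is.null(params)) params <- hvec_params(init_seed = seed)
  ctl <- hvec_control(multitask = multitask,
                      upsampling_rate = upsampling_rate,
                      event_weight = event_weight,
                      batch_persons = batch_persons,
                      max_epochs = max_epochs, patience = patience,
                      main_task = task, seed = seed)

  labels <- label_cohort(cohort)
  split <- split_cohort(cohort, seed = seed)
  vocab <- parse_codes(cohort$records$codes)[c("category", "code")]
  table <- make_embedding_table(vocab, dimension = params$code_embed_size,
                                seed = seed, unknown = "zero")
  Xraw <- feature_matrix(cohort, table)
  train_rows <- which(cohort$records$person_id %in% split$train)
  scaler <- fit_scaler(Xraw, train_rows)
  X <- apply_scaler_keep(Xraw, scaler)

  tgt_all <- build_targets(cohort, labels, train_rows)
  keep_row <- if (drop_mortality_records) {
    !cohort$records$discharge_dead_or_critical
  } else rep(TRUE, nrow(cohort$records))
  seqs <- split(which(keep_row), cohort$records$person_id[keep_row])
  seqs <- seqs[lengths(seqs) > 0L]
  seq_of <- function(ids) seqs[names(seqs) %in% ids]
  seq_train <- seq_of(split$train)
  seq_val <- seq_of(split$validation)
  seq_test <- seq_of(split$test)
  if (!length(seq_train) || !length(seq_val) || !length(seq_test)) {
    stop("empty split: cohort too small for a 70/15/15 person split")
  }

  # persons (in the training split) carrying a CA-positive main-task record
  main_y <- if (task == "mortality") tgt_all$y_mort else tgt_all$y_readm
  capos <- tgt_all$is_ca & !is.na(main_y) & main_y == 1L
  tgt_all$positive_ids <- intersect(
    unique(cohort$records$person_id[capos]), split$train)

  w0 <- init_weights(params)
  res <- with_seed(seed, train_loop(X, seq_train, seq_val, tgt_all, w0, ctl))

  fit <- structure(
    list(task = task, params = params, control = ctl,
         weights = res$weights, history = res$history,
         best_epoch = res$best_epoch, best_val_auroc = res$best_val_auroc,
         table = table, scaler = scaler,
         cost_stats = tgt_all$cost_stats, split = split,
         n_parameters = count_parameters(res$weights),
         call = match.call()),
    class = "hvec")

  # scores for every record of the input cohort, tagged by split
  all_seqs <- c(seq_train, seq_val, seq_test)
  rows <- unlist(all_seqs, use.names = FALSE)
  scores <- predict_scores(X, all_seqs, res$weights, task)
  split_of <- c(rep("train", sum(lengths(seq_train))),
                rep("validation", sum(lengths(seq_val))),
                rep("test", sum(lengths(seq_test))))
  fit$fitted <- data.frame(
    record_id = cohort$records$record_id[rows],
    person_id = cohort$records$person_id[rows],
    split = split_of,
    score = scores,
    label = main_y[rows],
    is_ca = tgt_all$is_ca[rows],
    stringsAsFactors = FALSE)
  fit$metrics <- evaluate_model(fit)
  fit
}

# per-record training targets aligned with cohort record order
build_targets <- function(cohort, labels, train_rows) {
  stopifnot(identical(labels$record_id, cohort$records$record_id))
  cost_raw <- log1p(rowSums(
    cohort$records[paste0("cost_", category_suffixes())]))
  mu <- mean(cost_raw[train_rows])
  sdv <- stats::sd(cost_raw[train_rows])
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  cost_cur <- (cost_raw - mu) / sdv
  # future cost: next record of the same person, 0 if none
  n <- length(cost_cur)
  cost_fut <- numeric(n)
  same_person <- cohort$records$person_id[-1L] ==
    cohort$records$person_id[-n]
  if (n > 1L) cost_fut[-n][same_person] <- cost_cur[-1L][same_person]
  list(y_mort = labels$mortality_30d,
       y_readm = labels$readmission_30d,
       is_ca = labels$is_ca,
       cost_cur = cost_cur, cost_fut = cost_fut,
       cost_stats = c(mean = mu, sd = sdv))
}

#' @export
#' @method print hvec
print.hvec <- function(x, ...) {
  cat("HVec model --", x$task, "\n")
  cat(sprintf("  multitask: %s | upsampling rate: %d | event weight: %g\n",
              x$control$multitask, x$control$upsampling_rate,
              x$control$event_weight))
  cat(sprintf("  %s trainable parameters | best epoch %d (val AUROC %.3f)\n",
              format(x$n_parameters, big.mark = ","), x$best_epoch,
              x$best_val_auroc))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  test %-16s AUROC %s  F1 %s  (n=%d, positives=%d)\n",
                m$task[i], fmt3(m$auroc[i]), fmt3(m$f1[i]),
                m$n_records[i], m$n_positive[i]))
  }
  invisible(x)
}

fmt3 <- function(v) ifelse(is.na(v), "NA", sprintf("%.3f", v))

#' @export
#' @method summary hvec
summary.hvec <- function(object, ...) {
  structure(list(fit = object), class = "summary.hvec")
}

#' @export
#' @method print summary.hvec
print.summary.hvec <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nSplit sizes (persons): train",
      length(f$split$train), "| validation", length(f$split$validation),
      "| test", length(f$split$test), "\n")
  cat("\nTraining history:\n")
  print(f$history, row.names = FALSE, digits = 4)
  cat("\nTest metrics:\n")
  print(f$metrics, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.hvec <- function(object, ...) {
  w <- object$weights
  v <- flatten_weights(w)
  names(v) <- unlist(lapply(weight_names, function(nm) {
    paste0(nm, "[", seq_along(w[[nm]]), "]")
  }), use.names = FALSE)
  v
}

#' Predict main-task probabilities
#'
#' Scores every record of a cohort with the fitted model (evaluation mode:
#' deterministic, no dropout). Codes unseen in training embed as zero
#' vectors.
#'
#' @param object A fitted [hvec()] model.
#' @param newdata An `hvec_cohort`; omitted, the stored in-sample scores
#'   are returned.
#' @param ... Unused.
#' @return Data frame `record_id`, `person_id`, `score` (probability of the
#'   main-task positive within 30 days).
#' @export
predict.hvec <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    return(object$fitted[c("record_id", "person_id", "score")])
  }
  stopifnot(inherits(newdata, "hvec_cohort"))
  X <- feature_matrix(newdata, object$table, object$scaler)
  seqs <- split(seq_len(nrow(newdata$records)),
                newdata$records$person_id)
  rows <- unlist(seqs, use.names = FALSE)
  scores <- predict_scores(X, seqs, object$weights, object$task)
  data.frame(record_id = newdata$records$record_id[rows],
             person_id = newdata$records$person_id[rows],
             score = scores, stringsAsFactors = FALSE)
}

#' @export
fitted.hvec <- function(object, ...) object$fitted$score

#' @export
residuals.hvec <- function(object, ...) {
  object$fitted$label - object$fitted$score
}

#' Plot training history
#'
#' Two panels: per-task training losses and validation AUROC of the main
#' task, by epoch.
#'
#' @param x A fitted [hvec()] model.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.hvec <- function(x, ...) {
  h <- x$history
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  loss_cols <- setdiff(names(h), c("epoch", "val_auroc"))
  graphics::matplot(h$epoch, as.matrix(h[loss_cols]), type = "b", pch = 1,
                    xlab = "epoch", ylab = "training loss",
                    main = "task losses", ...)
  graphics::legend("topright", legend = loss_cols, col = seq_along(loss_cols),
                   lty = seq_along(loss_cols), cex = 0.7, bty = "n")
  graphics::plot(h$epoch, h$val_auroc, type = "b", xlab = "epoch",
                 ylab = "validation AUROC", main = paste("main task:", x$task))
  invisible(x)
}
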