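# Task metrics. AUROC uses the Mann-Whitney formulation -- the probability
# that a uniformly random positive outscores a uniformly random negative,
# ties counted 1/2 -- computed from rank sums. Degenerate subsets report NA,
# never 0.

#' Area under the ROC curve (Mann-Whitney)
#'
#' `P(score_pos > score_neg) + P(score_pos = score_neg)/2` over all
#' positive-negative pairs, computed via rank sums in O(n log n). Invariant
#' under strictly increasing transforms of the scores.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels aligned with `scores`.
#' @return AUROC in `[0, 1]`; `NA` (with a warning) when only one class is
#'   present.
#' @export
compute_auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    warning("AUROC undefined: labels contain a single class; returning NA")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Thresholded classification metrics
#'
#' Precision, recall and F1 at a probability threshold (prediction positive
#' iff `score >= threshold`). Conventions for degenerate cases: precision 0
#' with no predicted positives, recall 0 with no true positives, F1 0 when
#' precision + recall is 0.
#'
#' @param scores Probability scores.
#' @param labels 0/1 labels.
#' @param threshold Decision threshold in (0, 1).
#' @return Named numeric vector `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Best-F1 threshold on held-out scores
#'
#' Scans the candidate thresholds implied by the scores and returns the one
#' maximizing F1; intended for threshold selection on the validation split.
#'
#' @param scores,labels As in [classification_metrics()].
#' @return The F1-maximizing threshold.
#' @export
select_threshold <- function(scores, labels) {
  cand <- unique(pmin(pmax(scores, 1e-9), 1 - 1e-9))
  f1 <- vapply(cand, function(th) {
    classification_metrics(scores, labels, th)[["f1"]]
  }, numeric(1))
  cand[which.max(f1)]
}

#' Evaluate a fitted model on its task subsets
#'
#' Computes AUROC/F1/precision/recall for the model's main task on the ALL
#' set and on its CA-record subset of one split (one model, two masks).
#' Records with undefined labels (readmission-ineligible) are excluded; an
#' empty or single-class subset reports NA metrics with its counts.
#'
#' @param model A fitted [hvec()] model.
#' @param split `"test"` (default), `"validation"` or `"train"`.
#' @param threshold Decision threshold for F1/precision/recall.
#' @return Data frame with one row per task subset (`ALL-<task>`,
#'   `CA-<task>`): `auroc`, `f1`, `precision`, `recall`, `n_records`,
#'   `n_positive`.
#' @export
evaluate_model <- function(model, split = "test", threshold = 0.5) {
  stopifnot(inherits(model, "hvec"))
  f <- model$fitted[model$fitted$split == split, , drop = FALSE]
  f <- f[!is.na(f$label), , drop = FALSE]
  subsets <- list(f, f[f$is_ca, , drop = FALSE])
  names(subsets) <- paste0(c("ALL-", "CA-"), model$task)
  rows <- lapply(names(subsets), function(nm) {
    s <- subsets[[nm]]
    if (nrow(s) == 0L || length(unique(s$label)) < 2L) {
      return(data.frame(task = nm, auroc = NA_real_, f1 = NA_real_,
                        precision = NA_real_, recall = NA_real_,
                        n_records = nrow(s),
                        n_positive = sum(s$label == 1L),
                        stringsAsFactors = FALSE))
    }
    cm <- classification_metrics(s$score, s$label, threshold)
    data.frame(task = nm, auroc = compute_auroc(s$score, s$label),
               f1 = cm[["f1"]], precision = cm[["precision"]],
               recall = cm[["recall"]], n_records = nrow(s),
               n_positive = sum(s$label == 1L), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run a configuration grid
#'
#' Fits one model per configuration row and seed and collects test metrics
#' for the ALL and CA subsets of the main task — the structure of the
#' single-task/multitask and upsampling-rate x event-weight experiments. A
#' failed run is recorded in the `error` column and skipped, not fatal.
#'
#' @param cohort An `hvec_cohort`.
#' @param grid Data frame with columns `multitask`, `upsampling_rate`,
#'   `event_weight`.
#' @param task Main task for every run.
#' @param seeds Integer vector; each config is fit once per seed.
#' @param params An [hvec_params()] shared by all runs.
#' @param ... Further arguments to [hvec()] (e.g. `max_epochs`).
#' @return Data frame: one row per (config, seed, task subset).
#' @export
run_grid <- function(cohort, grid, task = "mortality", seeds = 1L,
                     params = NULL, ...) {
  stopifnot(nrow(grid) >= 1L,
            all(c("multitask", "upsampling_rate", "event_weight") %in%
                  names(grid)))
  out <- list()
  for (gi in seq_len(nrow(grid))) {
    for (seed in seeds) {
      res <- tryCatch({
        fit <- hvec(cohort, task = task,
                    multitask = grid$multitask[gi],
                    upsampling_rate = grid$upsampling_rate[gi],
                    event_weight = grid$event_weight[gi],
                    params = params, seed = seed, ...)
        m <- fit$metrics
        m$error <- NA_character_
        m
      }, error = function(e) {
        data.frame(task = paste0(c("ALL-", "CA-"), task),
                   auroc = NA_real_, f1 = NA_real_, precision = NA_real_,
                   recall = NA_real_, n_records = NA_integer_,
                   n_positive = NA_integer_,
                   error = conditionMessage(e), stringsAsFactors = FALSE)
      })
      res <- cbind(data.frame(multitask = grid$multitask[gi],
                              upsampling_rate = grid$upsampling_rate[gi],
                              event_weight = grid$event_weight[gi],
                              seed = seed), res)
      out[[length(out) + 1L]] <- res
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize grid results
#'
#' Mean and standard deviation of AUROC/F1 over seeds for each
#' configuration and task subset — the layout of the experiment tables.
#'
#' @param results Output of [run_grid()].
#' @return Data frame with one row per (config, task subset).
#' @export
summarize_grid <- function(results) {
  key <- interaction(results$multitask, results$upsampling_rate,
                     results$event_weight, results$task, drop = TRUE)
  rows <- lapply(split(results, key), function(g) {
    data.frame(upsampling_rate = g$upsampling_rate[1L],
               event_weight = g$event_weight[1L],
               multitask = g$multitask[1L], task = g$task[1L],
               auroc_mean = mean(g$auroc, na.rm = TRUE),
               auroc_sd = stats::sd(g$auroc, na.rm = TRUE),
               f1_mean = mean(g$f1, na.rm = TRUE),
               f1_sd = stats::sd(g$f1, na.rm = TRUE),
               n_seeds = nrow(g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$task, out$multitask, out$upsampling_rate,
                   out$event_weight), ]
  rownames(out) <- NULL
  out
}
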