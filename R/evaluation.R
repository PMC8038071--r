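#' Confusion matrix for the stressed-vs-relaxed task
#'
#' Positive class is `stressed`.
#'
#' @param predicted,actual character vectors in
#'   `c("stressed", "relaxed")`.
#' @return an object of class `contrp_cm`: list with integer counts `tp`,
#'   `tn`, `fp`, `fn`.
#' @export
confusion_matrix <- function(predicted, actual) {
  if (length(predicted) != length(actual))
    abort_data("predicted and actual must have equal length")
  structure(list(
    tp = sum(predicted == "stressed" & actual == "stressed"),
    tn = sum(predicted == "relaxed" & actual == "relaxed"),
    fp = sum(predicted == "stressed" & actual == "relaxed"),
    fn = sum(predicted == "relaxed" & actual == "stressed")),
    class = "contrp_cm")
}

cm_add <- function(a, b) {
  structure(list(tp = a$tp + b$tp, tn = a$tn + b$tn,
                 fp = a$fp + b$fp, fn = a$fn + b$fn), class = "contrp_cm")
}

cm_total <- function(cm) cm$tp + cm$tn + cm$fp + cm$fn

#' @export
print.contrp_cm <- function(x, ...) {
  cat(sprintf("<confusion matrix (positive = stressed): TP=%d FP=%d FN=%d TN=%d>\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

# single-class precision/recall/F1 given tp, fp, fn; NA for 0/0
prf <- function(tp, fp, fn) {
  precision <- if (tp + fp == 0) NA_real_ else 100 * tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * (precision / 100) * (recall / 100) /
                  (precision / 100 + recall / 100)
  list(precision = precision, recall = recall, f1 = f1)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, precision and recall as percentages and F1 as a proportion,
#' using the standard formulas `accuracy = (TP+TN)/(TP+TN+FP+FN) x 100%`,
#' `precision = TP/(TP+FP) x 100%`, `recall = TP/(TP+FN) x 100%`,
#' `F1 = 2PR/(P+R)`.  Per-class values are obtained by swapping class
#' roles; a zero denominator yields `NA` (undefined), never 0.
#'
#' @param cm a [confusion_matrix()].
#' @return list with `accuracy`, `precision`, `recall`, `f1` (positive
#'   class), `per_class` (data.frame with rows stressed/relaxed) and
#'   `macro_precision`, `macro_recall`, `macro_f1`.
#' @export
cm_metrics <- function(cm) {
  if (!inherits(cm, "contrp_cm")) abort_data("cm must be a confusion matrix")
  n <- cm_total(cm)
  if (n == 0) abort_data("empty confusion matrix")
  pos <- prf(cm$tp, cm$fp, cm$fn)
  neg <- prf(cm$tn, cm$fn, cm$fp)  # relaxed as the positive class
  per_class <- data.frame(
    class = c("stressed", "relaxed"),
    precision = c(pos$precision, neg$precision),
    recall = c(pos$recall, neg$recall),
    f1 = c(pos$f1, neg$f1))
  list(accuracy = 100 * (cm$tp + cm$tn) / n,
       precision = pos$precision, recall = pos$recall, f1 = pos$f1,
       per_class = per_class,
       macro_precision = mean(per_class$precision),
       macro_recall = mean(per_class$recall),
       macro_f1 = mean(per_class$f1))
}

#' Rank-based AUC
#'
#' Probability that a randomly drawn stressed score exceeds a randomly
#' drawn relaxed score, ties counted one half (the Mann-Whitney statistic).
#'
#' @param scores numeric classifier scores.
#' @param labels character labels (`"stressed"` positive).
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  pos <- labels == "stressed"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    abort_data("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Leave-one-recording-out folds
#'
#' One fold per distinct recording id; the fold's test set holds every
#' sample of that recording and its training set everything else, so a
#' model is always evaluated on a completely unseen subject session.
#'
#' @param triples list of sample triples.
#' @return list of folds, each with `test_id`, `train_idx`, `test_idx`.
#' @export
loro_split <- function(triples) {
  ids <- vapply(triples, function(s) s$recording_id, character(1))
  uid <- sort(unique(ids))
  if (length(uid) < 2L)
    abort_config("leave-one-recording-out needs at least 2 recordings")
  lapply(uid, function(id) {
    list(test_id = id,
         train_idx = which(ids != id),
         test_idx = which(ids == id))
  })
}

#' Recording-wise cross-validated evaluation
#'
#' For each leave-one-recording-out fold: balance the training samples by
#' random undersampling, train a fresh model from scratch, predict on the
#' held-out recording, and record its confusion matrix and AUC.  Fold
#' matrices are summed into an aggregated matrix from which the overall
#' metrics are computed; AUC is reported both as the mean of per-fold AUCs
#' and pooled over all held-out scores.
#'
#' @param triples list of sample triples from >= 2 recordings.
#' @param arch an [arch_config()].
#' @param train_cfg a [train_config()]; fold `i` trains with seed
#'   `train_cfg$seed + i`.
#' @param balance_mode `"fold"` (default) undersamples within each training
#'   fold only, which is leakage-safe; `"global"` undersamples the full
#'   sample list once before splitting, replicating protocols that balance
#'   before cross-validation.
#' @return an object of class `contrp_eval_report`: list with `per_fold`
#'   (per-recording confusion matrices, metrics, AUC and the identity of
#'   every sample trained on), `aggregated` ([confusion_matrix()]),
#'   `overall` ([cm_metrics()]), `auc_mean`, `auc_pooled`, `balance_mode`.
#' @export
run_cv <- function(triples, arch = arch_config(),
                   train_cfg = train_config(),
                   balance_mode = c("fold", "global")) {
  balance_mode <- match.arg(balance_mode)
  if (balance_mode == "global")
    triples <- undersample_triples(triples, train_cfg$seed)
  folds <- loro_split(triples)
  per_fold <- list()
  all_scores <- numeric(0); all_labels <- character(0)
  agg <- structure(list(tp = 0L, tn = 0L, fp = 0L, fn = 0L), class = "contrp_cm")
  for (i in seq_along(folds)) {
    f <- folds[[i]]
    fold_seed <- train_cfg$seed + i
    train_set <- triples[f$train_idx]
    if (balance_mode == "fold")
      train_set <- undersample_triples(train_set, fold_seed)
    cfg_i <- train_cfg; cfg_i$seed <- fold_seed
    model <- build_model(arch, seed = fold_seed)
    fit <- train_cnn(model, train_set, cfg_i)
    test_set <- triples[f$test_idx]
    pred <- predict_cnn(fit$model, test_set)
    truth <- vapply(test_set, function(s) s$label, character(1))
    cm <- confusion_matrix(pred$label, truth)
    auc <- if (length(unique(truth)) == 2L) auc_rank(pred$p, truth) else NA_real_
    agg <- cm_add(agg, cm)
    all_scores <- c(all_scores, pred$p)
    all_labels <- c(all_labels, truth)
    per_fold[[i]] <- list(
      recording_id = f$test_id, cm = cm, metrics = cm_metrics(cm), auc = auc,
      loss = fit$loss,
      train_samples = data.frame(
        recording_id = vapply(train_set, function(s) s$recording_id, character(1)),
        start_s = vapply(train_set, function(s) s$start_s, numeric(1))))
  }
  structure(list(per_fold = per_fold, aggregated = agg,
                 overall = cm_metrics(agg),
                 auc_mean = mean(vapply(per_fold, function(f) f$auc, numeric(1)),
                                 na.rm = TRUE),
                 auc_pooled = auc_rank(all_scores, all_labels),
                 balance_mode = balance_mode),
            class = "contrp_eval_report")
}

#' @export
print.contrp_eval_report <- function(x, ...) {
  cat(sprintf("<leave-one-recording-out evaluation, %d folds, balance mode '%s'>\n",
              length(x$per_fold), x$balance_mode))
  for (f in x$per_fold)
    cat(sprintf("  %-10s accuracy %6.2f%%  AUC %s  (TP=%d FP=%d FN=%d TN=%d)\n",
                f$recording_id, f$metrics$accuracy,
                ifelse(is.na(f$auc), "   NA", sprintf("%.4f", f$auc)),
                f$cm$tp, f$cm$fp, f$cm$fn, f$cm$tn))
  cat(sprintf("  overall accuracy %.2f%%  F1 %.4f  AUC (mean) %.4f  AUC (pooled) %.4f\n",
              x$overall$accuracy, x$overall$f1, x$auc_mean, x$auc_pooled))
  invisible(x)
}

#' Grid search over training hyperparameters
#'
#' Evaluates every (learning rate, batch size, epochs) combination by
#' recording-wise cross-validated accuracy and returns the best; ties are
#' broken by the first row in the grid's lexicographic order.
#'
#' @param triples list of sample triples.
#' @param grid data.frame with columns `learning_rate`, `batch_size`,
#'   `epochs` (one row per combination).
#' @param arch an [arch_config()].
#' @param base_seed seed passed to each combination's [run_cv()].
#' @param balance_mode see [run_cv()].
#' @return list with `best` (a [train_config()]), `best_accuracy` and
#'   `table` (the grid plus an `accuracy` column).
#' @export
grid_search <- function(triples, grid, arch = arch_config(), base_seed = 1,
                        balance_mode = "fold") {
  if (!is.data.frame(grid) || nrow(grid) == 0L)
    abort_config("grid must be a non-empty data.frame")
  need <- c("learning_rate", "batch_size", "epochs")
  if (!all(need %in% names(grid)))
    abort_config("grid must have columns learning_rate, batch_size, epochs")
  grid <- grid[do.call(order, grid[need]), , drop = FALSE]
  rownames(grid) <- NULL
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- train_config(learning_rate = grid$learning_rate[i],
                        batch_size = grid$batch_size[i],
                        epochs = grid$epochs[i], seed = base_seed)
    run_cv(triples, arch, cfg, balance_mode)$overall$accuracy
  }, numeric(1))
  best_i <- which.max(acc)  # first maximum in lexicographic grid order
  best <- train_config(learning_rate = grid$learning_rate[best_i],
                       batch_size = grid$batch_size[best_i],
                       epochs = grid$epochs[best_i], seed = base_seed)
  list(best = best, best_accuracy = acc[best_i],
       table = cbind(grid, accuracy = acc))
}
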