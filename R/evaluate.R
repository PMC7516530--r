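#' Classification metrics from predictions
#'
#' Computes the confusion matrix (rows = true class, columns = predicted)
#' and the derived metrics: overall accuracy, macro-averaged precision and
#' recall (percentages), and the macro F1 score (fraction).  Classes absent
#' from both truth and prediction contribute 0 to the macro averages.
#'
#' @param y_true,y_pred integer class labels in `1..C`.
#' @param C number of classes.
#' @return an object of class `metrics_report`.
#' @export
metrics_from_predictions <- function(y_true, y_pred, C = max(y_true)) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  cm <- matrix(0L, C, C,
               dimnames = list(true = seq_len(C), predicted = seq_len(C)))
  for (i in seq_along(y_true)) cm[y_true[i], y_pred[i]] <-
      cm[y_true[i], y_pred[i]] + 1L
  support <- rowSums(cm)
  tp <- diag(cm)
  prec_c <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec_c <- ifelse(support > 0, tp / support, 0)
  f1_c <- ifelse(prec_c + rec_c > 0,
                 2 * prec_c * rec_c / (prec_c + rec_c), 0)
  row_pct <- cm
  nz <- support > 0
  row_pct[nz, ] <- 100 * cm[nz, , drop = FALSE] / support[nz]
  structure(list(accuracy = 100 * sum(tp) / length(y_true),
                 precision = 100 * mean(prec_c), recall = 100 * mean(rec_c),
                 f1 = mean(f1_c), support = support, confusion = cm,
                 confusion_pct = row_pct),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.1f%%  precision %.1f%%  recall %.1f%%  F1 %.3f  (n = %d)\n",
              x$accuracy, x$precision, x$recall, x$f1, sum(x$support)))
  invisible(x)
}

#' Evaluate a trained model on labelled trials
#'
#' Argmax of the predicted class probabilities against the true labels, in
#' evaluation mode (dropout off, batch-norm running statistics).
#'
#' @param model a `cdan_model` from [train_da()].
#' @param trials a labelled [eeg_trial_set()].
#' @param domain which domain's batch-norm statistics to use (see
#'   [predict_proba()]).
#' @return a `metrics_report` (see [metrics_from_predictions()]).
#' @export
evaluate_model <- function(model, trials,
                           domain = c("auto", "target", "source")) {
  if (is.null(trials$labels) || inherits(trials$labels, "withheld_labels"))
    stop("evaluation requires readable labels")
  metrics_from_predictions(trials$labels,
                           predict_classes(model, trials, domain = domain),
                           trials$n_classes)
}

#' Compare training variants across seeds (and subjects)
#'
#' Trains each requested variant for each seed — and, when given a pool of
#' subjects, for each left-out target subject — and records the target-test
#' accuracy together with the in-sample source accuracy (evaluation-mode
#' forward over the source training trials, a proxy for within-domain
#' performance).
#'
#' @param x a [domain_pair()] or a list of labelled [eeg_trial_set()]
#'   (a subject pool; leave-one-subject-out pairs are formed internally).
#' @param variants character vector of [train_config()] variants.
#' @param n_seeds number of seeds (`base_seed + 0:(n_seeds-1)`).
#' @param arch an [arch_config()].
#' @param cfg a [train_config()] template; its `variant` and `seed` fields
#'   are overridden per run.
#' @param base_seed first seed.
#' @param subjects for a pool, which subjects to use as targets (default
#'   all).
#' @return data.frame with columns `variant`, `subject`, `seed`,
#'   `source_acc`, `target_acc`.
#' @export
compare_variants <- function(x, variants, n_seeds, arch, cfg,
                             base_seed = cfg$seed, subjects = NULL) {
  pairs <- if (inherits(x, "domain_pair")) {
    list(x)
  } else {
    if (is.null(subjects)) subjects <- seq_along(x)
    lapply(subjects, function(j) leave_one_out(x, j))
  }
  ids <- vapply(pairs, function(p) p$target_test$subject_id, character(1L))
  rows <- list()
  for (pi in seq_along(pairs)) for (v in variants) for (s in seq_len(n_seeds)) {
    cfg_run <- cfg
    cfg_run$variant <- match.arg(v, c("cdan", "cdan1", "dan", "source_only"))
    cfg_run$seed <- as.integer(base_seed + s - 1L)
    model <- train_da(pairs[[pi]], arch, cfg_run)
    src_acc <- evaluate_model(model, pairs[[pi]]$source,
                              domain = "source")$accuracy
    tgt_acc <- evaluate_model(model, pairs[[pi]]$target_test)$accuracy
    rows[[length(rows) + 1L]] <-
      data.frame(variant = cfg_run$variant, subject = ids[pi],
                 seed = cfg_run$seed, source_acc = src_acc,
                 target_acc = tgt_acc)
  }
  do.call(rbind, rows)
}

#' Summarise a variant comparison
#'
#' @param results output of [compare_variants()].
#' @return data.frame with per-variant mean and sd of target accuracy.
#' @export
summarize_comparison <- function(results) {
  agg <- stats::aggregate(target_acc ~ variant, results, function(v)
    c(mean = mean(v), sd = stats::sd(v)))
  out <- data.frame(variant = agg$variant,
                    mean_target_acc = agg$target_acc[, "mean"],
                    sd_target_acc = agg$target_acc[, "sd"])
  out[order(out$mean_target_acc), ]
}

#' Hyperparameter sweep on a source-domain validation split
#'
#' Holds out the last `val_frac` of the source trials (chronological order)
#' as a validation set, trains on the remainder (the unlabelled target
#' training set is still used for adaptation), and reports validation
#' accuracy for each value of the swept parameter.  The parameter may live
#' in the training config (e.g. `lambda`) or in the architecture (e.g.
#' `d_f`, `k_dense`).
#'
#' @param param parameter name.
#' @param values vector of values to try.
#' @param pair a [domain_pair()].
#' @param arch an [arch_config()].
#' @param cfg a [train_config()].
#' @param val_frac held-out fraction of source trials.
#' @return data.frame with columns `param`, `value`, `val_acc`.
#' @export
sweep_param <- function(param, values, pair, arch, cfg, val_frac = 0.2) {
  n_s <- n_trials(pair$source)
  n_val <- max(1L, floor(n_s * val_frac))
  val_idx <- (n_s - n_val + 1L):n_s
  src_train <- subset_trials(pair$source, setdiff(seq_len(n_s), val_idx))
  src_val <- subset_trials(pair$source, val_idx)
  sub_pair <- domain_pair(src_train, pair$target_train, pair$target_test)
  rows <- lapply(values, function(v) {
    arch_run <- arch; cfg_run <- cfg
    if (param %in% names(cfg_run)) {
      cfg_run[[param]] <- v
    } else if (param %in% names(arch_run)) {
      args <- unclass(arch_run); args[[param]] <- v
      arch_run <- do.call(arch_config, args)
    } else stop("unknown parameter: ", param)
    model <- train_da(sub_pair, arch_run, cfg_run)
    data.frame(param = param, value = v,
               val_acc = evaluate_model(model, src_val,
                                        domain = "source")$accuracy)
  })
  do.call(rbind, rows)
}
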