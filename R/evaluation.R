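#' Classification metric panel and balanced-resampling external validation
#'
#' Implements the metric panel (accuracy, precision, sensitivity, specificity,
#' F1, AUROC, AUPRC) and the repeated balanced-undersampling protocol used to
#' validate the ensemble on a heavily imbalanced screening library: in each of
#' `n_reps` repetitions, as many negatives as there are positives are drawn
#' without replacement from the negative pool, the balanced set is evaluated
#' at every threshold, and results are averaged over repetitions. Because the
#' averaging order is ambiguous in principle, both aggregations are reported:
#' the metrics of the averaged confusion counts, and the average of per-rep
#' metrics (with undefined per-rep metrics excluded and counted).
#'
#' @name evaluation
NULL

#' Confusion counts from binary labels and predictions
#'
#' @param labels,predictions equal-length binary (0/1) vectors.
#' @return an object of class `confusion_counts`: fields `tp`, `fn`, `tn`,
#'   `fp` (integers summing to the input length).
#' @export
confusion_counts <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    config_error("'labels' and 'predictions' must have equal length")
  if (length(labels) < 1L) config_error("need at least one observation")
  if (!all(labels %in% c(0L, 1L)) || !all(predictions %in% c(0L, 1L)))
    config_error("labels and predictions must be 0/1")
  structure(list(tp = sum(labels == 1L & predictions == 1L),
                 fn = sum(labels == 1L & predictions == 0L),
                 tn = sum(labels == 0L & predictions == 0L),
                 fp = sum(labels == 0L & predictions == 1L)),
            class = "confusion_counts")
}

#' Metric panel from (possibly fractional) confusion counts
#'
#' Counts may be fractional because they are typically averages over
#' resampling repetitions. A metric whose denominator is zero is reported as
#' `NA` (undefined — never coerced to 0) and flagged in the `undefined`
#' attribute.
#'
#' @param counts a [confusion_counts()] or a named list/vector with `tp`,
#'   `fn`, `tn`, `fp` (nonnegative, not all zero).
#' @return an object of class `metric_set`: `accuracy`, `precision`,
#'   `sensitivity`, `specificity`, `f1` (harmonic mean of precision and
#'   sensitivity).
#' @examples
#' metrics_from_counts(list(tp = 3, fn = 2, tn = 4, fp = 1))
#' @export
metrics_from_counts <- function(counts) {
  c_ <- as.list(counts)[c("tp", "fn", "tn", "fp")]
  if (any(vapply(c_, is.null, logical(1))) || any(unlist(c_) < 0))
    config_error("counts must provide nonnegative tp, fn, tn, fp")
  tp <- c_$tp; fn <- c_$fn; tn <- c_$tn; fp <- c_$fp
  total <- tp + fn + tn + fp
  if (total <= 0) config_error("counts sum to zero")
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  accuracy <- (tp + tn) / total
  precision <- safe_div(tp, tp + fp)
  sensitivity <- safe_div(tp, tp + fn)
  specificity <- safe_div(tn, tn + fp)
  f1 <- if (is.na(precision) || is.na(sensitivity) ||
            (precision + sensitivity) == 0) NA_real_
        else 2 * precision * sensitivity / (precision + sensitivity)
  m <- list(accuracy = accuracy, precision = precision,
            sensitivity = sensitivity, specificity = specificity, f1 = f1)
  structure(m, class = "metric_set",
            undefined = names(m)[vapply(m, is.na, logical(1))])
}

#' @export
print.metric_set <- function(x, ...) {
  v <- unlist(x)
  cat("<metric_set>", paste(sprintf("%s=%.3f", names(v), v), collapse = "  "),
      "\n")
  invisible(x)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a uniformly random positive
#' outscores a uniformly random negative, ties counting one half. Invariant
#' under strictly increasing score transforms. Returns `NA` (flagged) when
#' only one class is present.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels, same length.
#' @return AUROC in \[0, 1\], or flagged `NA`.
#' @examples
#' auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
auroc <- function(scores, labels) {
  if (length(scores) != length(labels))
    config_error("'scores' and 'labels' must have equal length")
  pos <- labels == 1L
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0L || nn == 0L)
    return(structure(NA_real_, undefined = "single-class labels"))
  r <- rank(scores, ties.method = "average")
  unname((sum(r[pos]) - np * (np + 1) / 2) / (np * nn))
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-interpolated) summation: molecules are ranked by descending
#' score (ties broken by original position, a fixed documented convention) and
#' the precision at each positive's rank is averaged over positives. The
#' random-classifier baseline equals the positive prevalence. Returns `NA`
#' (flagged) when no positive is present.
#'
#' @inheritParams auroc
#' @return AUPRC in \[0, 1\], or flagged `NA`.
#' @export
auprc <- function(scores, labels) {
  if (length(scores) != length(labels))
    config_error("'scores' and 'labels' must have equal length")
  np <- sum(labels == 1L)
  if (np == 0L) return(structure(NA_real_, undefined = "no positives"))
  ord <- order(-scores, seq_along(scores))
  y <- labels[ord]
  prec_at <- cumsum(y) / seq_along(y)
  sum(prec_at[y == 1L]) / np
}

#' Held-out test evaluation of a trained model
#'
#' Scores the test set, binarizes at the threshold for the confusion-derived
#' metrics, and adds the threshold-free AUROC and AUPRC from the raw scores.
#'
#' @param model a `trained_target_model`.
#' @param test a [labeled_dataset()] containing both classes.
#' @param threshold decision threshold (default 0.5).
#' @return a `metric_set` with additional `auroc` and `auprc` fields.
#' @export
evaluate_model_on_test <- function(model, test, threshold = 0.5) {
  stopifnot(inherits(test, "labeled_dataset"))
  if (nrow(test$records) == 0L) config_error("empty test set")
  if (length(unique(test$records$label)) < 2L)
    config_error("test set must contain both classes")
  scores <- predict(model, test)
  labels <- test$records$label
  keep <- !is.na(scores)
  m <- metrics_from_counts(confusion_counts(
    labels[keep], classify(scores[keep], screening_config(threshold))))
  m$auroc <- as.numeric(auroc(scores[keep], labels[keep]))
  m$auprc <- as.numeric(auprc(scores[keep], labels[keep]))
  m
}

#' Repeated balanced-subsampling validation with a threshold sweep
#'
#' Emulates external validation under extreme class imbalance: all positives
#' are kept, and in each repetition `n_sample` negatives are drawn without
#' replacement from the negative pool to build a balanced set (by default
#' `n_sample` equals the number of positives, as in a 154-vs-154 design drawn
#' from 5744 negatives, repeated 1000 times). Confusion counts and metrics are
#' evaluated at every threshold and averaged over repetitions.
#'
#' @param score_table data.frame with a score column (`ensemble` or `score`)
#'   and a 0/1 `label` column.
#' @param thresholds decision thresholds to sweep (default
#'   `c(0.5, 0.6, 0.7, 0.8, 0.9, 0.95)`).
#' @param n_reps repetitions (default 1000).
#' @param n_sample negatives drawn per repetition (default: number of
#'   positives).
#' @param seed sampling seed.
#' @return an object of class `resampling_report`: averaged counts per
#'   threshold, both metric aggregations (`metrics_of_mean_counts`,
#'   `mean_of_metrics` with per-metric exclusion counts), the running-average
#'   convergence trace of the sampled counts, and the protocol parameters.
#' @export
balanced_resampling_validation <- function(score_table,
                                           thresholds = c(0.5, 0.6, 0.7,
                                                          0.8, 0.9, 0.95),
                                           n_reps = 1000L, n_sample = NULL,
                                           seed = 1L) {
  sc_col <- intersect(c("ensemble", "score"), names(score_table))[1]
  if (is.na(sc_col) || !"label" %in% names(score_table))
    config_error("score_table needs a score column ('ensemble' or 'score') and 'label'")
  s <- score_table[[sc_col]]
  y <- score_table$label
  pos <- s[y == 1L]
  neg <- s[y == 0L]
  if (length(pos) < 1L) config_error("need at least one positive")
  n_sample <- as.integer(n_sample %||% length(pos))
  if (n_sample > length(neg))
    config_error(sprintf("n_sample (%d) exceeds the negative pool (%d)",
                         n_sample, length(neg)))
  if (n_reps < 1L) config_error("'n_reps' must be >= 1")
  nt <- length(thresholds)
  np <- length(pos)
  # positives are fixed across repetitions
  tp <- vapply(thresholds, function(t) sum(pos >= t), numeric(1))
  fn <- np - tp
  fp_mat <- matrix(NA_real_, n_reps, nt)
  with_seed(derive_seed(seed, "resample"), {
    for (r in seq_len(n_reps)) {
      ns <- neg[sample.int(length(neg), n_sample)]
      fp_mat[r, ] <- vapply(thresholds, function(t) sum(ns >= t), numeric(1))
    }
  })
  tn_mat <- n_sample - fp_mat
  metric_names <- c("accuracy", "precision", "sensitivity", "specificity",
                    "f1")
  mean_counts <- data.frame(threshold = thresholds, tp = tp, fn = fn,
                            tn = colMeans(tn_mat), fp = colMeans(fp_mat))
  momc <- do.call(rbind, lapply(seq_len(nt), function(k) {
    m <- metrics_from_counts(mean_counts[k, c("tp", "fn", "tn", "fp")])
    as.data.frame(unclass(m)[metric_names])
  }))
  momc <- cbind(threshold = thresholds, momc)
  # per-repetition metrics, undefined excluded from the mean with a count
  mom <- matrix(NA_real_, nt, length(metric_names),
                dimnames = list(NULL, metric_names))
  excl <- matrix(0L, nt, length(metric_names),
                 dimnames = list(NULL, metric_names))
  for (k in seq_len(nt)) {
    per_rep <- vapply(seq_len(n_reps), function(r) {
      m <- metrics_from_counts(list(tp = tp[k], fn = fn[k],
                                    tn = tn_mat[r, k], fp = fp_mat[r, k]))
      unlist(unclass(m)[metric_names])
    }, numeric(length(metric_names)))
    mom[k, ] <- rowMeans(per_rep, na.rm = TRUE)
    excl[k, ] <- rowSums(is.na(per_rep))
  }
  mom_df <- cbind(data.frame(threshold = thresholds), as.data.frame(mom))
  conv <- lapply(seq_len(nt), function(k)
    cumsum(fp_mat[, k]) / seq_len(n_reps))
  names(conv) <- paste0("threshold_", thresholds)
  structure(list(thresholds = thresholds, n_reps = n_reps,
                 n_sample = n_sample, n_pos = np,
                 n_neg_pool = length(neg), seed = seed,
                 counts = mean_counts,
                 metrics_of_mean_counts = momc,
                 mean_of_metrics = mom_df,
                 n_excluded = as.data.frame(excl),
                 convergence_fp = conv),
            class = "resampling_report")
}

#' @export
print.resampling_report <- function(x, ...) {
  cat(sprintf("<resampling_report> %d reps, %d positives vs %d-of-%d sampled negatives\n",
              x$n_reps, x$n_pos, x$n_sample, x$n_neg_pool))
  print(as.data.frame(x), digits = 3)
  invisible(x)
}

#' Threshold-sweep table of a resampling report
#'
#' One row per threshold with the averaged counts and the metric panel,
#' mirroring the layout `threshold, TP, FN, TN, FP, accuracy, precision,
#' sensitivity, specificity, F1`.
#'
#' @param x a `resampling_report`.
#' @param row.names,optional ignored (S3 signature).
#' @param aggregation `"mean_counts"` (metrics of the averaged counts,
#'   default) or `"mean_metrics"` (average of per-repetition metrics).
#' @param ... unused.
#' @export
as.data.frame.resampling_report <- function(x, row.names = NULL,
                                            optional = FALSE,
                                            aggregation = c("mean_counts",
                                                            "mean_metrics"),
                                            ...) {
  aggregation <- match.arg(aggregation)
  m <- if (aggregation == "mean_counts") x$metrics_of_mean_counts else
    x$mean_of_metrics
  out <- cbind(x$counts, m[, c("accuracy", "precision", "sensitivity",
                               "specificity", "f1")])
  names(out) <- c("threshold", "TP", "FN", "TN", "FP", "accuracy",
                  "precision", "sensitivity", "specificity", "F1")
  rownames(out) <- NULL
  out
}
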