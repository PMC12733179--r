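#' Accumulate per-label confusion counts from predicted probabilities
#'
#' Thresholds a probability matrix at a fixed operating point (inclusive:
#' a prediction is positive when the probability is **at least** the
#' threshold) and tallies true/false positives and negatives per label.
#'
#' @param probs Numeric matrix `[n x L]` of predicted positive-class
#'   probabilities (a vector is treated as a single label).
#' @param labels Binary matrix of the same shape with ground-truth labels.
#' @param threshold Decision threshold in (0, 1); default 0.5, the fixed
#'   operating point used throughout training and evaluation.
#'
#' @return A tibble with one row per label and columns `label`, `tp`, `fp`,
#'   `fn`, `tn`, `n_pos`, `n_neg`. Pool rows with [pool_counts()] for
#'   micro-averaged metrics.
#' @seealso [pool_counts()], [precision_recall()], [fbeta_from_counts()]
#' @export
#' @examples
#' probs <- matrix(c(0.9, 0.4, 0.2, 0.7), nrow = 2)
#' labels <- matrix(c(1, 1, 0, 1), nrow = 2)
#' accumulate_counts(probs, labels)
accumulate_counts <- function(probs, labels, threshold = 0.5) {
  probs <- as_prob_matrix(probs, "probs")
  labels <- as_prob_matrix(labels, "labels")
  check_same_shape(probs, labels)
  check_binary(labels)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    abort("`threshold` must be a single number in (0, 1).")
  }
  pred <- probs >= threshold
  pos <- labels == 1
  tibble(
    label = label_names(labels),
    tp = as.integer(colSums(pred & pos)),
    fp = as.integer(colSums(pred & !pos)),
    fn = as.integer(colSums(!pred & pos)),
    tn = as.integer(colSums(!pred & !pos))
  ) |>
    dplyr::mutate(n_pos = .data$tp + .data$fn, n_neg = .data$fp + .data$tn)
}

#' Pool per-label confusion counts into a single micro count row
#'
#' @param counts A tibble of per-label counts from [accumulate_counts()].
#' @return A one-row tibble with the field-wise sums (`label = "pooled"`).
#' @export
pool_counts <- function(counts) {
  check_counts(counts)
  tn <- if ("tn" %in% names(counts)) sum(counts$tn) else 0L
  tibble(
    label = "pooled",
    tp = sum(counts$tp), fp = sum(counts$fp),
    fn = sum(counts$fn), tn = tn
  ) |>
    dplyr::mutate(n_pos = .data$tp + .data$fn, n_neg = .data$fp + .data$tn)
}

check_counts <- function(counts) {
  need <- c("tp", "fp", "fn")
  if (!is.data.frame(counts) || !all(need %in% names(counts))) {
    abort("`counts` must be a data frame with columns tp, fp, fn (see accumulate_counts()).")
  }
  if (nrow(counts) == 0L) abort("`counts` must have at least one row.")
  invisible(counts)
}

#' Precision and recall from confusion counts
#'
#' Adds `precision = tp / (tp + fp)` and `recall = tp / (tp + fn)` columns.
#' Either is `NA` when its denominator is zero (no positive predictions or
#' no positive labels, respectively) — the undefined case, which the weight
#' update treats via its fallback rule.
#'
#' @param counts Per-label or pooled counts (see [accumulate_counts()]).
#' @return The input tibble with `precision` and `recall` columns appended.
#' @export
precision_recall <- function(counts) {
  check_counts(counts)
  counts |>
    dplyr::mutate(
      precision = ifelse(.data$tp + .data$fp > 0, .data$tp / (.data$tp + .data$fp), NA_real_),
      recall = ifelse(.data$tp + .data$fn > 0, .data$tp / (.data$tp + .data$fn), NA_real_)
    )
}

#' F-beta score from confusion counts
#'
#' Computes `(1 + b^2) tp / ((1 + b^2) tp + b^2 fn + fp)`, the count form of
#' the F-beta score. By convention the score is 0 whenever `tp = 0` (a label
#' that is never correctly predicted scores zero, even when precision is
#' undefined).
#'
#' @param tp,fp,fn Nonnegative counts (vectorized).
#' @param beta Positive scalar; `beta = 1` gives the F1 score.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
#' @examples
#' fbeta_from_counts(2, 1, 0)          # 0.8
#' fbeta_from_counts(1, 0, 1, beta = 2) # 5/9
fbeta_from_counts <- function(tp, fp, fn, beta = 1) {
  check_beta(beta)
  if (any(tp < 0 | fp < 0 | fn < 0)) abort("Counts must be nonnegative.")
  b2 <- beta^2
  num <- (1 + b2) * tp
  den <- (1 + b2) * tp + b2 * fn + fp
  ifelse(tp > 0, num / den, 0)
}

#' Micro-averaged F-beta score
#'
#' Pools TP/FP/FN counts across labels by summation, then applies the count
#' form of the F-beta score, so frequent labels weigh proportionally more.
#'
#' @param counts Per-label counts tibble.
#' @inheritParams fbeta_from_counts
#' @return A single score in `[0, 1]`.
#' @export
micro_fbeta <- function(counts, beta = 1) {
  pooled <- pool_counts(counts)
  fbeta_from_counts(pooled$tp, pooled$fp, pooled$fn, beta)
}

#' Macro-averaged F-beta report
#'
#' Computes per-label F-beta scores (zero when a label has no true
#' positives) and their unweighted mean, alongside the micro-averaged score
#' from pooled counts.
#'
#' @param counts Per-label counts tibble.
#' @inheritParams fbeta_from_counts
#' @param include_empty If `FALSE`, labels with no positive ground-truth
#'   instances (`n_pos = 0`) are excluded from the macro average. Default
#'   `TRUE`: such labels contribute a zero, the convention used throughout.
#' @return An object of class `fscore_report`: a list with `beta`,
#'   `per_label` (counts plus `precision`, `recall`, `fbeta`), `micro_f` and
#'   `macro_f`.
#' @export
macro_fbeta <- function(counts, beta = 1, include_empty = TRUE) {
  check_counts(counts)
  check_beta(beta)
  per_label <- precision_recall(counts) |>
    dplyr::mutate(
      n_pos = .data$tp + .data$fn,
      fbeta = fbeta_from_counts(.data$tp, .data$fp, .data$fn, beta)
    )
  keep <- if (include_empty) rep(TRUE, nrow(per_label)) else per_label$n_pos > 0
  if (!any(keep)) abort("No labels left in the macro average.")
  structure(
    list(
      beta = beta,
      per_label = per_label,
      micro_f = micro_fbeta(counts, beta),
      macro_f = mean(per_label$fbeta[keep])
    ),
    class = "fscore_report"
  )
}

#' @export
print.fscore_report <- function(x, ...) {
  cat(sprintf(
    "<fscore_report> beta = %g, %d label(s)\n  micro F = %.4f, macro F = %.4f\n",
    x$beta, nrow(x$per_label), x$micro_f, x$macro_f
  ))
  invisible(x)
}

#' Mean per-instance intersection-over-union of label sets
#'
#' For each instance, the size of the intersection of the true and predicted
#' label sets divided by the size of their union, averaged over instances.
#' When both sets are empty the instance scores 1 (the model and the truth
#' agree that nothing is present).
#'
#' @param true_sets,pred_sets Equal-length lists of label vectors.
#' @return Mean IoU in `[0, 1]`.
#' @export
instance_iou <- function(true_sets, pred_sets) {
  if (length(true_sets) != length(pred_sets)) {
    abort("`true_sets` and `pred_sets` must have equal length.")
  }
  vals <- purrr::map2_dbl(true_sets, pred_sets, function(a, b) {
    u <- union(a, b)
    if (length(u) == 0L) 1 else length(intersect(a, b)) / length(u)
  })
  mean(vals)
}

#' Cardinality statistics of predicted label sets
#'
#' @inheritParams instance_iou
#' @return A one-row tibble with `mean_true` and `mean_pred` set sizes and
#'   `mae`, the mean absolute per-instance size error.
#' @export
cardinality_stats <- function(true_sets, pred_sets) {
  if (length(true_sets) != length(pred_sets)) {
    abort("`true_sets` and `pred_sets` must have equal length.")
  }
  if (length(true_sets) == 0L) abort("Need at least one instance.")
  nt <- lengths(true_sets)
  np <- lengths(pred_sets)
  tibble(mean_true = mean(nt), mean_pred = mean(np), mae = mean(abs(nt - np)))
}

#' Write a metrics report to CSV and JSON
#'
#' The CSV holds one row per label (counts, precision, recall, F-beta); the
#' JSON summary holds the micro/macro scores plus optional instance-level
#' IoU and cardinality fields.
#'
#' @param report An `fscore_report` from [macro_fbeta()].
#' @param csv_path,json_path Output paths; either may be `NULL` to skip.
#' @param iou Optional mean IoU to include in the summary.
#' @param cardinality Optional one-row tibble from [cardinality_stats()].
#' @return `report`, invisibly.
#' @export
write_metrics_report <- function(report, csv_path = NULL, json_path = NULL,
                                 iou = NULL, cardinality = NULL) {
  if (!inherits(report, "fscore_report")) abort("`report` must be an fscore_report.")
  if (!is.null(csv_path)) {
    readr::write_csv(
      dplyr::select(
        report$per_label,
        label_id = "label", "tp", "fp", "fn", "tn", "precision", "recall", "fbeta"
      ),
      csv_path
    )
  }
  if (!is.null(json_path)) {
    summary <- list(beta = report$beta, micro_f = report$micro_f, macro_f = report$macro_f)
    if (!is.null(iou)) summary$iou <- iou
    if (!is.null(cardinality)) summary <- c(summary, as.list(cardinality))
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
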