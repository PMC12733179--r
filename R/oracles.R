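#' Exhaustive threshold sweep for the best achievable F-beta
#'
#' Evaluates the F-beta score at every distinct-score cutpoint of a score
#' vector (plus the all-positive and all-negative rules, with predictions
#' positive when `score >= threshold`) and returns the maximum — the exact
#' post hoc thresholding optimum by exhaustion. `labels` may also contain
#' probabilities in `[0, 1]`, in which case expected (soft) counts are
#' swept, which evaluates the best expected score on a known posterior.
#'
#' @param scores Numeric score vector.
#' @param labels Binary labels (or posterior probabilities) of equal
#'   length with positive total mass.
#' @param beta Positive scalar.
#' @return List with `best_f`, `best_threshold` (a score value, or `Inf`
#'   for the empty prediction set) and `n_cuts` evaluated.
#' @export
#' @examples
#' brute_force_threshold_f1(c(0.9, 0.8, 0.7, 0.4, 0.2), c(1, 0, 1, 0, 0))
brute_force_threshold_f1 <- function(scores, labels, beta = 1) {
  check_beta(beta)
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have equal length.")
  }
  if (any(labels < 0 | labels > 1)) abort("`labels` must lie in [0, 1].")
  n_pos <- sum(labels)
  if (n_pos <= 0) abort("Need at least one positive label.")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y)
  k_all <- seq_along(s)
  # Valid cuts: positions where the next score is strictly smaller
  # (inclusive thresholding cannot split tied scores), plus predict-all.
  valid <- c(which(diff(s) < 0), length(s))
  b2 <- beta^2
  f_at <- function(tp_k, k) {
    fp <- k - tp_k
    fn <- n_pos - tp_k
    num <- (1 + b2) * tp_k
    den <- num + b2 * fn + fp
    ifelse(den > 0, num / den, 0)
  }
  f_cuts <- f_at(tp[valid], k_all[valid])
  f_empty <- 0
  if (max(f_cuts) >= f_empty) {
    best <- which.max(f_cuts)
    list(best_f = f_cuts[best], best_threshold = s[valid[best]],
         n_cuts = length(valid) + 1L)
  } else {
    list(best_f = f_empty, best_threshold = Inf, n_cuts = length(valid) + 1L)
  }
}

#' Learner-free fixed-point iteration of the weight update on a posterior
#'
#' Idealizes the epoch-wise algorithm on a calibrated posterior: given the
#' current weight, threshold the posterior at `1 / (1 + wpos)` (the
#' cost-sensitive Bayes rule), read off the implied precision and recall,
#' and re-derive the weight via `1/Pr + beta^2/Rc - 1`; iterate to a fixed
#' point. At the fixed point the implied threshold equals half the optimal
#' F1 (for beta = 1), so the achieved score should match the exhaustive
#' threshold sweep — the core optimality check of the weight formula.
#'
#' @param posterior Vector of calibrated positive-class probabilities.
#' @param labels Optional binary labels; when supplied, hard counts on the
#'   labels are used, otherwise expected (soft) counts under the posterior.
#' @param beta Positive scalar.
#' @param init Initial weight (e.g. the balanced upper bound).
#' @param max_iter,tol Iteration control: stop when `|delta wpos| < tol`.
#' @return List with `wpos`, `threshold`, `f_at_fixed_point`, `converged`,
#'   and a `trace` tibble (iteration, weight, threshold, precision, recall,
#'   F-beta). Oscillation is damped by averaging the two most recent
#'   iterates when the update alternates sign.
#' @export
fixed_point_wpos <- function(posterior, labels = NULL, beta = 1, init = 1,
                             max_iter = 100L, tol = 1e-8) {
  check_beta(beta)
  if (any(posterior < 0 | posterior > 1)) abort("`posterior` must lie in [0, 1].")
  if (init <= 0) abort("`init` must be positive.")
  y <- labels %||% posterior
  if (!is.null(labels)) check_binary(labels)
  n_pos <- sum(y)
  if (n_pos <= 0) abort("No positive mass in the task.")

  counts_at <- function(t) {
    sel <- posterior >= t
    tp <- sum(y[sel]); fp <- sum(1 - y[sel]); fn <- n_pos - tp
    list(tp = tp, fp = fp, fn = fn)
  }
  w <- init
  rows <- vector("list", max_iter)
  converged <- FALSE
  prev_delta <- NULL
  for (i in seq_len(max_iter)) {
    t <- implied_threshold(w)
    cc <- counts_at(t)
    if (cc$tp <= 0) {
      w_new <- init
      pr <- NA_real_; rc <- 0; f <- 0
    } else {
      pr <- cc$tp / (cc$tp + cc$fp)
      rc <- cc$tp / n_pos
      f <- soft_fbeta_from_counts(cc$tp, cc$fp, cc$fn, beta)
      w_new <- wpos_from_pr_rc(pr, rc, beta)
    }
    delta <- w_new - w
    if (!is.null(prev_delta) && prev_delta * delta < 0) {
      w_new <- (w + w_new) / 2  # damp sign-alternating oscillation
      delta <- w_new - w
    }
    rows[[i]] <- tibble(iter = i, wpos = w_new, threshold = t,
                        precision = pr, recall = rc, fbeta = f)
    prev_delta <- delta
    w <- w_new
    if (abs(delta) < tol) { converged <- TRUE; break }
  }
  trace <- dplyr::bind_rows(rows)
  t_final <- implied_threshold(w)
  cc <- counts_at(t_final)
  list(
    wpos = w, threshold = t_final,
    f_at_fixed_point = soft_fbeta_from_counts(cc$tp, cc$fp, cc$fn, beta),
    converged = converged, trace = trace
  )
}

# F-beta with FN, FP treated as continuous (TP eliminated via Npos - FN).
fbeta_continuous <- function(n_pos, fn, fp, beta = 1) {
  b2 <- beta^2
  (1 + b2) * (n_pos - fn) / ((1 + b2) * n_pos - fn + fp)
}

#' Closed-form derivatives of F-beta versus finite differences
#'
#' The weight formula is the negated ratio of the partial derivatives of
#' the F-beta score with respect to false negatives and false positives.
#' This check evaluates both closed forms and compares each against central
#' finite differences of the continuous count form, returning the largest
#' relative error — an independent verification of the derivation.
#'
#' @param n_pos Positive-class size.
#' @param fn,fp Interior operating point (`0 < fn < n_pos`, `fp > 0`).
#' @param beta Positive scalar.
#' @param h Finite-difference step.
#' @return List with the closed-form derivatives (`d_fp`, `d_fn`), their
#'   numeric estimates, the implied weight `wpos` (= `d_fn / d_fp`), and
#'   `max_rel_err`.
#' @export
finite_diff_check <- function(n_pos, fn, fp, beta = 1, h = 1e-4) {
  check_beta(beta)
  if (fn <= 0 || fn >= n_pos || fp <= 0) {
    abort("Need an interior point: 0 < fn < n_pos and fp > 0.")
  }
  b2 <- beta^2
  den <- (1 + b2) * n_pos - fn + fp
  d_fp <- -(1 + b2) * (n_pos - fn) / den^2
  d_fn <- -(1 + b2) * (b2 * n_pos + fp) / den^2
  num_fp <- (fbeta_continuous(n_pos, fn, fp + h, beta) -
               fbeta_continuous(n_pos, fn, fp - h, beta)) / (2 * h)
  num_fn <- (fbeta_continuous(n_pos, fn + h, fp, beta) -
               fbeta_continuous(n_pos, fn - h, fp, beta)) / (2 * h)
  list(
    d_fp = d_fp, d_fn = d_fn, d_fp_num = num_fp, d_fn_num = num_fn,
    wpos = d_fn / d_fp,
    max_rel_err = max(abs(num_fp - d_fp) / abs(d_fp),
                      abs(num_fn - d_fn) / abs(d_fn))
  )
}

#' One-tailed Welch t-test
#'
#' Unpaired t statistic with unequal variances and Satterthwaite degrees of
#' freedom; the p-value is for the alternative `mean(a) > mean(b)`. With
#' two degenerate (zero-variance) samples the p-value is 0, 0.5 or 1 by the
#' sign of the mean difference.
#'
#' @param a,b Numeric vectors with at least two values each.
#' @return The one-tailed p-value.
#' @export
welch_one_tailed <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    abort("Each sample needs at least two values.")
  }
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  if (va + vb == 0) {
    d <- mean(a) - mean(b)
    return(if (d > 0) 0 else if (d < 0) 1 else 0.5)
  }
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  pt(t_stat, df, lower.tail = FALSE)
}

run_one_config <- function(kind, wpos, train_data, val_data, config, seed) {
  cfg <- config
  cfg$seed <- as.integer(seed)
  h <- switch(kind,
    fola = fola_train(train_data, val_data, cfg),
    fola_unbounded = {
      cfg$bounding_factor <- NULL
      fola_train(train_data, val_data, cfg)
    },
    soft_fbeta = soft_fbeta_train(train_data, val_data, cfg),
    fixed = fixed_weight_train(train_data, val_data, wpos, cfg),
    abort(sprintf("Unknown configuration kind '%s'.", kind))
  )
  counts <- h$epochs$counts[[nrow(h$epochs)]]
  probs <- predict_proba(h$learner, as_training_data(val_data, "val")$features)
  labs <- as_training_data(val_data, "val")$labels
  true_sets <- apply(labs == 1, 1L, which, simplify = FALSE)
  pred_sets <- apply(probs >= 0.5, 1L, which, simplify = FALSE)
  final_w <- if (is.null(h$final_weights)) NA_real_ else median(h$final_weights$wpos)
  rep <- h$final_report
  pooled <- precision_recall(pool_counts(counts))
  tibble(
    configuration = if (kind == "fixed") sprintf("wpos=%.3g", wpos) else kind,
    kind = kind,
    wpos = if (kind == "fixed") wpos else NA_real_,
    seed = as.integer(seed),
    f = if (config$mode == "micro") rep$micro_f else rep$macro_f,
    precision = pooled$precision,
    recall = pooled$recall,
    iou = instance_iou(true_sets, pred_sets),
    final_wpos = final_w
  )
}

#' Fixed-weight grid search
#'
#' Trains with each weight of a (logarithmically spaced) grid held fixed,
#' across seeds, and reports final metrics per run — the trial-and-error
#' search the epoch-wise estimate replaces. The grid argmax should sit
#' within one grid step of the estimated weight.
#'
#' @param train_data,val_data Datasets as in [fola_train()].
#' @param grid Positive weights to evaluate; the default is the
#'   log-spaced grid (ratio about sqrt(2)) used in the ablations.
#' @param config A [trainer_config()].
#' @param seeds Integer vector of seeds (one run per grid point and seed).
#' @return An `ablation_result` tibble: one row per (configuration, seed)
#'   with final F, precision, recall, IoU.
#' @export
grid_search_wpos <- function(train_data, val_data = NULL,
                             grid = c(1.30, 1.84, 2.60, 3.68, 5.20),
                             config = trainer_config(), seeds = 1:3) {
  if (any(grid <= 0)) abort("`grid` must be positive.")
  if (inherits(train_data, "ml_task") && is.null(val_data)) {
    val_data <- dataset_role(train_data, "val")
    train_data <- dataset_role(train_data, "train")
  }
  rows <- purrr::map(grid, function(w) {
    purrr::map(seeds, function(s) {
      run_one_config("fixed", w, train_data, val_data, config, s)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  structure(rows, class = c("ablation_result", class(rows)))
}

#' Run the loss-function ablation
#'
#' Compares the epoch-wise weight-estimation algorithm against the soft
#' F-beta loss, the balanced-accuracy weight `n_neg/n_pos`, a fixed-weight
#' grid and (in macro mode) the unbounded variant, across seeds — the
#' small-scale structural analogue of the full ablation studies.
#'
#' @inheritParams grid_search_wpos
#' @param configurations Character vector among `"fola"`,
#'   `"fola_unbounded"`, `"soft_fbeta"`, `"balanced"`, `"grid"`.
#' @param grid Weights used when `"grid"` is included.
#' @param out_dir Optional directory: writes `ablation.csv` (per-run rows)
#'   and `ablation_summary.json` (mean +/- sd and Welch p-values against
#'   the fola rows).
#' @return An `ablation_result` tibble of per-run rows; the per-configuration
#'   summary is attached as attribute `"summary"` and via
#'   [summarize_ablation()].
#' @export
run_ablation <- function(train_data, val_data = NULL,
                         configurations = c("fola", "soft_fbeta", "balanced"),
                         grid = c(1.30, 1.84, 2.60, 3.68, 5.20),
                         config = trainer_config(), seeds = 1:3,
                         out_dir = NULL) {
  if (inherits(train_data, "ml_task") && is.null(val_data)) {
    val_data <- dataset_role(train_data, "val")
    train_data <- dataset_role(train_data, "train")
  }
  tr <- as_training_data(train_data, "train")
  balanced_w <- wpos_upper_bound(sum(tr$labels), length(tr$labels) - sum(tr$labels))

  rows <- purrr::map(configurations, function(kind) {
    runs <- if (kind == "grid") {
      tidyr::expand_grid(w = grid, s = seeds)
    } else if (kind == "balanced") {
      tidyr::expand_grid(w = balanced_w, s = seeds)
    } else {
      tidyr::expand_grid(w = NA_real_, s = seeds)
    }
    purrr::map2(runs$w, runs$s, function(w, s) {
      k <- if (kind %in% c("grid", "balanced")) "fixed" else kind
      out <- run_one_config(k, w, train_data, val_data, config, s)
      if (kind == "balanced") out$configuration <- "balanced"
      out
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  summary <- summarize_ablation(rows)
  attr(rows, "summary") <- summary
  class(rows) <- c("ablation_result", setdiff(class(rows), "ablation_result"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(dplyr::select(rows, !dplyr::any_of("counts")),
                     file.path(out_dir, "ablation.csv"))
    jsonlite::write_json(summary, file.path(out_dir, "ablation_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  rows
}

#' Summarize ablation runs per configuration
#'
#' Mean and standard deviation of the final score per configuration
#' (standard deviations only over two or more seeds) plus the one-tailed
#' Welch p-value of the `fola` rows against each other configuration, when
#' `fola` is present.
#'
#' @param rows An `ablation_result` from [run_ablation()] or
#'   [grid_search_wpos()].
#' @return A tibble with one row per configuration.
#' @export
summarize_ablation <- function(rows) {
  summ <- rows |>
    dplyr::group_by(.data$configuration) |>
    dplyr::summarise(
      n_seeds = dplyr::n(),
      mean_f = mean(.data$f),
      sd_f = ifelse(dplyr::n() >= 2, stats::sd(.data$f), NA_real_),
      mean_precision = mean(.data$precision),
      mean_recall = mean(.data$recall),
      mean_iou = mean(.data$iou),
      .groups = "drop"
    )
  fola_f <- rows$f[rows$configuration == "fola"]
  if (length(fola_f) >= 2) {
    summ$p_vs_fola <- vapply(summ$configuration, function(cfg) {
      if (cfg == "fola") return(NA_real_)
      other <- rows$f[rows$configuration == cfg]
      if (length(other) < 2) return(NA_real_)
      welch_one_tailed(fola_f, other)
    }, 0)
  }
  summ
}
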