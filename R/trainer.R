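#' Trainer configuration
#'
#' Collects the knobs of the epoch-wise weight-re-estimation trainer. The
#' decision threshold is fixed at 0.5 throughout: a well-trained
#' cost-sensitive model should perform well at the predetermined operating
#' point, so thresholds are never tuned post hoc.
#'
#' @param beta Target F-beta; 1 optimizes F1.
#' @param mode `"micro"` (one pooled weight) or `"macro"` (per-label
#'   weights).
#' @param epochs Number of training epochs.
#' @param initial_wpos `"upper_bound"` (the balanced-accuracy weight
#'   `n_neg/n_pos`, the recommended start when no estimate exists) or a
#'   positive scalar / per-label vector.
#' @param bounding_factor Macro-mode weight cap as a multiple of the median
#'   weight; defaults to 2 in macro mode and `NULL` (no bounding) in micro
#'   mode.
#' @param batch_size Mini-batch size for the reference learner.
#' @param max_lr Peak learning rate.
#' @param lr_schedule `"clr"` (triangular cyclical schedule rising from 5%
#'   of `max_lr`) or `"constant"`.
#' @param cycle_len Steps per triangular cycle; default one cycle spanning
#'   the whole run.
#' @param warmup_epochs Linear learning-rate warmup; defaults to 0 for the
#'   cyclical schedule (which already starts low) and 2 otherwise, so a
#'   poor initial weight estimate cannot derail early training.
#' @param refine_passes,refine_tol Multi-pass refinement: maximum number of
#'   re-training passes with frozen weights and the relative weight-change
#'   threshold declaring convergence.
#' @param seed Integer seed controlling learner initialization and data
#'   shuffling.
#' @return An object of class `trainer_config`.
#' @export
trainer_config <- function(beta = 1, mode = c("micro", "macro"), epochs = 20L,
                           initial_wpos = "upper_bound", bounding_factor = NULL,
                           batch_size = 256L, max_lr = 1,
                           lr_schedule = c("clr", "constant"), cycle_len = NULL,
                           warmup_epochs = NULL, refine_passes = 3L,
                           refine_tol = 0.02, seed = 1L) {
  mode <- match.arg(mode)
  lr_schedule <- match.arg(lr_schedule)
  check_beta(beta)
  if (epochs < 1L) abort("`epochs` must be >= 1.")
  if (is.null(bounding_factor) && mode == "macro") bounding_factor <- 2
  if (is.null(warmup_epochs)) warmup_epochs <- if (lr_schedule == "clr") 0L else 2L
  structure(
    list(beta = beta, mode = mode, epochs = as.integer(epochs),
         initial_wpos = initial_wpos, bounding_factor = bounding_factor,
         threshold = 0.5, batch_size = as.integer(batch_size), max_lr = max_lr,
         lr_schedule = lr_schedule, cycle_len = cycle_len,
         warmup_epochs = warmup_epochs, refine_passes = as.integer(refine_passes),
         refine_tol = refine_tol, seed = as.integer(seed)),
    class = "trainer_config"
  )
}

# Accept either list(features, labels) or an ml_task (+ role).
as_training_data <- function(x, role = NULL, arg = "data") {
  if (inherits(x, "ml_task")) return(dataset_role(x, role %||% "train"))
  if (is.list(x) && !is.null(x$features) && !is.null(x$labels)) {
    out <- list(
      features = as_prob_matrix(x$features, "features"),
      labels = as_prob_matrix(x$labels, "labels")
    )
    if (nrow(out$features) != nrow(out$labels)) {
      abort(sprintf("`%s`: features and labels disagree on the number of rows.", arg))
    }
    if (nrow(out$features) == 0L) abort(sprintf("`%s` is empty.", arg))
    return(out)
  }
  abort(sprintf("`%s` must be an ml_task or a list(features, labels).", arg))
}

resolve_initial_weights <- function(config, labels) {
  L <- ncol(labels)
  n_weights <- if (config$mode == "micro") 1L else L
  init <- config$initial_wpos
  if (identical(init, "upper_bound")) {
    np <- colSums(labels)
    nn <- nrow(labels) - np
    if (any(np == 0)) {
      abort("Some labels have no positive training samples; supply `initial_wpos` explicitly.")
    }
    init <- if (config$mode == "micro") {
      wpos_upper_bound(sum(np), sum(nn))
    } else {
      wpos_upper_bound(np, nn)
    }
  }
  if (!is.numeric(init) || !(length(init) %in% c(1L, n_weights))) {
    abort(sprintf("`initial_wpos` must be \"upper_bound\" or 1 or %d value(s).", n_weights))
  }
  class_weights(rep_len(init, n_weights), beta = config$beta,
                bounding_factor = config$bounding_factor,
                initial_wpos = rep_len(init, n_weights))
}

#' Triangular cyclical learning rate
#'
#' Linear rise from the base rate (5% of `max_lr`) to `max_lr` over half a
#' cycle, then back down, repeating.
#'
#' @param step 0-based global step index (vectorized).
#' @param cycle_len Steps per full cycle (`>= 2`).
#' @param max_lr Peak rate.
#' @return Learning rate(s).
#' @export
clr_rate <- function(step, cycle_len, max_lr) {
  if (cycle_len < 2) abort("`cycle_len` must be >= 2.")
  if (max_lr <= 0) abort("`max_lr` must be positive.")
  base <- 0.05 * max_lr
  pos <- (step %% cycle_len) / cycle_len
  tri <- 1 - abs(2 * pos - 1)
  base + (max_lr - base) * tri
}

make_lr_fun <- function(config, steps_per_epoch) {
  total <- steps_per_epoch * config$epochs
  cycle <- config$cycle_len %||% max(2L, total)
  warm <- config$warmup_epochs * steps_per_epoch
  function(step) {
    lr <- if (config$lr_schedule == "clr") {
      clr_rate(step, cycle, config$max_lr)
    } else {
      config$max_lr
    }
    if (warm > 0) lr <- lr * min(1, (step + 1) / warm)
    lr
  }
}

epoch_eval <- function(probs, labels, config) {
  counts <- accumulate_counts(probs, labels, config$threshold)
  pooled <- precision_recall(pool_counts(counts))
  fb <- if (config$mode == "micro") {
    micro_fbeta(counts, config$beta)
  } else {
    macro_fbeta(counts, config$beta)$macro_f
  }
  list(counts = counts, precision = pooled$precision, recall = pooled$recall,
       fbeta = fb)
}

# Shared epoch loop. `weights` is NULL for the soft F-beta objective;
# `update` re-estimates weights from validation counts after each epoch.
train_loop <- function(train_data, val_data, config, learner, weights,
                       update, loss_kind) {
  set.seed(config$seed)
  tr <- as_training_data(train_data, "train", "train_data")
  va <- as_training_data(val_data, "val", "val_data")
  L <- ncol(tr$labels)
  if (is.null(learner)) learner <- logistic_learner(ncol(tr$features), L)
  steps_per_epoch <- length(seq(1L, nrow(tr$features), by = config$batch_size))
  lr_fun <- make_lr_fun(config, steps_per_epoch)

  rows <- vector("list", config$epochs)
  eval_last <- NULL
  for (epoch in seq_len(config$epochs)) {
    spec <- if (loss_kind == "weighted_bce") {
      loss_spec("weighted_bce", weights = weights, mode = config$mode)
    } else {
      loss_spec("soft_fbeta", beta = config$beta, mode = config$mode)
    }
    fit <- train_one_epoch(learner, tr$features, tr$labels, spec, lr_fun,
                           batch_size = config$batch_size,
                           step_offset = (epoch - 1L) * steps_per_epoch)
    learner <- fit$learner
    eval_last <- epoch_eval(predict_proba(learner, va$features), va$labels, config)
    rows[[epoch]] <- tibble(
      epoch = epoch,
      wpos = list(if (is.null(weights)) NA_real_ else weights$wpos),
      val_precision = eval_last$precision,
      val_recall = eval_last$recall,
      val_fbeta = eval_last$fbeta,
      mean_loss = fit$mean_loss,
      counts = list(eval_last$counts)
    )
    if (update) {
      weights <- update_class_weights(eval_last$counts, weights, config$mode)
    }
  }

  structure(
    list(
      epochs = dplyr::bind_rows(rows),
      final_weights = weights,
      final_report = macro_fbeta(eval_last$counts, config$beta),
      learner = learner,
      config = config,
      seed = config$seed
    ),
    class = "fola_history"
  )
}

#' Train with epoch-wise re-estimation of the positive-class weight
#'
#' The core algorithm: each epoch trains the learner for one pass under the
#' weighted binary cross-entropy built from the current weight(s), evaluates
#' precision and recall on the validation split at the fixed 0.5 threshold,
#' and re-derives the weight(s) via `wpos = 1/Pr + beta^2/Rc - 1` for the
#' next epoch. Labels with no validation true positives fall back to their
#' initial weight; in macro mode the updated weights are median-bounded when
#' a bounding factor is configured. Validation — never training — metrics
#' drive the update, and test data must never be passed as `val_data`
#' (evaluate test sets with [fixed_weight_train()] instead, using the
#' weights estimated here).
#'
#' @param train_data,val_data Disjoint datasets: `list(features, labels)`
#'   or an [make_multilabel_task()] / [make_binary_gaussian_task()] object
#'   (whose `train` and `val` splits are then used; pass the task as
#'   `train_data` and omit `val_data`).
#' @param config A [trainer_config()].
#' @param learner A learner implementing the [learner-interface], or `NULL`
#'   to create a fresh [logistic_learner()].
#' @return A `fola_history`: per-epoch records (weights used, validation
#'   precision/recall/F-beta, mean training loss, validation counts), the
#'   final weights (from the last validation evaluation), the final metric
#'   report, and the trained learner. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
fola_train <- function(train_data, val_data = NULL, config = trainer_config(),
                       learner = NULL) {
  if (inherits(train_data, "ml_task") && is.null(val_data)) {
    val_data <- dataset_role(train_data, "val")
    train_data <- dataset_role(train_data, "train")
  }
  tr <- as_training_data(train_data, "train", "train_data")
  weights <- resolve_initial_weights(config, tr$labels)
  train_loop(train_data, val_data, config, learner, weights,
             update = TRUE, loss_kind = "weighted_bce")
}

#' Train with a frozen positive-class weight
#'
#' The same epoch loop as [fola_train()] but the weight is never updated.
#' This is the test-set protocol (weights estimated on validation data are
#' frozen, so no information leaks from test predictions) and the workhorse
#' of the fixed-weight ablation grid. `wpos = 1` reduces to plain BCE.
#'
#' @inheritParams fola_train
#' @param eval_data Dataset evaluated after every epoch (a test or
#'   validation split).
#' @param wpos Positive scalar, per-label vector, or [class_weights()].
#' @return A `fola_history` (with constant weights).
#' @export
fixed_weight_train <- function(train_data, eval_data = NULL, wpos,
                               config = trainer_config(), learner = NULL) {
  if (inherits(train_data, "ml_task") && is.null(eval_data)) {
    eval_data <- dataset_role(train_data, "val")
    train_data <- dataset_role(train_data, "train")
  }
  tr <- as_training_data(train_data, "train", "train_data")
  L <- ncol(tr$labels)
  n_weights <- if (config$mode == "micro") 1L else L
  weights <- if (inherits(wpos, "class_weights")) wpos else {
    class_weights(rep_len(wpos, n_weights), beta = config$beta,
                  bounding_factor = config$bounding_factor)
  }
  train_loop(train_data, eval_data, config, learner, weights,
             update = FALSE, loss_kind = "weighted_bce")
}

#' Train under the soft F-beta loss baseline
#'
#' Trains the learner by directly minimizing the negated batch-soft F-beta
#' score (no cross-entropy, no class weights), evaluating on `val_data`
#' each epoch. Provided as the comparison baseline.
#'
#' @inheritParams fola_train
#' @return A `fola_history` (weights recorded as `NA`).
#' @export
soft_fbeta_train <- function(train_data, val_data = NULL,
                             config = trainer_config(), learner = NULL) {
  if (inherits(train_data, "ml_task") && is.null(val_data)) {
    val_data <- dataset_role(train_data, "val")
    train_data <- dataset_role(train_data, "train")
  }
  train_loop(train_data, val_data, config, learner, weights = NULL,
             update = FALSE, loss_kind = "soft_fbeta")
}

#' Multi-pass refinement of the positive-class weight
#'
#' Pass 1 runs the epoch-wise algorithm; each later pass retrains from
#' scratch with the previous pass's final weights held fixed and re-derives
#' weights from its final validation metrics. Passes stop when the largest
#' relative weight change drops below `refine_tol` (convergence) or
#' `refine_passes` is exhausted.
#'
#' @inheritParams fola_train
#' @param learner_factory Zero-argument function returning a fresh learner,
#'   or `NULL` for fresh [logistic_learner()]s.
#' @return A list with final `weights`, one `fola_history` per pass in
#'   `histories`, and `converged`.
#' @export
refine_wpos <- function(train_data, val_data = NULL, config = trainer_config(),
                        learner_factory = NULL) {
  if (inherits(train_data, "ml_task") && is.null(val_data)) {
    val_data <- dataset_role(train_data, "val")
    train_data <- dataset_role(train_data, "train")
  }
  new_learner <- function() if (is.null(learner_factory)) NULL else learner_factory()
  histories <- list()
  h <- fola_train(train_data, val_data, config, new_learner())
  histories[[1]] <- h
  weights <- h$final_weights
  # an infinite tolerance accepts the first estimate outright
  converged <- is.infinite(config$refine_tol)
  pass <- 1L
  while (!converged && pass < max(1L, config$refine_passes)) {
    pass <- pass + 1L
    h <- fixed_weight_train(train_data, val_data, weights, config, new_learner())
    new_weights <- update_class_weights(
      h$epochs$counts[[nrow(h$epochs)]], weights, config$mode
    )
    rel <- max(abs(new_weights$wpos - weights$wpos) / weights$wpos)
    histories[[pass]] <- h
    weights <- new_weights
    converged <- rel < config$refine_tol
  }
  list(weights = weights, histories = histories, converged = converged)
}

#' Predicted label sets at the fixed threshold
#'
#' @param learner A trained learner.
#' @param features Feature matrix.
#' @param threshold Inclusive decision threshold (default 0.5).
#' @return A list (one element per row) of integer label indices whose
#'   predicted probability reaches the threshold.
#' @export
predict_sets <- function(learner, features, threshold = 0.5) {
  probs <- predict_proba(learner, features)
  apply(probs >= threshold, 1L, which, simplify = FALSE)
}
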