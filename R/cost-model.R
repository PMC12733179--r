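#' Class-weight container for cost-sensitive training
#'
#' Bundles the positive-class weight(s) `wpos` (the negative-class weight is
#' fixed at 1: only the ratio matters), the F-beta `beta` they target, an
#' optional macro-mode bounding factor, and the user-supplied initial value
#' used as fallback whenever a validation-based update is undefined.
#'
#' @param wpos Positive numeric vector: length 1 in micro mode, one entry
#'   per label in macro mode.
#' @param beta Positive scalar.
#' @param bounding_factor `NULL` (no bounding) or a scalar `>= 1`; macro-mode
#'   weights are capped at `bounding_factor` times their median.
#' @param initial_wpos Fallback value(s) used when a label has zero true
#'   positives on validation; recycled to the length of `wpos`.
#' @return An object of class `class_weights`.
#' @export
class_weights <- function(wpos, beta = 1, bounding_factor = NULL,
                          initial_wpos = wpos) {
  if (!is.numeric(wpos) || length(wpos) < 1L || any(is.na(wpos)) || any(wpos <= 0)) {
    abort("`wpos` must be positive.")
  }
  check_beta(beta)
  if (!is.null(bounding_factor)) {
    if (!is.numeric(bounding_factor) || length(bounding_factor) != 1L ||
        bounding_factor < 1) {
      abort("`bounding_factor` must be a single number >= 1 (or NULL).")
    }
  }
  if (any(is.na(initial_wpos)) || any(initial_wpos <= 0)) {
    abort("`initial_wpos` must be positive.")
  }
  structure(
    list(
      wpos = as.numeric(wpos),
      wneg = 1,
      beta = beta,
      bounding_factor = bounding_factor,
      initial_wpos = rep_len(as.numeric(initial_wpos), length(wpos))
    ),
    class = "class_weights"
  )
}

#' @export
print.class_weights <- function(x, ...) {
  cat(sprintf(
    "<class_weights> beta = %g, wneg = 1, %d weight(s)%s\n",
    x$beta, length(x$wpos),
    if (is.null(x$bounding_factor)) "" else sprintf(", bounding factor %g", x$bounding_factor)
  ))
  if (length(x$wpos) <= 10) {
    cat("  wpos:", paste(signif(x$wpos, 5), collapse = " "), "\n")
  } else {
    cat(sprintf(
      "  wpos: min %.3g / median %.3g / max %.3g\n",
      min(x$wpos), median(x$wpos), max(x$wpos)
    ))
  }
  invisible(x)
}

#' Optimal positive-class weight from precision and recall
#'
#' The weight that makes weighted cross-entropy training optimize the F-beta
#' score: `wpos = 1/Pr + beta^2/Rc - 1`, the (negated) ratio of the partial
#' derivatives of F-beta with respect to false negatives and false
#' positives. Evaluated at the optimal model's precision and recall, it is
#' the cost ratio under which that model is cost-optimal.
#'
#' @param pr,rc Precision and recall in `(0, 1]` (vectorized). A zero or
#'   `NA` entry yields `NA` — the undefined-weight signal; callers fall back
#'   to the initial weight.
#' @param beta Positive scalar.
#' @return Numeric vector of weights (`NA` where undefined).
#' @export
#' @examples
#' wpos_from_pr_rc(0.5, 0.5)       # 3
#' wpos_from_pr_rc(1, 1)           # 1, the balanced case
wpos_from_pr_rc <- function(pr, rc, beta = 1) {
  check_beta(beta)
  if (any(pr < 0 | pr > 1, na.rm = TRUE) || any(rc < 0 | rc > 1, na.rm = TRUE)) {
    abort("`pr` and `rc` must lie in [0, 1].")
  }
  out <- 1 / pr + beta^2 / rc - 1
  out[!is.na(pr) & !is.na(rc) & (pr == 0 | rc == 0)] <- NA_real_
  out
}

#' Balanced-accuracy upper bound for the positive-class weight
#'
#' `n_neg / n_pos` equalizes the total weight on each class and optimizes
#' balanced accuracy; the F-beta-optimal weight lies in `[1, n_neg/n_pos]`,
#' so this is the recommended starting point when no estimate of the final
#' precision/recall is available.
#'
#' @param n_pos,n_neg Positive and negative sample counts (vectorized).
#' @return `n_neg / n_pos`.
#' @export
wpos_upper_bound <- function(n_pos, n_neg) {
  if (any(n_pos <= 0)) abort("`n_pos` must be positive.")
  if (any(n_neg < 0)) abort("`n_neg` must be nonnegative.")
  n_neg / n_pos
}

#' Cap macro-mode weights at a multiple of their median
#'
#' Extreme per-label weights cause overshooting gradient steps for the
#' affected labels; values above `factor * median(wpos)` are set to that
#' cap, while lower values are left unchanged. The median is taken over the
#' supplied (pre-bounding) vector.
#'
#' @param wpos Positive numeric vector of per-label weights.
#' @param factor Scalar `>= 1`; the recommended default is 2.
#' @return The capped vector.
#' @export
#' @examples
#' bound_weights(c(1, 2, 4, 100), factor = 2)  # cap = 6
bound_weights <- function(wpos, factor = 2) {
  if (length(wpos) == 0L) abort("`wpos` must be non-empty.")
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1) {
    abort("`factor` must be a single number >= 1.")
  }
  cap <- factor * median(wpos)
  pmin(wpos, cap)
}

#' Re-estimate class weights from validation confusion counts
#'
#' The per-epoch weight update: micro mode derives a single weight from the
#' pooled validation precision/recall; macro mode derives one weight per
#' label and then applies median bounding when a bounding factor is set. Any
#' label with zero validation true positives (undefined update) reverts to
#' its initial weight. Micro-mode weights are additionally capped at the
#' balanced-accuracy weight `n_neg/n_pos`, beyond which the update has no
#' rational interpretation.
#'
#' @param counts Per-label validation counts from [accumulate_counts()]
#'   (never training-set counts, which would underestimate the weight).
#' @param weights Current [class_weights()].
#' @param mode `"micro"` or `"macro"`.
#' @return Updated `class_weights` (same beta, bounding factor, initials).
#' @export
update_class_weights <- function(counts, weights, mode = c("micro", "macro")) {
  mode <- match.arg(mode)
  check_counts(counts)
  if (!inherits(weights, "class_weights")) abort("`weights` must be a class_weights object.")
  beta <- weights$beta

  if (mode == "micro") {
    pooled <- precision_recall(pool_counts(counts))
    w <- if (pooled$tp == 0) {
      weights$initial_wpos[1]
    } else {
      raw <- wpos_from_pr_rc(pooled$precision, pooled$recall, beta)
      ub <- wpos_upper_bound(pooled$n_pos, pooled$n_neg)
      if (raw > ub) {
        warn(sprintf("Micro wpos update %.3g capped at n_neg/n_pos = %.3g.", raw, ub))
        ub
      } else {
        raw
      }
    }
    return(class_weights(w, beta = beta, bounding_factor = weights$bounding_factor,
                         initial_wpos = weights$initial_wpos[1]))
  }

  if (length(weights$wpos) != nrow(counts)) {
    abort(sprintf(
      "Macro mode needs one weight per label: got %d weights for %d labels.",
      length(weights$wpos), nrow(counts)
    ))
  }
  pr_rc <- precision_recall(counts)
  raw <- wpos_from_pr_rc(pr_rc$precision, pr_rc$recall, beta)
  fallback <- pr_rc$tp == 0 | is.na(raw)
  raw[fallback] <- weights$initial_wpos[fallback]
  bounded <- if (is.null(weights$bounding_factor)) raw else {
    bound_weights(raw, weights$bounding_factor)
  }
  class_weights(bounded, beta = beta, bounding_factor = weights$bounding_factor,
                initial_wpos = weights$initial_wpos)
}

#' Decision threshold implied by a positive-class weight
#'
#' Under the cost-sensitive Bayes rule, a classifier with positive-class
#' cost `wpos` predicts positive when the posterior reaches
#' `1 / (1 + wpos)`. For the F1-optimal weight this equals half the optimal
#' F1 score — the classical plug-in-threshold characterization — which
#' connects the weight formula to threshold-based F-measure theory.
#'
#' @param wpos Positive weight(s).
#' @return Threshold(s) in `(0, 1)`.
#' @export
implied_threshold <- function(wpos) {
  if (any(wpos <= 0)) abort("`wpos` must be positive.")
  1 / (1 + wpos)
}

#' Write a per-epoch weight audit table to CSV
#'
#' @param raw,bounded Numeric vectors of pre- and post-bounding weights.
#' @param path Output CSV path.
#' @return The audit tibble, invisibly.
#' @export
write_weight_audit <- function(raw, bounded, path) {
  tbl <- tibble(
    label_id = seq_along(raw),
    wpos_raw = raw,
    wpos_bounded = rep_len(bounded, length(raw))
  )
  readr::write_csv(tbl, path)
  invisible(tbl)
}
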