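#' Loss specification
#'
#' Describes the training objective: either the class-weighted binary
#' cross-entropy (the cost-sensitive route to F-beta optimization) or the
#' soft F-beta baseline that uses the negated F-beta score on probabilistic
#' counts as the loss.
#'
#' @param kind `"weighted_bce"` or `"soft_fbeta"`.
#' @param weights A [class_weights()] object (required for `weighted_bce`).
#' @param beta Positive scalar, used by `soft_fbeta`.
#' @param prob_clamp Probabilities are clamped to
#'   `[prob_clamp, 1 - prob_clamp]` before logarithms; must lie in
#'   `(0, 0.01]`.
#' @param mode `"micro"` (counts pooled over the whole batch) or `"macro"`
#'   (per-label scores averaged); affects `soft_fbeta` and per-label weight
#'   broadcasting.
#' @return An object of class `loss_spec`.
#' @export
loss_spec <- function(kind = c("weighted_bce", "soft_fbeta"), weights = NULL,
                      beta = 1, prob_clamp = 1e-7, mode = c("micro", "macro")) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  check_beta(beta)
  if (!is.numeric(prob_clamp) || length(prob_clamp) != 1L ||
      prob_clamp <= 0 || prob_clamp > 0.01) {
    abort("`prob_clamp` must lie in (0, 0.01].")
  }
  if (kind == "weighted_bce") {
    if (!inherits(weights, "class_weights")) {
      abort("`weighted_bce` requires a class_weights object in `weights`.")
    }
    beta <- weights$beta
  }
  structure(
    list(kind = kind, weights = weights, beta = beta,
         prob_clamp = prob_clamp, mode = mode),
    class = "loss_spec"
  )
}

clamp_probs <- function(probs, eps) pmin(pmax(probs, eps), 1 - eps)

# Per-element weight matrix: wpos where the label is positive, 1 elsewhere.
elementwise_weights <- function(labels, wpos) {
  L <- ncol(labels)
  if (length(wpos) == 1L) wpos <- rep(wpos, L)
  if (length(wpos) != L) {
    abort(sprintf("Need 1 or %d positive-class weights, got %d.", L, length(wpos)))
  }
  w <- matrix(1, nrow(labels), L)
  wmat <- matrix(wpos, nrow(labels), L, byrow = TRUE)
  w[labels == 1] <- wmat[labels == 1]
  w
}

#' Class-weighted binary cross-entropy loss
#'
#' Element loss `-w [y log x + (1 - y) log(1 - x)]` with `w = wpos` for
#' positive elements and 1 for negative ones, reduced by the mean over all
#' `n x L` elements. The mean reduction couples the weight scale with the
#' learning rate and is the convention used by the reference learner.
#'
#' @param probs Predicted probability matrix `[n x L]` (or vector).
#' @param labels Binary matrix of the same shape.
#' @param weights A [class_weights()] object; per-label weights are
#'   broadcast across rows.
#' @param prob_clamp Clamp applied before logarithms (numerical stability).
#' @return Nonnegative scalar loss.
#' @export
#' @examples
#' weighted_bce(0.5, 1, class_weights(3))  # 3 * log(2)
weighted_bce <- function(probs, labels, weights, prob_clamp = 1e-7) {
  probs <- as_prob_matrix(probs, "probs")
  labels <- as_prob_matrix(labels, "labels")
  check_same_shape(probs, labels)
  check_binary(labels)
  if (!inherits(weights, "class_weights")) abort("`weights` must be a class_weights object.")
  x <- clamp_probs(probs, prob_clamp)
  w <- elementwise_weights(labels, weights$wpos)
  mean(-w * (labels * log(x) + (1 - labels) * log1p(-x)))
}

#' Differentiable soft confusion counts
#'
#' Replaces hard thresholded counts with sums of predicted probability:
#' `TP = sum(O * T)`, `FP = sum(O * (1 - T))`, `FN = sum((1 - O) * T)` over
#' the batch, where `O` is the predicted probability and `T` the label.
#' When predictions are binary these equal the hard counts exactly.
#'
#' @inheritParams weighted_bce
#' @param by_label If `TRUE`, return per-label (column) sums instead of
#'   batch totals.
#' @return A list with numeric components `tp`, `fp`, `fn` (scalars, or
#'   per-label vectors when `by_label = TRUE`).
#' @export
soft_counts <- function(probs, labels, by_label = FALSE) {
  probs <- as_prob_matrix(probs, "probs")
  labels <- as_prob_matrix(labels, "labels")
  check_same_shape(probs, labels)
  reduce <- if (by_label) colSums else sum
  list(
    tp = reduce(probs * labels),
    fp = reduce(probs * (1 - labels)),
    fn = reduce((1 - probs) * labels)
  )
}

soft_fbeta_from_counts <- function(tp, fp, fn, beta) {
  b2 <- beta^2
  den <- (1 + b2) * tp + b2 * fn + fp
  ifelse(den > 0, (1 + b2) * tp / den, 0)
}

#' Soft F-beta loss
#'
#' The negated F-beta score computed on the soft counts of the current
#' batch; minimizing it maximizes a differentiable surrogate of the score.
#' Degenerate batches whose count denominator is zero (no positive mass at
#' all) are assigned a loss of 0 with zero gradient — the minimal handling
#' of the undefined-gradient case this surrogate is known for.
#'
#' @inheritParams weighted_bce
#' @param beta Positive scalar.
#' @param mode `"micro"` pools soft counts over the whole batch; `"macro"`
#'   averages per-label soft F-beta scores.
#' @return Scalar loss in `[-1, 0]`.
#' @export
soft_fbeta_loss <- function(probs, labels, beta = 1, mode = c("micro", "macro")) {
  mode <- match.arg(mode)
  check_beta(beta)
  sc <- soft_counts(probs, labels, by_label = (mode == "macro"))
  -mean(soft_fbeta_from_counts(sc$tp, sc$fp, sc$fn, beta))
}

#' Evaluate a loss specification on a batch
#'
#' @param spec A [loss_spec()].
#' @inheritParams weighted_bce
#' @return Scalar loss value.
#' @export
loss_value <- function(spec, probs, labels) {
  if (!inherits(spec, "loss_spec")) abort("`spec` must be a loss_spec.")
  switch(spec$kind,
    weighted_bce = weighted_bce(probs, labels, spec$weights, spec$prob_clamp),
    soft_fbeta = soft_fbeta_loss(probs, labels, spec$beta, spec$mode)
  )
}

# Gradient of the loss w.r.t. the logits Z (probs = plogis(Z)).
# For weighted BCE the chain collapses to w * (p - y) / (n L); for the soft
# F-beta loss d(denominator)/dp = 1 for every element, which gives the
# closed forms below.
loss_logit_grad <- function(spec, probs, labels) {
  n_elem <- length(probs)
  if (spec$kind == "weighted_bce") {
    w <- elementwise_weights(labels, spec$weights$wpos)
    return(w * (probs - labels) / n_elem)
  }
  b2 <- spec$beta^2
  dsig <- probs * (1 - probs)
  if (spec$mode == "micro") {
    sc <- soft_counts(probs, labels)
    D <- (1 + b2) * sc$tp + b2 * sc$fn + sc$fp
    if (D <= 0) return(matrix(0, nrow(probs), ncol(probs)))
    A <- (1 + b2) * sc$tp
    dLdp <- (A - (1 + b2) * labels * D) / D^2
    return(dLdp * dsig)
  }
  sc <- soft_counts(probs, labels, by_label = TRUE)
  L <- ncol(probs)
  D <- (1 + b2) * sc$tp + b2 * sc$fn + sc$fp
  A <- (1 + b2) * sc$tp
  g <- matrix(0, nrow(probs), L)
  ok <- D > 0
  if (any(ok)) {
    Dm <- matrix(D, nrow(probs), L, byrow = TRUE)
    Am <- matrix(A, nrow(probs), L, byrow = TRUE)
    gg <- (Am - (1 + b2) * labels * Dm) / Dm^2 / L
    g[, ok] <- gg[, ok]
  }
  g * dsig
}
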