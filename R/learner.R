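#' Learner interface
#'
#' Any learner usable with [fola_train()] implements two generics:
#' [predict_proba()], a deterministic map from a feature matrix to an
#' `[n x L]` probability matrix given the current parameters, and
#' [train_one_epoch()], one pass of gradient updates under a supplied
#' [loss_spec()]. The shipped reference learner is a per-label logistic
#' model (linear layer + sigmoid) trained by mini-batch gradient descent,
#' sufficient for small-scale verification; deep models plug in by
#' implementing the same two methods.
#'
#' @param learner A learner object.
#' @param features Numeric feature matrix `[n x d]`.
#' @param ... Passed to methods.
#' @return `predict_proba()`: a probability matrix. `train_one_epoch()`: a
#'   list with the updated `learner`, the `mean_loss` over batches, and the
#'   number of gradient `steps` taken.
#' @name learner-interface
NULL

#' @rdname learner-interface
#' @export
predict_proba <- function(learner, features, ...) UseMethod("predict_proba")

#' @rdname learner-interface
#' @param labels Binary label matrix aligned with `features`.
#' @param spec A [loss_spec()] giving the objective for this epoch.
#' @param lr_fun Function mapping a 0-based global step index to a learning
#'   rate.
#' @param batch_size Mini-batch size.
#' @param step_offset Global step index of the first batch of this epoch.
#' @export
train_one_epoch <- function(learner, features, labels, spec, lr_fun,
                            batch_size = 256L, step_offset = 0L, ...) {
  UseMethod("train_one_epoch")
}

#' Reference per-label logistic learner
#'
#' A linear-sigmoid model: one weight vector and bias per label, trained by
#' mini-batch gradient descent on whatever loss it is given. Parameters are
#' initialized from `N(0, init_sd^2)` using the current RNG state, so a
#' surrounding `set.seed()` makes construction reproducible.
#'
#' @param feature_dim Number of input features.
#' @param n_labels Number of binary outputs.
#' @param init_sd Standard deviation of the random initialization; 0 gives
#'   a deterministic all-zero start.
#' @return An object of class `logistic_learner`.
#' @export
logistic_learner <- function(feature_dim, n_labels = 1L, init_sd = 0.01) {
  if (feature_dim < 1L || n_labels < 1L) abort("Dimensions must be positive.")
  W <- matrix(rnorm(feature_dim * n_labels, sd = init_sd), feature_dim, n_labels)
  b <- rnorm(n_labels, sd = init_sd)
  structure(
    list(W = W, b = b, feature_dim = feature_dim, n_labels = n_labels),
    class = "logistic_learner"
  )
}

#' @export
print.logistic_learner <- function(x, ...) {
  cat(sprintf("<logistic_learner> %d feature(s) -> %d label(s)\n",
              x$feature_dim, x$n_labels))
  invisible(x)
}

#' @rdname learner-interface
#' @export
predict_proba.logistic_learner <- function(learner, features, ...) {
  features <- as_prob_matrix(features, "features")
  z <- features %*% learner$W
  z <- sweep(z, 2L, learner$b, `+`)
  plogis(z)
}

#' @rdname learner-interface
#' @export
train_one_epoch.logistic_learner <- function(learner, features, labels, spec,
                                             lr_fun, batch_size = 256L,
                                             step_offset = 0L, ...) {
  features <- as_prob_matrix(features, "features")
  labels <- as_prob_matrix(labels, "labels")
  check_same_shape(
    matrix(0, nrow(features), ncol(labels)), labels, "features rows", "labels"
  )
  n <- nrow(features)
  perm <- sample.int(n)
  starts <- seq(1L, n, by = batch_size)
  losses <- numeric(length(starts))
  for (i in seq_along(starts)) {
    idx <- perm[starts[i]:min(starts[i] + batch_size - 1L, n)]
    Xb <- features[idx, , drop = FALSE]
    Yb <- labels[idx, , drop = FALSE]
    P <- plogis(sweep(Xb %*% learner$W, 2L, learner$b, `+`))
    losses[i] <- loss_value(spec, P, Yb)
    G <- loss_logit_grad(spec, P, Yb)
    lr <- lr_fun(step_offset + i - 1L)
    learner$W <- learner$W - lr * crossprod(Xb, G)
    learner$b <- learner$b - lr * colSums(G)
  }
  list(learner = learner, mean_loss = mean(losses), steps = length(starts))
}
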