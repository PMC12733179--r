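# Shared fixtures, built in code at test time.

# Small, easy binary task for fast trainer tests.
small_task <- function(n = 2000, prior = 0.2, separation = 3, seed = 42) {
  make_binary_gaussian_task(n, prior, separation, seed = seed)
}

# Random confusion-count triples for property sweeps.
random_counts <- function(n, seed = 1, max_count = 200L) {
  set.seed(seed)
  tibble::tibble(
    tp = sample.int(max_count, n, replace = TRUE),
    fp = sample.int(max_count, n, replace = TRUE) - 1L,
    fn = sample.int(max_count, n, replace = TRUE) - 1L
  )
}

# A learner that always predicts its features as probabilities; with
# features equal to the labels it is a perfect classifier. Exercises the
# learner interface extension point.
perfect_learner <- function() structure(list(), class = "perfect_learner")

predict_proba.perfect_learner <- function(learner, features, ...) features

train_one_epoch.perfect_learner <- function(learner, features, labels, spec,
                                            lr_fun, batch_size = 256L,
                                            step_offset = 0L, ...) {
  probs <- pmin(pmax(features, 1e-7), 1 - 1e-7)
  list(learner = learner, mean_loss = loss_value(spec, probs, labels), steps = 1L)
}

.S3method("predict_proba", "perfect_learner", predict_proba.perfect_learner)
.S3method("train_one_epoch", "perfect_learner", train_one_epoch.perfect_learner)

# Naive O(n^2) threshold sweep used as the independent oracle for the
# sorted-cumulative implementation.
naive_threshold_sweep <- function(scores, labels, beta = 1) {
  thresholds <- c(sort(unique(scores)), max(scores) + 1)
  best <- 0
  best_t <- max(scores) + 1
  for (t in thresholds) {
    pred <- as.integer(scores >= t)
    tp <- sum(pred == 1 & labels == 1)
    fp <- sum(pred == 1 & labels == 0)
    fn <- sum(pred == 0 & labels == 1)
    f <- fbeta_from_counts(tp, fp, fn, beta)
    if (f > best) {
      best <- f
      best_t <- t
    }
  }
  list(best_f = best, best_threshold = best_t)
}
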