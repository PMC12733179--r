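test_that("the cyclical schedule rises from 5% of the peak and returns to it", {
  expect_equal(clr_rate(0, 100, 2), 0.1)
  expect_equal(clr_rate(50, 100, 2), 2)
  expect_equal(clr_rate(100, 100, 2), 0.1)
  expect_equal(clr_rate(25, 100, 1), 0.05 + 0.95 * 0.5)
  expect_error(clr_rate(0, 1, 1), "cycle_len")
})

test_that("prediction sets use the inclusive 0.5 threshold", {
  learner <- perfect_learner()
  sets <- predict_sets(learner, matrix(c(0.6, 0.4, 0.5), 1))
  expect_equal(sets[[1]], c(1L, 3L))
  expect_equal(predict_sets(learner, matrix(c(0.1, 0.2), 1))[[1]], integer(0))
  labels <- matrix(c(1, 0, 0, 1), 2)
  expect_equal(predict_sets(learner, labels),
               apply(labels == 1, 1, which, simplify = FALSE))
})

test_that("the logistic learner reduces its loss and predicts deterministically", {
  task <- small_task()
  tr <- dataset_role(task, "train")
  set.seed(1)
  learner <- logistic_learner(ncol(tr$features), 1)
  spec <- loss_spec("weighted_bce", weights = class_weights(1))
  l0 <- weighted_bce(predict_proba(learner, tr$features), tr$labels,
                     class_weights(1))
  fit <- train_one_epoch(learner, tr$features, tr$labels, spec,
                         lr_fun = function(s) 0.5)
  l1 <- weighted_bce(predict_proba(fit$learner, tr$features), tr$labels,
                     class_weights(1))
  expect_lt(l1, l0)
  expect_identical(predict_proba(fit$learner, tr$features),
                   predict_proba(fit$learner, tr$features))
})

test_that("a single epoch applies the update rule to first-epoch validation metrics", {
  task <- small_task()
  h <- fola_train(task, config = trainer_config(epochs = 1, seed = 3))
  expect_equal(nrow(h$epochs), 1L)
  pooled <- precision_recall(pool_counts(h$epochs$counts[[1]]))
  expect_identical(h$final_weights$wpos,
                   wpos_from_pr_rc(pooled$precision, pooled$recall, 1))
})

test_that("a perfect learner drives the weight to one and keeps it there", {
  labels <- matrix(rbinom(400, 1, 0.3), ncol = 1)
  data <- list(features = labels, labels = labels)
  h <- fola_train(data, data, trainer_config(epochs = 3, initial_wpos = 7),
                  learner = perfect_learner())
  expect_equal(h$final_weights$wpos, 1)
  expect_equal(unlist(h$epochs$wpos), c(7, 1, 1))
  expect_equal(h$epochs$val_fbeta, rep(1, 3))
})

test_that("every weight in the history traces back to the previous epoch's counts", {
  task <- small_task()
  cfg <- trainer_config(epochs = 6, seed = 9)
  h <- fola_train(task, config = cfg)
  for (e in 2:6) {
    prev <- precision_recall(pool_counts(h$epochs$counts[[e - 1]]))
    expect_identical(h$epochs$wpos[[e]],
                     wpos_from_pr_rc(prev$precision, prev$recall, 1))
  }
  # and the final weights come from the last epoch's validation metrics
  last <- precision_recall(pool_counts(h$epochs$counts[[6]]))
  expect_identical(h$final_weights$wpos,
                   wpos_from_pr_rc(last$precision, last$recall, 1))
})

test_that("fixed-weight training never updates the weight", {
  task <- small_task()
  h <- fixed_weight_train(task, wpos = 2.5, config = trainer_config(epochs = 4, seed = 2))
  expect_true(all(vapply(h$epochs$wpos, identical, TRUE, y = 2.5)))
  expect_equal(h$final_weights$wpos, 2.5)
})

test_that("training histories are reproducible from the seed", {
  task <- small_task()
  cfg <- trainer_config(epochs = 3, seed = 17)
  h1 <- fola_train(task, config = cfg)
  h2 <- fola_train(task, config = cfg)
  expect_equal(tidy(h1), tidy(h2), tolerance = 0)
  expect_identical(h1$learner$W, h2$learner$W)
})

test_that("refinement converges for a stationary learner and respects the tolerance", {
  labels <- matrix(rbinom(300, 1, 0.4), ncol = 1)
  data <- list(features = labels, labels = labels)
  cfg <- trainer_config(epochs = 2, refine_passes = 4, refine_tol = 0.01,
                        initial_wpos = 3)
  out <- refine_wpos(data, data, cfg, learner_factory = perfect_learner)
  expect_true(out$converged)
  expect_length(out$histories, 2L)   # one extra pass confirms stationarity
  expect_equal(out$weights$wpos, 1)

  # an infinite tolerance declares convergence after the first pass
  cfg$refine_tol <- Inf
  out1 <- refine_wpos(data, data, cfg, learner_factory = perfect_learner)
  expect_length(out1$histories, 1L)
  expect_true(out1$converged)
})

test_that("tidy, glance and autoplot summarize a history", {
  task <- small_task()
  h <- fola_train(task, config = trainer_config(epochs = 3, seed = 5))
  td <- tidy(h)
  expect_equal(nrow(td), 3L)
  expect_named(td, c("epoch", "wpos", "val_precision", "val_recall",
                     "val_fbeta", "mean_loss"))
  g <- glance(h)
  expect_equal(g$val_fbeta, td$val_fbeta[3])
  expect_s3_class(autoplot(h), "ggplot")
})

test_that("macro training keeps one weight per label and applies bounding", {
  priors <- c(0.3, 0.1, 0.02)
  spec <- task_spec(3000, 3, feature_dim = 4, label_priors = priors,
                    class_separation = 2, co_occurrence_rank = 2, seed = 11)
  task <- make_multilabel_task(spec)
  cfg <- trainer_config(mode = "macro", epochs = 4, bounding_factor = 2, seed = 1)
  h <- fola_train(task, config = cfg)
  expect_length(h$final_weights$wpos, 3L)
  expect_lte(max(h$final_weights$wpos),
             2 * median(h$final_weights$wpos) + 1e-12)
})
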