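test_that("binary Gaussian tasks are reproducible and realize their prior", {
  t1 <- make_binary_gaussian_task(50000, 0.02, 2, seed = 1)
  t2 <- make_binary_gaussian_task(50000, 0.02, 2, seed = 1)
  expect_identical(t1$features, t2$features)
  expect_identical(t1$labels, t2$labels)
  expect_identical(t1$split, t2$split)

  frac <- mean(t1$labels)
  expect_lt(abs(frac - 0.02), 3 * sqrt(0.02 * 0.98 / 50000))
  expect_error(make_binary_gaussian_task(100, 0.7, 1), "prior")
})

test_that("the analytic posterior of the Gaussian task is calibrated", {
  task <- make_binary_gaussian_task(100000, 0.05, 2, seed = 4)
  post <- as.vector(task$true_posterior)
  y <- as.vector(task$labels)
  bins <- cut(post, breaks = quantile(post, seq(0, 1, 0.1)),
              include.lowest = TRUE)
  for (b in levels(bins)) {
    idx <- bins == b
    n <- sum(idx)
    p_hat <- mean(y[idx])
    p_bar <- mean(post[idx])
    expect_lt(abs(p_hat - p_bar),
              4 * sqrt(max(p_bar * (1 - p_bar), 1e-6) / n) + 1e-3)
  }
})

test_that("extreme separations reach the expected best achievable F1", {
  # near-separable: post hoc optimum approaches 1
  sep <- make_binary_gaussian_task(20000, 0.05, 8, seed = 2)
  bf <- brute_force_threshold_f1(as.vector(sep$true_posterior),
                                 as.vector(sep$labels))
  expect_gt(bf$best_f, 0.99)

  # uninformative features at prior 0.5: best rule is all-positive, F = 2/3
  flat <- make_binary_gaussian_task(20000, 0.5, 0.01, seed = 3)
  bf2 <- brute_force_threshold_f1(as.vector(flat$true_posterior),
                                  as.vector(flat$labels))
  expect_equal(bf2$best_f, 2 / 3, tolerance = 0.01)
})

test_that("splits are exact, disjoint and seed-deterministic", {
  tags <- split_dataset(100, c(0.7, 0.15, 0.15), seed = 6)
  expect_equal(as.vector(table(tags)), c(70L, 15L, 15L))
  expect_false(anyNA(tags))
  expect_identical(tags, split_dataset(100, c(0.7, 0.15, 0.15), seed = 6))
  expect_false(identical(tags, split_dataset(100, c(0.7, 0.15, 0.15), seed = 7)))
  expect_error(split_dataset(5, c(0.7, 0.15, 0.15)), "too small")
  expect_error(split_dataset(100, c(0.5, 0.2, 0.2)), "summing")
})

test_that("power-law priors honor the imbalance ratio and mass concentration", {
  p <- power_law_priors(50, max_ratio = 100)
  expect_equal(min(p), 1 / 101, tolerance = 1e-12)
  expect_true(all(diff(p) < 0))
  p2 <- power_law_priors(100, max_ratio = 185)
  expect_equal(sum(p2[1:16]) / sum(p2), 0.5, tolerance = 1e-6)
})

test_that("rank-zero tasks have independent labels and flat posteriors", {
  spec <- task_spec(100000, 4, feature_dim = 3,
                    label_priors = c(0.3, 0.2, 0.1, 0.05),
                    co_occurrence_rank = 0, seed = 5)
  task <- make_multilabel_task(spec)
  cors <- cor(task$labels)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.02)
  expect_equal(task$true_posterior[1, ], c(0.3, 0.2, 0.1, 0.05),
               ignore_attr = TRUE)
  realized <- colMeans(task$labels)
  expect_true(all(abs(realized - spec$label_priors) <
                    4 * sqrt(spec$label_priors / 100000)))
})

test_that("shared latent factors induce co-occurrence and inferable hidden labels", {
  # factor 1 is visible in the features; factor 2 is hidden (zero map).
  # labels 1 and 2 share factor 1; label 3 depends only on factor 2.
  A <- rbind(c(2, 0), c(2, 0), c(0, 2))
  M <- cbind(c(1, 1), c(0, 0))
  spec <- task_spec(40000, 3, feature_dim = 2,
                    label_priors = c(0.2, 0.1, 0.1),
                    co_occurrence_rank = 2, noise_sd = 0.5,
                    loadings = A, feature_map = M, seed = 12)
  task <- make_multilabel_task(spec)

  expect_gt(cor(task$labels[, 1], task$labels[, 2]), 0.1)

  # the hidden co-occurring label is predictable beyond its prior ...
  post2 <- task$true_posterior[, 2]
  y2 <- task$labels[, 2]
  prior_only_f <- fbeta_from_counts(sum(y2), sum(1 - y2), 0)  # all-positive rule
  bf2 <- brute_force_threshold_f1(post2, y2)
  expect_gt(bf2$best_f, prior_only_f + 0.05)

  # ... while the label tied to the invisible factor is not
  expect_lt(stats::sd(task$true_posterior[, 3]), 1e-8)
})

test_that("multi-label posteriors are calibrated under partial observability", {
  spec <- task_spec(50000, 4, feature_dim = 4, label_priors = c(0.3, 0.15, 0.08, 0.04),
                    class_separation = 2, co_occurrence_rank = 2,
                    noise_sd = 0.8, seed = 13)
  task <- make_multilabel_task(spec)
  for (l in 1:4) {
    post <- task$true_posterior[, l]
    y <- task$labels[, l]
    bins <- cut(post, breaks = unique(quantile(post, seq(0, 1, 0.2))),
                include.lowest = TRUE)
    for (b in levels(bins)) {
      idx <- bins == b
      p_bar <- mean(post[idx])
      expect_lt(abs(mean(y[idx]) - p_bar),
                4 * sqrt(max(p_bar * (1 - p_bar), 1e-6) / sum(idx)) + 2e-3)
    }
  }
  # realized label frequencies follow the configured priors
  expect_true(all(abs(colMeans(task$labels) - spec$label_priors) <
                    4 * sqrt(spec$label_priors / 50000) + 1e-3))
})

test_that("tasks round-trip through their plain-text representation", {
  spec <- task_spec(200, 3, feature_dim = 4, label_priors = c(0.3, 0.2, 0.1),
                    co_occurrence_rank = 2, seed = 9)
  task <- make_multilabel_task(spec)
  dir <- withr::local_tempdir()
  write_task(task, dir)
  back <- read_task(dir)
  expect_equal(back$features, task$features, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$labels, task$labels, tolerance = 0, ignore_attr = TRUE)
  expect_identical(as.character(back$split), as.character(task$split))
  expect_equal(back$true_posterior, task$true_posterior, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$spec$label_priors, task$spec$label_priors)
})
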