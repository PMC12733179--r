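test_that("confusion counts are tallied per label with an inclusive threshold", {
  probs <- matrix(c(0.9, 0.4, 0.2, 0.7), nrow = 2)
  labels <- matrix(c(1, 1, 0, 1), nrow = 2)
  counts <- accumulate_counts(probs, labels)
  expect_equal(counts$tp, c(1L, 1L))
  expect_equal(counts$fp, c(0L, 0L))
  expect_equal(counts$fn, c(1L, 0L))
  expect_equal(counts$n_pos, c(2L, 1L))

  # all-zero probabilities: every positive becomes a false negative
  zero <- accumulate_counts(matrix(0, 4, 1), matrix(c(1, 1, 1, 0), 4, 1))
  expect_equal(c(zero$tp, zero$fp, zero$fn), c(0L, 0L, 3L))

  # a probability of exactly 0.5 counts as a positive prediction
  half <- accumulate_counts(matrix(0.5), matrix(1))
  expect_equal(half$tp, 1L)

  expect_error(accumulate_counts(matrix(0.5, 2, 2), matrix(1)), "shape")
  expect_error(accumulate_counts(matrix(0.5), matrix(2)), "0 and 1")
  expect_error(accumulate_counts(matrix(0.5), matrix(1), threshold = 1), "0, 1")
})

test_that("precision and recall handle zero denominators as undefined", {
  counts <- tibble::tibble(tp = c(2L, 0L, 50L), fp = c(1L, 0L, 50L),
                           fn = c(0L, 5L, 50L))
  pr <- precision_recall(counts)
  expect_equal(pr$precision, c(2 / 3, NA, 0.5))
  expect_equal(pr$recall, c(1, 0, 0.5))
})

test_that("the count form of F-beta matches hand-computed values", {
  expect_equal(fbeta_from_counts(2, 1, 0), 0.8)
  expect_equal(fbeta_from_counts(1, 0, 0, beta = 0.5), 1)
  expect_equal(fbeta_from_counts(1, 0, 0, beta = 7), 1)
  expect_equal(fbeta_from_counts(1, 0, 1, beta = 2), 5 / 9)
  expect_equal(fbeta_from_counts(0, 10, 5), 0)  # zero-TP convention
  expect_error(fbeta_from_counts(1, 0, 0, beta = 0), "positive")
})

test_that("F-beta from counts equals the harmonic-mean form and stays in range", {
  counts <- random_counts(1000, seed = 11)
  counts$tp <- counts$tp + 1L  # ensure tp > 0 so Pr, Rc are defined
  pr <- counts$tp / (counts$tp + counts$fp)
  rc <- counts$tp / (counts$tp + counts$fn)
  f_harmonic <- 2 * pr * rc / (pr + rc)
  f_counts <- fbeta_from_counts(counts$tp, counts$fp, counts$fn, beta = 1)
  expect_equal(f_counts, f_harmonic, tolerance = 1e-12)
  expect_true(all(f_counts >= 0 & f_counts <= 1))

  # non-increasing in fp and fn at fixed tp
  worse_fp <- fbeta_from_counts(counts$tp, counts$fp + 5L, counts$fn)
  worse_fn <- fbeta_from_counts(counts$tp, counts$fp, counts$fn + 5L)
  expect_true(all(worse_fp <= f_counts))
  expect_true(all(worse_fn <= f_counts))
})

test_that("micro averaging pools counts and macro averaging means per-label scores", {
  counts <- tibble::tibble(tp = c(1L, 1L), fp = c(0L, 0L), fn = c(1L, 0L),
                           tn = c(5L, 5L))
  expect_equal(micro_fbeta(counts), 0.8)  # pooled (2, 0, 1)

  pooled <- pool_counts(counts)
  expect_equal(pooled$tp, sum(counts$tp))
  expect_equal(pooled$tn, sum(counts$tn))

  report <- macro_fbeta(tibble::tibble(tp = c(1L, 1L), fp = c(1L, 0L),
                                       fn = c(0L, 0L)))
  expect_equal(report$per_label$fbeta, c(2 / 3, 1))
  expect_equal(report$macro_f, mean(c(2 / 3, 1)), tolerance = 1e-12)

  # single label: micro = macro = plain count form
  one <- tibble::tibble(tp = 7L, fp = 3L, fn = 2L)
  expect_equal(micro_fbeta(one), macro_fbeta(one)$macro_f)
  expect_equal(micro_fbeta(one), fbeta_from_counts(7, 3, 2))

  # a label that is never predicted contributes zero to the macro mean
  rep0 <- macro_fbeta(tibble::tibble(tp = c(5L, 0L), fp = c(0L, 0L),
                                     fn = c(0L, 4L)))
  expect_equal(rep0$per_label$fbeta, c(1, 0))
  expect_equal(rep0$macro_f, 0.5)
  # excluding labels without positives drops them from the mean
  rep1 <- macro_fbeta(tibble::tibble(tp = c(5L, 0L), fp = c(0L, 2L),
                                     fn = c(0L, 0L)), include_empty = FALSE)
  expect_equal(rep1$macro_f, 1)
})

test_that("micro pooling conserves totals on random per-label counts", {
  set.seed(3)
  probs <- matrix(runif(200 * 6), 200, 6)
  labels <- matrix(rbinom(200 * 6, 1, 0.3), 200, 6)
  counts <- accumulate_counts(probs, labels)
  pooled <- pool_counts(counts)
  expect_identical(pooled$tp + pooled$fp + pooled$fn + pooled$tn, 200L * 6L)
  expect_identical(pooled$n_pos, sum(labels == 1L))
})

test_that("instance IoU and cardinality statistics follow the set definitions", {
  expect_equal(instance_iou(list(c("a", "b", "c")), list(c("b", "c", "d"))), 0.5)
  expect_equal(instance_iou(list(1:3), list(1:3)), 1)
  expect_equal(instance_iou(list(1:2), list(3:4)), 0)
  expect_equal(instance_iou(list(integer(0)), list(integer(0))), 1)

  cs <- cardinality_stats(list(1:3, 1:5), list(1:4, 1:3))
  expect_equal(cs$mean_true, 4)
  expect_equal(cs$mean_pred, 3.5)
  expect_equal(cs$mae, 1.5)
  expect_equal(cardinality_stats(list(1:3), list(1:3))$mae, 0)
  expect_error(cardinality_stats(list(), list()), "at least one")
})

test_that("metrics reports round-trip through CSV and JSON", {
  counts <- tibble::tibble(label = c("a", "b"), tp = c(3L, 1L), fp = c(1L, 0L),
                           fn = c(0L, 2L), tn = c(6L, 7L))
  report <- macro_fbeta(counts)
  csv <- withr::local_tempfile(fileext = ".csv")
  json <- withr::local_tempfile(fileext = ".json")
  write_metrics_report(report, csv, json, iou = 0.4,
                       cardinality = cardinality_stats(list(1:2), list(1:3)))
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(back$fbeta, report$per_label$fbeta)
  summ <- jsonlite::read_json(json)
  expect_equal(summ$macro_f, report$macro_f)
  expect_equal(summ$iou, 0.4)
})
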