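test_that("confusion matrix counts direct examples", {
  cm <- confusion(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
  expect_equal(unname(unclass(cm)), rbind(c(1L, 1L), c(0L, 1L)))
  perfect <- confusion(rep(c("A", "B"), 5), rep(c("A", "B"), 5), c("A", "B"))
  expect_true(all(perfect[row(perfect) != col(perfect)] == 0))
  empty <- confusion(character(0), character(0), c("A", "B"))
  expect_true(all(empty == 0))
  expect_error(confusion("A", "C", c("A", "B")), "outside")
})

test_that("metrics agree with an independent brute-force implementation", {
  set.seed(14)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    cm <- matrix(rpois(k * k, 20), k, dimnames = list(truth = LETTERS[1:k],
                                                      predicted = LETTERS[1:k]))
    diag(cm) <- diag(cm) + rpois(k, 100)
    m <- per_class_metrics(cm)
    raw <- attr(m, "raw")
    bf <- brute_metrics(cm)
    for (j in seq_len(k)) {
      expect_equal(raw$sensitivity[j], bf[[j]]["sen"], ignore_attr = TRUE)
      expect_equal(raw$precision[j], bf[[j]]["pre"], ignore_attr = TRUE)
      expect_equal(raw$specificity[j], bf[[j]]["spec"], ignore_attr = TRUE)
      expect_equal(raw$accuracy[j], bf[[j]]["acc"], ignore_attr = TRUE)
      expect_equal(raw$f1[j], bf[[j]]["f1"], ignore_attr = TRUE)
      # F1 is the harmonic mean of precision and sensitivity
      expect_equal(raw$f1[j],
                   2 / (1 / raw$precision[j] + 1 / raw$sensitivity[j]),
                   ignore_attr = TRUE)
    }
    expect_equal(raw$overall_accuracy, sum(diag(cm)) / sum(cm))
  }
})

test_that("published 5-class confusion matrix reproduces the reported metrics", {
  m <- per_class_metrics(published_confusion("5class"))
  expect_equal(attr(m, "overall_accuracy"), 99.08)
  expected <- data.frame(
    class = c("N", "AFIB", "SVTA", "B", "T"),
    sensitivity = c(98.72, 99.56, 100, 99.76, 96.83),
    precision = c(99.52, 98.98, 100, 98.92, 92.11),
    f1 = c(99.12, 99.27, 100, 99.33, 94.41),
    accuracy = c(99.11, 99.39, 100, 99.94, 99.73)
  )
  for (col in c("sensitivity", "precision", "f1", "accuracy")) {
    expect_equal(m[[col]], expected[[col]], tolerance = 0.005)
  }
})

test_that("published 6-class confusion matrix reproduces the reported metrics", {
  m <- per_class_metrics(published_confusion("6class"))
  expect_equal(attr(m, "overall_accuracy"), 99.24)
  expected <- data.frame(
    class = c("N", "AFIB", "B", "P", "AFL", "SBR"),
    sensitivity = c(99.44, 99.18, 99.88, 100, 90.84, 100),
    precision = c(99.76, 98.72, 99.04, 100, 93.06, 100),
    f1 = c(99.60, 98.95, 99.46, 100, 91.94, 100),
    accuracy = c(99.67, 99.27, 99.96, 100, 99.58, 100)
  )
  expect_equal(m$class, expected$class)
  for (col in c("sensitivity", "precision", "f1", "accuracy")) {
    expect_equal(m[[col]], expected[[col]], tolerance = 0.005)
  }
})

test_that("degenerate confusion matrices follow the stated conventions", {
  ident <- matrix(c(5L, 0L, 0L, 5L), 2, dimnames = list(c("A", "B"),
                                                        c("A", "B")))
  m <- per_class_metrics(ident)
  expect_true(all(m$sensitivity == 100 & m$precision == 100 & m$f1 == 100))
  # class never predicted -> F1 = 0 with a warning, not a crash
  cm <- matrix(c(5L, 3L, 0L, 0L), 2, dimnames = list(c("A", "B"),
                                                     c("A", "B")))
  expect_warning(m2 <- per_class_metrics(cm), "never predicted")
  expect_equal(m2$f1[2], 0)
  # empty truth row -> sensitivity missing, not 0
  cm3 <- matrix(c(5L, 0L, 1L, 0L), 2, dimnames = list(c("A", "B"),
                                                      c("A", "B")))
  m3 <- per_class_metrics(cm3)
  expect_true(is.na(m3$sensitivity[2]))
})

test_that("rounding is half-up to two decimals", {
  expect_equal(bsmecg:::round_half_up(99.125), 99.13)
  expect_equal(bsmecg:::round_half_up(99.124999), 99.12)
  expect_equal(bsmecg:::round_half_up(-99.125), -99.13)
})

test_that("noise experiment is keyed by level and matches a manual clean run", {
  recs <- generate_class_records(c("N", "B"), duration_s = 19, seed = 61)
  cfg <- training_config(epochs = 2, folds = 2)
  res <- noise_experiment(recs, c("none", -6), cfg, seed = 8)
  expect_setequal(names(res), c("none", "-6dB"))
  for (k in names(res)) {
    expect_s3_class(res[[k]]$metrics, "data.frame")
    expect_true(res[[k]]$macro_f1 >= 0 && res[[k]]$macro_f1 <= 1)
  }
  # the "none" level reproduces a manual clean pipeline run with same seeds
  den <- lapply(recs, denoise_record)
  bs <- make_beat_training_set(den)
  bm <- train_beat_classifier(bs$scalograms, bs$labels, cfg, seed = 8)
  ds <- make_bsm_dataset(den, bm)
  cv <- cross_validate(ds$images, ds$labels, cfg, seed = 8)
  expect_identical(unclass(res$none$confusion), unclass(cv$confusion))
})
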