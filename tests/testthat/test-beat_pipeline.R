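test_that("chunk extraction spans 1.2 s either side with zero padding", {
  sig <- seq_len(10000) * 1.0
  ch <- extract_chunk(sig, 5000, 360)
  expect_length(ch$signal, 864)
  # slice [4568, 5432) in 0-based indexing -> values 4569..5432
  expect_equal(ch$signal, as.numeric(4569:5432))
  left <- extract_chunk(sig, 100, 360)
  expect_length(left$signal, 864)
  expect_true(all(left$signal[1:(432 - 100)] == 0))
  expect_equal(left$signal[433], sig[101])             # centre sample = R peak
  right <- extract_chunk(sig, 9999, 360)
  expect_true(all(right$signal[(432 + 2):864] == 0))
  expect_error(extract_chunk(sig, 10000, 360), "outside")
})

test_that("scalograms localize pure tones and vanish on zero input", {
  cfg <- bsm_config()$cwt
  z <- cwt_scalogram(extract_chunk(numeric(1000), 500, 360))
  expect_equal(dim(z$values), c(cfg$n_scales, 864))
  expect_true(all(z$values == 0))
  t <- (0:863) / 360
  step <- log(cfg$fmax_hz / cfg$fmin_hz) / (cfg$n_scales - 1)
  for (f in c(2, 5, 10, 25)) {
    sc <- cwt_scalogram(sin(2 * pi * f * t), cfg, fs = 360)
    peak <- sc$freqs_hz[which.max(rowMeans(sc$values))]
    expect_lt(abs(log(peak / f)), step + 1e-9)         # within one grid cell
  }
})

test_that("oracle scorer emits the one-hot vector of the true label", {
  m <- oracle_beat_model()
  ch <- extract_chunk(rnorm(2000), 1000, 360, true_label = "V")
  s <- predict_beat_scores(m, ch)
  expect_equal(sum(s), 1)
  expect_equal(names(which(s == 1)), "V")
  expect_equal(sum(s > 0), 1)
  expect_error(predict_beat_scores(m, extract_chunk(rnorm(2000), 1000, 360)),
               "true_label")
})

test_that("beat classifier separates template classes and is seeded", {
  set.seed(99)
  tr <- make_template_scalograms(c("N", "V", "/"), 150, seed = 11)
  te <- make_template_scalograms(c("N", "V", "/"), 50, seed = 22)
  cfg <- training_config(epochs = 10)
  model <- train_beat_classifier(tr$scalograms, tr$labels, cfg, seed = 3)
  score_one <- function(m, sc) {
    ch <- structure(list(signal = NULL), class = "beat_chunk")
    # scalograms are precomputed; go through the cnn directly
    img <- bsmecg:::scalogram_image(sc)
    m$vocab[which.max(bsmecg:::cnn_predict(m$cnn, img))]
  }
  pred <- vapply(te$scalograms, function(s) score_one(model, s), "")
  expect_gte(mean(pred == te$labels), 0.95)
  # score-vector contract on raw chunks
  sig <- rnorm(2000)
  sv <- predict_beat_scores(model, extract_chunk(sig, 900, 360))
  expect_length(sv, 15)
  expect_true(all(sv >= 0))
  expect_equal(sum(sv), 1, tolerance = 1e-6)
  expect_identical(sv, predict_beat_scores(model, extract_chunk(sig, 900, 360)))
  # same seed, same data -> identical model predictions
  model2 <- train_beat_classifier(tr$scalograms, tr$labels, cfg, seed = 3)
  expect_identical(predict_beat_scores(model2, extract_chunk(sig, 900, 360)), sv)
})

test_that("label-permuted training collapses to chance accuracy", {
  tr <- make_template_scalograms(c("N", "V", "/"), 60, seed = 31)
  te <- make_template_scalograms(c("N", "V", "/"), 50, seed = 32)
  set.seed(5)
  perm_labels <- sample(tr$labels)
  model <- train_beat_classifier(tr$scalograms, perm_labels,
                                 training_config(epochs = 6), seed = 3)
  pred <- vapply(te$scalograms, function(s) {
    img <- bsmecg:::scalogram_image(s)
    model$vocab[which.max(bsmecg:::cnn_predict(model$cnn, img))]
  }, "")
  acc <- mean(pred == te$labels)
  se <- sqrt(1 / 3 * 2 / 3 / length(te$labels))
  expect_lt(abs(acc - 1 / 3), 3 * se)
})

test_that("single-class beat training is rejected", {
  tr <- make_template_scalograms("N", 5, seed = 1)
  expect_error(train_beat_classifier(tr$scalograms, tr$labels),
               "two classes")
})
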