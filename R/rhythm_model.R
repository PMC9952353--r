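#' Imbalance-aware sampling weights
#'
#' Per-window weight `1 / (count of its class)`, so a weighted-with-
#' replacement mini-batch sampler draws each class with equal expected
#' frequency regardless of the class imbalance of the dataset.
#'
#' @param labels rhythm symbol per window
#' @return Positive numeric vector, one weight per window; equal within a
#'   class.
#' @export
make_sampler_weights <- function(labels) {
  stopifnot(length(labels) > 0)
  counts <- table(labels)
  as.numeric(1 / counts[labels])
}

rhythm_classes <- function(labels, vocab) {
  present <- vocab[vocab %in% unique(labels)]
  extra <- setdiff(unique(labels), vocab)
  if (length(extra)) stop("labels outside rhythm vocabulary: ", paste(extra, collapse = " "))
  present
}

#' Train the rhythm classifier on BSM images
#'
#' With the default `small-cnn` backbone a compact convolutional network is
#' trained from scratch on the resized BSM images, using weighted random
#' sampling (see [make_sampler_weights()]) to counter class imbalance. The
#' `vgg16-transfer` backbone mirrors the transfer-learning contract (all
#' layers fine-tuned from pretrained initial weights) but requires
#' externally supplied weights, which this package does not bundle.
#'
#' @param images list of resized `bsm_matrix` images (equal shapes)
#' @param labels rhythm symbol per image (>= 2 distinct)
#' @param config [training_config()]
#' @param seed integer seed (defaults to `config$seed`)
#' @param vocab rhythm vocabulary (fixes class order)
#' @return A `rhythm_model` with elements `cnn`, `classes`, `config`.
#' @export
train_rhythm_classifier <- function(images, labels, config = training_config(),
                                    seed = config$seed,
                                    vocab = rhythm_vocabulary()) {
  stopifnot(length(images) == length(labels))
  if (config$backbone == "vgg16-transfer") {
    stop("backbone 'vgg16-transfer' needs pretrained VGG16 weights, which ",
         "are not bundled; supply them externally or use 'small-cnn'")
  }
  classes <- rhythm_classes(labels, vocab)
  if (length(classes) < 2) stop("rhythm classifier needs at least two classes")
  imgs <- lapply(images, unclass)
  shp <- dim(imgs[[1]])
  if (!all(vapply(imgs, function(i) all(dim(i) == shp), TRUE))) {
    stop("BSM images have inconsistent shapes")
  }
  cnn <- cnn_init(shp, n_classes = length(classes),
                  n_filters = config$n_filters,
                  kernel = c(config$kernel_t, 0L), stride = c(2L, 1L),
                  pool = c(2L, max(1L, shp[2] %/% 15L)), mp = 2L,
                  hidden = config$hidden, seed = seed)
  y <- match(labels, classes)
  w <- make_sampler_weights(labels)
  cnn <- cnn_train(cnn, imgs, y, epochs = config$epochs,
                   learning_rate = config$learning_rate,
                   batch_size = config$batch_size, seed = seed + 1L,
                   sample_weights = w)
  structure(list(cnn = cnn, classes = classes, config = config),
            class = "rhythm_model")
}

#' Classify one BSM image
#'
#' @param model a trained `rhythm_model`
#' @param bsm a resized `bsm_matrix` (or plain matrix of the trained shape)
#' @return list with `label` (argmax rhythm symbol) and `scores` (named
#'   nonnegative vector summing to 1 over the model's classes).
#' @export
predict_rhythm <- function(model, bsm) {
  stopifnot(inherits(model, "rhythm_model"))
  scores <- drop(cnn_predict(model$cnn, unclass(bsm)))
  names(scores) <- model$classes
  list(label = model$classes[which.max(scores)], scores = scores)
}

#' Stratified k-fold cross-validation of the rhythm classifier
#'
#' Windows are partitioned into `config$folds` stratified folds (per-fold
#' class proportions within one window of the global proportions); each
#' window is predicted exactly once, by the model not trained on its fold,
#' and predictions are pooled into one confusion matrix.
#'
#' @inheritParams train_rhythm_classifier
#' @return list with `predictions` (data.frame `index`, `fold`, `truth`,
#'   `predicted`), `confusion` (pooled, class order = vocabulary order) and
#'   `classes`.
#' @export
cross_validate <- function(images, labels, config = training_config(),
                           seed = config$seed, vocab = rhythm_vocabulary()) {
  stopifnot(length(images) == length(labels))
  classes <- rhythm_classes(labels, vocab)
  k <- config$folds
  counts <- table(factor(labels, classes))
  small <- names(counts)[counts < k]
  if (length(small)) {
    stop("class ", paste(small, collapse = ", "), " has fewer members than ",
         k, " folds")
  }
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in classes) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  preds <- character(length(labels))
  for (f in seq_len(k)) {
    tr <- fold != f
    model <- train_rhythm_classifier(images[tr], labels[tr], config,
                                     seed = seed + f, vocab = vocab)
    te <- which(!tr)
    scores <- cnn_predict(model$cnn, lapply(images[te], unclass))
    preds[te] <- model$classes[max.col(scores, ties.method = "first")]
  }
  list(predictions = data.frame(index = seq_along(labels), fold = fold,
                                truth = labels, predicted = preds),
       confusion = confusion(labels, preds, classes),
       classes = classes)
}
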