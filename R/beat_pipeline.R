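# Per-beat stage: 2.4-s chunks centred on annotated R peaks, analytic-Morlet
# CWT scalograms, and a classifier that emits one normalized score vector
# over the 15 beat symbols per chunk. An oracle scorer (one-hot of the true
# label) lets downstream BSM logic be exercised independently of training.

#' Extract a beat chunk around an R peak
#'
#' The chunk spans from 1.2 s before to 1.2 s after the R peak
#' (`[r - round(1.2 fs), r + round(1.2 fs))`, 864 samples at 360 Hz); parts
#' falling outside the record are zero-padded.
#'
#' @param signal numeric record signal (typically denoised)
#' @param r_position 0-based sample index of the R peak
#' @param fs sampling rate in Hz
#' @param chunk_s chunk duration in seconds (default 2.4)
#' @param true_label optional beat symbol carried along for training
#' @return A `beat_chunk`: list with `signal` (length `round(chunk_s * fs)`),
#'   `r_position`, `fs`, `true_label`.
#' @export
extract_chunk <- function(signal, r_position, fs, chunk_s = 2.4,
                          true_label = NULL) {
  if (r_position < 0 || r_position >= length(signal)) {
    stop("r_position outside record")
  }
  half <- round(chunk_s / 2 * fs)
  idx <- (r_position - half):(r_position + half - 1)   # 0-based
  out <- numeric(length(idx))
  ok <- idx >= 0 & idx < length(signal)
  out[ok] <- signal[idx[ok] + 1]
  structure(list(signal = out, r_position = r_position, fs = fs,
                 true_label = true_label), class = "beat_chunk")
}

#' Continuous wavelet transform scalogram of a beat chunk
#'
#' FFT-based analytic Morlet CWT over a logarithmic frequency grid. The
#' response at each scale peaks when the signal frequency matches the
#' scale's centre frequency `omega0 / (2 pi s)`, so a pure tone lights up
#' the row nearest its frequency.
#'
#' @param chunk a `beat_chunk` (or plain numeric signal with `fs` attribute
#'   given via `fs`)
#' @param config list with `n_scales`, `fmin_hz`, `fmax_hz`, `omega0` (see
#'   [bsm_config()])
#' @param fs sampling rate if `chunk` is a bare numeric vector
#' @return A `scalogram`: list with `values` (n_scales x n nonnegative
#'   magnitudes, row 1 = lowest frequency) and `freqs_hz`.
#' @export
cwt_scalogram <- function(chunk, config = bsm_config()$cwt, fs = NULL) {
  if (inherits(chunk, "beat_chunk")) {
    x <- chunk$signal; fs <- chunk$fs
  } else {
    x <- as.numeric(chunk)
    if (is.null(fs)) stop("fs required for a bare signal")
  }
  if (any(!is.finite(x))) stop("chunk contains non-finite samples")
  n <- length(x)
  freqs <- exp(seq(log(config$fmin_hz), log(config$fmax_hz),
                   length.out = config$n_scales))
  scales <- config$omega0 * fs / (2 * pi * freqs)      # in samples
  w_k <- 2 * pi * (seq_len(n) - 1) / n                 # angular freq / sample
  X <- stats::fft(x)
  psi <- outer(w_k, scales, function(w, s) {
    ifelse(w > 0 & w < pi, exp(-0.5 * (s * w - config$omega0)^2), 0)
  })
  W <- stats::mvfft(psi * X, inverse = TRUE) / n       # n x n_scales
  structure(list(values = t(Mod(W)), freqs_hz = freqs), class = "scalogram")
}

# min-max scale a scalogram's magnitudes to [0, 1] (flat image -> zeros)
scalogram_image <- function(sc) {
  v <- sc$values
  rng <- range(v)
  if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else v * 0
}

#' Train the beat classifier on labelled scalograms
#'
#' Fits the compact convolutional network to min-max-scaled scalogram images.
#' The output layer always spans the full beat vocabulary (15 classes), so
#' every prediction is a complete beat score vector even when the training
#' set contains only a subset of symbols.
#'
#' @param scalograms list of `scalogram` objects (or plain matrices of equal
#'   shape)
#' @param labels beat symbol per scalogram (at least two distinct)
#' @param config [training_config()]
#' @param seed integer seed (defaults to `config$seed`)
#' @param vocab beat vocabulary defining score-vector order
#' @param cwt_config the CWT settings the scalograms were built with; stored
#'   so [predict_beat_scores()] can process raw chunks identically
#' @return A `beat_model` (class `beat_model_cnn`).
#' @export
train_beat_classifier <- function(scalograms, labels, config = training_config(),
                                  seed = config$seed, vocab = beat_vocabulary(),
                                  cwt_config = bsm_config()$cwt) {
  stopifnot(length(scalograms) == length(labels))
  if (length(unique(labels)) < 2) {
    stop("beat classifier needs at least two classes in the training set")
  }
  bad <- setdiff(unique(labels), vocab)
  if (length(bad)) stop("labels outside beat vocabulary: ", paste(bad, collapse = " "))
  imgs <- lapply(scalograms, function(s)
    if (inherits(s, "scalogram")) scalogram_image(s) else s)
  shp <- dim(imgs[[1]])
  if (!all(vapply(imgs, function(i) all(dim(i) == shp), TRUE))) {
    stop("scalograms have inconsistent shapes")
  }
  cnn <- cnn_init(shp, n_classes = length(vocab),
                  n_filters = config$n_filters, kernel = c(9L, 0L),
                  stride = c(1L, 4L), pool = c(2L, 8L), mp = 2L,
                  hidden = config$hidden, seed = seed)
  y <- match(labels, vocab)
  cnn <- cnn_train(cnn, imgs, y, epochs = config$epochs,
                   learning_rate = config$learning_rate,
                   batch_size = config$batch_size, seed = seed + 1L)
  structure(list(cnn = cnn, vocab = vocab, cwt_config = cwt_config),
            class = c("beat_model_cnn", "beat_model"))
}

#' Oracle beat scorer
#'
#' A stand-in for a trained beat classifier that emits the one-hot score
#' vector of each chunk's true label. It bypasses learning entirely, so BSM
#' construction and rhythm classification can be tested and run
#' independently of beat-classifier quality.
#'
#' @param vocab beat vocabulary defining score-vector order
#' @return A `beat_model` (class `beat_model_oracle`).
#' @export
oracle_beat_model <- function(vocab = beat_vocabulary()) {
  structure(list(vocab = vocab), class = c("beat_model_oracle", "beat_model"))
}

#' Score one beat chunk
#'
#' @param model a `beat_model`
#' @param chunk a `beat_chunk`
#' @return Named numeric vector over the beat vocabulary: entries are
#'   nonnegative and sum to 1; the argmax is the predicted beat class.
#' @export
predict_beat_scores <- function(model, chunk) UseMethod("predict_beat_scores")

#' @export
predict_beat_scores.beat_model_oracle <- function(model, chunk) {
  if (is.null(chunk$true_label)) stop("oracle scorer needs chunks carrying true_label")
  i <- match(chunk$true_label, model$vocab)
  if (is.na(i)) stop("unknown beat label: ", chunk$true_label)
  stats::setNames(as.numeric(seq_along(model$vocab) == i), model$vocab)
}

#' @export
predict_beat_scores.beat_model_cnn <- function(model, chunk) {
  img <- scalogram_image(cwt_scalogram(chunk, model$cwt_config))
  stats::setNames(drop(cnn_predict(model$cnn, img)), model$vocab)
}

# score every annotated beat of a record in one batched pass;
# returns n_beats x |vocab| matrix in beat order
score_record_beats <- function(model, record, chunk_s = 2.4) {
  n <- nrow(record$beats)
  if (n == 0) return(matrix(0, 0, length(model$vocab)))
  if (inherits(model, "beat_model_oracle")) {
    i <- match(record$beats$label, model$vocab)
    if (anyNA(i)) stop("unknown beat label in record")
    m <- matrix(0, n, length(model$vocab))
    m[cbind(seq_len(n), i)] <- 1
    return(m)
  }
  imgs <- lapply(seq_len(n), function(b) {
    ch <- extract_chunk(record$samples, record$beats$position[b], record$fs,
                        chunk_s = chunk_s, true_label = record$beats$label[b])
    scalogram_image(cwt_scalogram(ch, model$cwt_config))
  })
  cnn_predict(model$cnn, imgs)
}
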