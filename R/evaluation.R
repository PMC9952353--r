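#' Confusion matrix
#'
#' @param truth,predicted equal-length label vectors
#' @param classes class order (rows = truth, columns = predicted); every
#'   label must appear in it
#' @return K x K integer matrix of counts with dimnames.
#' @export
confusion <- function(truth, predicted, classes) {
  stopifnot(length(truth) == length(predicted))
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad)) stop("labels outside class order: ", paste(bad, collapse = " "))
  m <- table(factor(truth, classes), factor(predicted, classes))
  matrix(as.integer(m), length(classes), length(classes),
         dimnames = list(truth = classes, predicted = classes))
}

# round half-up on the percentage scale (display convention)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-class one-vs-rest metrics from a confusion matrix
#'
#' For each class taken as positive: sensitivity `TP/(TP+FN)`, precision
#' `TP/(TP+FP)`, specificity `TN/(TN+FP)`, class accuracy `(TP+TN)/total`,
#' F1 the harmonic mean of precision and sensitivity (0 when both are 0,
#' with a warning when the class was never predicted). Overall accuracy is
#' `trace/total`. Percentages are rounded half-up to 2 decimals for the
#' report; unrounded ratios are kept in the `"raw"` attribute. A class with
#' an empty truth row gets `NA` sensitivity (undefined, not 0).
#'
#' @param cm confusion matrix from [confusion()]
#' @return data.frame (class, sensitivity, specificity, precision, f1,
#'   accuracy; percentages), with attributes `overall_accuracy` (rounded
#'   percentage) and `raw` (unrounded proportions incl. `overall_accuracy`).
#' @export
per_class_metrics <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm), sum(cm) > 0)
  total <- sum(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  sen <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  pre <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  spec <- tn / (tn + fp)
  acc <- (tp + tn) / total
  f1 <- numeric(length(tp))
  for (i in seq_along(tp)) {
    s <- sen[i]; p <- pre[i]
    if (is.na(s)) { f1[i] <- NA_real_; next }
    if (is.na(p) || (p + s) == 0) {
      if (is.na(p)) warning("class '", rownames(cm)[i],
                            "' never predicted; F1 reported as 0")
      f1[i] <- 0
    } else {
      f1[i] <- 2 * p * s / (p + s)
    }
  }
  overall <- sum(tp) / total
  out <- data.frame(
    class = rownames(cm),
    sensitivity = round_half_up(100 * sen),
    specificity = round_half_up(100 * spec),
    precision = round_half_up(100 * pre),
    f1 = round_half_up(100 * f1),
    accuracy = round_half_up(100 * acc),
    row.names = NULL
  )
  attr(out, "overall_accuracy") <- round_half_up(100 * overall)
  attr(out, "raw") <- list(sensitivity = sen, specificity = spec,
                           precision = pre, f1 = f1, accuracy = acc,
                           overall_accuracy = overall)
  out
}

#' Macro-averaged F1 from a confusion matrix
#'
#' Unweighted mean of the per-class F1 ratios (proportion scale, not
#' percent); classes with undefined F1 are skipped.
#'
#' @param cm confusion matrix
#' @return A single number in \[0, 1\].
#' @export
macro_f1 <- function(cm) {
  raw <- attr(per_class_metrics(cm), "raw")
  mean(raw$f1, na.rm = TRUE)
}

#' Noise-robustness experiment
#'
#' For each SNR level: inject calibrated white noise into the raw records,
#' re-run denoising, train a beat classifier on the noisy beat chunks, build
#' BSM images for all rhythm windows, cross-validate the rhythm classifier,
#' and report per-class metrics. The level `"none"` runs the identical
#' pipeline without noise injection. Deterministic given `seed`.
#'
#' @param records named list of raw `ecg_record`s (with beats and regions)
#' @param snr_levels vector of SNR levels in dB; the string `"none"` (or
#'   `NA`) means no injected noise
#' @param config [training_config()] used for both classifiers
#' @param seed integer master seed
#' @param window_s,stride_s windowing parameters
#' @param cwt_config scalogram settings for the beat classifier
#' @return Named list per level: `metrics` (per-class data.frame),
#'   `confusion`, `macro_f1`.
#' @export
noise_experiment <- function(records, snr_levels, config = training_config(),
                             seed = 1L, window_s = 10, stride_s = 1,
                             cwt_config = bsm_config()$cwt) {
  out <- list()
  for (li in seq_along(snr_levels)) {
    level <- snr_levels[li]
    key <- if (identical(level, "none") || is.na(suppressWarnings(as.numeric(level))))
      "none" else paste0(level, "dB")
    noisy <- lapply(seq_along(records), function(i) {
      if (key == "none") records[[i]]
      else add_noise(records[[i]], as.numeric(level), seed + 37L * i)
    })
    denoised <- lapply(noisy, denoise_record)
    beat_set <- make_beat_training_set(denoised, cwt_config)
    beat_model <- train_beat_classifier(beat_set$scalograms, beat_set$labels,
                                        config, seed = seed,
                                        cwt_config = cwt_config)
    ds <- make_bsm_dataset(denoised, beat_model, window_s = window_s,
                           stride_s = stride_s)
    cv <- cross_validate(ds$images, ds$labels, config, seed = seed)
    out[[key]] <- list(metrics = per_class_metrics(cv$confusion),
                       confusion = cv$confusion,
                       macro_f1 = macro_f1(cv$confusion))
  }
  out
}
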