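# Dataset assembly: chunks -> scalograms for beat training, and
# records -> labelled BSM images for rhythm training.

#' Build a beat training set from annotated records
#'
#' Extracts the 2.4-s chunk of every annotated beat in every record and
#' computes its scalogram.
#'
#' @param records list of (denoised) `ecg_record`s
#' @param cwt_config scalogram settings ([bsm_config()]`$cwt`)
#' @param chunk_s chunk duration in seconds
#' @return list with `scalograms` (list) and `labels` (beat symbols).
#' @export
make_beat_training_set <- function(records, cwt_config = bsm_config()$cwt,
                                   chunk_s = 2.4) {
  scal <- list(); labs <- character()
  for (rec in records) {
    for (b in seq_len(nrow(rec$beats))) {
      ch <- extract_chunk(rec$samples, rec$beats$position[b], rec$fs,
                          chunk_s = chunk_s, true_label = rec$beats$label[b])
      scal[[length(scal) + 1L]] <- cwt_scalogram(ch, cwt_config)
      labs <- c(labs, rec$beats$label[b])
    }
  }
  list(scalograms = scal, labels = labs)
}

#' Build a labelled BSM image dataset from annotated records
#'
#' Slides labelled rhythm windows over each (denoised) record and converts
#' every window to its resized BSM image with the given beat model.
#'
#' @param records list of (denoised) `ecg_record`s
#' @param beat_model a `beat_model` (trained or [oracle_beat_model()])
#' @param window_s,stride_s windowing parameters (defaults 10 s / 1 s)
#' @param reduce_factor,resize_rep BSM pipeline constants
#' @return list with `images` (list of resized `bsm_matrix`), `labels`
#'   (rhythm symbols) and `meta` (data.frame `record`, `start`).
#' @export
make_bsm_dataset <- function(records, beat_model, window_s = 10, stride_s = 1,
                             reduce_factor = 10, resize_rep = 10) {
  images <- list(); labels <- character()
  rec_id <- character(); start <- integer()
  for (rec in records) {
    wins <- slide_windows(rec, window_s, stride_s)
    if (length(wins) == 0) next
    # each beat sits in up to window_s/stride_s overlapping windows: score
    # the record's beats once and slice per window
    scores <- score_record_beats(beat_model, rec)
    for (w in wins) {
      inside <- which(rec$beats$position >= w$start &
                        rec$beats$position < w$start + length(w$signal))
      bsm <- build_bsm(w, scores[inside, , drop = FALSE], beat_model$vocab)
      images[[length(images) + 1L]] <-
        resize_image(reduce_time(bsm, reduce_factor), resize_rep)
      labels <- c(labels, w$label)
      rec_id <- c(rec_id, w$source_record)
      start <- c(start, w$start)
    }
  }
  list(images = images, labels = labels,
       meta = data.frame(record = rec_id, start = start))
}

#' Printed study confusion matrices
#'
#' Loads one of the two published confusion matrices shipped with the
#' package as plain-text fixtures: `"5class"` (rhythms with few samples: N,
#' AFIB, SVTA, B, T) or `"6class"` (similar rhythms: N, AFIB, B, P, AFL,
#' SBR). Rows are true classes, columns predicted.
#'
#' @param which `"5class"` or `"6class"`
#' @return Integer confusion matrix with dimnames.
#' @export
published_confusion <- function(which = c("5class", "6class")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("confusion_", which, ".tsv"),
                      package = "bsmecg")
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  names(dimnames(m)) <- c("truth", "predicted")
  m
}
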