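#' Beat and rhythm vocabularies
#'
#' The beat vocabulary is the fixed, ordered set of 15 MIT-BIH beat symbols
#' kept after dropping the unreadable symbol `"?"`. Its *order* defines the
#' class axis of every beat score vector and hence the row order of BSM
#' images; any trained model stores the vocabulary it was built with.
#'
#' @return Character vector of class symbols, in canonical order.
#' @export
beat_vocabulary <- function() {
  c("N", "L", "R", "A", "a", "J", "S", "V", "F", "e", "j", "E", "/", "f", "Q")
}

#' @rdname beat_vocabulary
#' @details The rhythm vocabulary covers the eight MIT-BIH rhythm labels the
#'   classifier distinguishes: normal sinus rhythm (N), atrial fibrillation
#'   (AFIB), atrial flutter (AFL), supraventricular tachyarrhythmia (SVTA),
#'   ventricular bigeminy (B), ventricular trigeminy (T), sinus bradycardia
#'   (SBR) and paced rhythm (P).
#' @export
rhythm_vocabulary <- function() {
  c("N", "AFIB", "AFL", "SVTA", "B", "T", "SBR", "P")
}

#' Package configuration
#'
#' Returns the full configuration list, optionally overridden by a YAML file
#' and/or a named list. Keys (defaults in parentheses):
#' \describe{
#'   \item{beat_vocabulary, rhythm_vocabulary}{ordered class symbol lists}
#'   \item{lead}{ECG lead to read ("MLII")}
#'   \item{window_s (10), stride_s (1)}{rhythm window length and stride, seconds}
#'   \item{wavelet ("db4"), baseline_level (9), highfreq_level (6)}{denoising}
#'   \item{label_rule ("majority")}{window label assignment rule}
#'   \item{chunk_s (2.4)}{beat chunk duration, centred on the R peak}
#'   \item{cwt}{`n_scales` (32), `fmin_hz` (0.5), `fmax_hz` (50), `omega0` (6)}
#'   \item{bsm}{`reduce_factor` (10), `resize_rep` (10)}
#'   \item{training}{see [training_config()]}
#' }
#'
#' @param path optional YAML file whose keys override the defaults
#' @param overrides optional named list applied after the file
#' @return A nested configuration list.
#' @export
bsm_config <- function(path = NULL, overrides = NULL) {
  cfg <- list(
    beat_vocabulary = beat_vocabulary(),
    rhythm_vocabulary = rhythm_vocabulary(),
    lead = "MLII",
    window_s = 10,
    stride_s = 1,
    wavelet = "db4",
    baseline_level = 9,
    highfreq_level = 6,
    label_rule = "majority",
    chunk_s = 2.4,
    cwt = list(n_scales = 32, fmin_hz = 0.5, fmax_hz = 50, omega0 = 6),
    bsm = list(reduce_factor = 10, resize_rep = 10),
    training = training_config()
  )
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- modify_list_deep(cfg, yaml::read_yaml(path))
  }
  if (!is.null(overrides)) cfg <- modify_list_deep(cfg, overrides)
  cfg
}

# recursive utils::modifyList that merges nested lists key-wise
modify_list_deep <- function(base, new) {
  for (k in names(new)) {
    if (is.list(new[[k]]) && is.list(base[[k]]) && !is.null(names(new[[k]]))) {
      base[[k]] <- modify_list_deep(base[[k]], new[[k]])
    } else {
      base[[k]] <- new[[k]]
    }
  }
  base
}

#' Training configuration for the rhythm (and beat) classifier
#'
#' Defaults follow the study settings: Adam, learning rate 0.001, 30 epochs,
#' batch size 16, five folds. The source reports both 16 and 4 as the batch
#' size in different sections; 16 is kept as the default.
#'
#' @param learning_rate positive step size for Adam
#' @param epochs number of passes over the training set
#' @param batch_size mini-batch size
#' @param folds number of cross-validation folds (>= 2)
#' @param optimizer only "adam" is implemented
#' @param backbone "small-cnn" (compact network trained from scratch) or
#'   "vgg16-transfer" (requires externally supplied pretrained weights)
#' @param seed integer seed controlling initialisation and sampling
#' @param n_filters,kernel_t,hidden convolutional width, temporal kernel
#'   length and hidden dense width of the small-cnn backbone
#' @return A list of class `training_config`.
#' @export
training_config <- function(learning_rate = 0.001, epochs = 30, batch_size = 16,
                            folds = 5, optimizer = "adam",
                            backbone = "small-cnn", seed = 1L,
                            n_filters = 8L, kernel_t = 25L, hidden = 32L) {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1, folds >= 2)
  if (!optimizer %in% "adam") stop("unsupported optimizer: ", optimizer)
  if (!backbone %in% c("small-cnn", "vgg16-transfer")) {
    stop("unknown backbone: ", backbone)
  }
  structure(list(
    learning_rate = learning_rate, epochs = as.integer(epochs),
    batch_size = as.integer(batch_size), folds = as.integer(folds),
    optimizer = optimizer, backbone = backbone, seed = as.integer(seed),
    n_filters = as.integer(n_filters), kernel_t = as.integer(kernel_t),
    hidden = as.integer(hidden)
  ), class = "training_config")
}
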