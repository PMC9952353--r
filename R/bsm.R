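# Beat score map construction: interval padding (score vectors placed at
# their R-peak time index, zeros elsewhere, so zero-run lengths encode the
# R-R intervals), one-tenth time reduction by per-class block max, and
# nearest-neighbour replication of the class axis to the final image size.
# Orientation: time on the first axis, beat class on the second
# (3600 x 15 -> 360 x 15 -> 360 x 150 for a 10-s window at 360 Hz).

new_bsm <- function(values, stage, vocab) {
  structure(values, stage = stage, vocab = vocab, class = "bsm_matrix")
}

#' @export
print.bsm_matrix <- function(x, ...) {
  cat(sprintf("<bsm_matrix %s> %d x %d, %d nonzero time points\n",
              attr(x, "stage"), nrow(x), ncol(x),
              sum(rowSums(unclass(x)) > 0)))
  invisible(x)
}

bsm_stage <- function(x) attr(x, "stage")

#' Build the raw beat score map of one rhythm window
#'
#' Interval padding: row `p` of the output equals the score vector of the
#' beat annotated at window-relative R position `p`; all other rows are
#' exactly zero.
#'
#' @param window a `rhythm_window` (provides the relative R positions)
#' @param score_vectors matrix with one row per beat (columns = beat
#'   vocabulary, rows in beat order), or a list of score vectors
#' @param vocab beat vocabulary (fixes the class axis)
#' @return A `bsm_matrix`, stage `"raw"`, shape `length(window$signal)` x
#'   `length(vocab)`.
#' @export
build_bsm <- function(window, score_vectors, vocab = beat_vocabulary()) {
  stopifnot(inherits(window, "rhythm_window"))
  if (is.list(score_vectors)) score_vectors <- do.call(rbind, score_vectors)
  if (is.null(score_vectors)) score_vectors <- matrix(0, 0, length(vocab))
  n_beats <- nrow(window$beats)
  if (nrow(score_vectors) != n_beats) {
    stop("got ", nrow(score_vectors), " score vectors for ", n_beats, " beats")
  }
  t_len <- length(window$signal)
  m <- matrix(0, t_len, length(vocab))
  if (n_beats > 0) {
    pos <- window$beats$position
    if (any(pos < 0 | pos >= t_len)) stop("relative R position outside window")
    m[pos + 1L, ] <- score_vectors
  }
  new_bsm(m, "raw", vocab)
}

#' Reduce the BSM time axis by block maximum
#'
#' Entry `(t, c)` of the output is the maximum of class `c` over the
#' `factor`-length time block `[t*factor, (t+1)*factor)`. Block max (rather
#' than decimation) guarantees every beat's scores survive the reduction;
#' two beats falling in one block merge into the elementwise max.
#'
#' @param bsm a raw `bsm_matrix`
#' @param factor reduction factor; must divide the time length (3600 -> 360
#'   with the default 10)
#' @return A `bsm_matrix`, stage `"reduced"`.
#' @export
reduce_time <- function(bsm, factor = 10) {
  stopifnot(inherits(bsm, "bsm_matrix"))
  if (bsm_stage(bsm) != "raw") {
    stop("reduce_time expects a raw BSM, got stage '", bsm_stage(bsm), "'")
  }
  v <- unclass(bsm)
  t_len <- nrow(v)
  if (t_len %% factor != 0) {
    stop("time length ", t_len, " not divisible by reduction factor ", factor)
  }
  t_out <- t_len %/% factor
  dim(v) <- c(factor, t_out * ncol(bsm))
  r <- matrix(apply(v, 2, max), t_out, ncol(bsm))
  new_bsm(r, "reduced", attr(bsm, "vocab"))
}

#' Resize a reduced BSM to the final image
#'
#' Nearest-neighbour replication of each beat-class column `rep` times
#' (360 x 15 -> 360 x 150 by default). Replication, not interpolation,
#' keeps the score values intact instead of blurring them across class
#' bands.
#'
#' @param bsm a reduced `bsm_matrix`
#' @param rep replication factor per class column (default 10)
#' @return A `bsm_matrix`, stage `"resized"`.
#' @export
resize_image <- function(bsm, rep = 10) {
  stopifnot(inherits(bsm, "bsm_matrix"))
  if (bsm_stage(bsm) != "reduced") {
    stop("resize_image expects a reduced BSM, got stage '", bsm_stage(bsm), "'")
  }
  v <- unclass(bsm)[, rep(seq_len(ncol(bsm)), each = rep), drop = FALSE]
  new_bsm(v, "resized", attr(bsm, "vocab"))
}

#' Window to final BSM image
#'
#' Full composition for one rhythm window: extract the 2.4-s chunk of every
#' beat from the *record* signal (so chunks overrunning the window boundary
#' keep their real samples), score each chunk with the beat model, place the
#' score vectors by interval padding, reduce time by one tenth, and resize.
#'
#' @param record the (denoised) `ecg_record` the window came from
#' @param window a `rhythm_window` of that record
#' @param model a `beat_model` (trained or [oracle_beat_model()])
#' @param reduce_factor,resize_rep pipeline constants (defaults 10, 10)
#' @param chunk_s beat chunk duration in seconds
#' @return A resized `bsm_matrix` (360 x 150 at the defaults).
#' @export
window_to_bsm <- function(record, window, model, reduce_factor = 10,
                          resize_rep = 10, chunk_s = 2.4) {
  stopifnot(inherits(record, "ecg_record"), inherits(window, "rhythm_window"))
  n_beats <- nrow(window$beats)
  scores <- matrix(0, n_beats, length(model$vocab))
  for (b in seq_len(n_beats)) {
    chunk <- extract_chunk(record$samples, window$start + window$beats$position[b],
                           record$fs, chunk_s = chunk_s,
                           true_label = window$beats$label[b])
    scores[b, ] <- predict_beat_scores(model, chunk)
  }
  resize_image(reduce_time(build_bsm(window, scores, model$vocab),
                           reduce_factor), resize_rep)
}

#' Persist a BSM image as 16-bit grayscale PNG with a JSON sidecar
#'
#' Scores are quantized to `round(score * 65535)`; the sidecar records the
#' window provenance, rhythm label, stage and beat vocabulary order.
#' [read_bsm_png()] restores the matrix (to 16-bit precision).
#'
#' @param bsm a `bsm_matrix`
#' @param path output PNG path (sidecar gets `.json` appended)
#' @param label rhythm label stored in the sidecar
#' @param source free-form provenance (record id / window start)
#' @return `path`, invisibly.
#' @export
write_bsm_png <- function(bsm, path, label = NA_character_, source = "") {
  stopifnot(inherits(bsm, "bsm_matrix"))
  write_png16(unclass(bsm), path)
  jsonlite::write_json(
    list(label = label, source = source, stage = bsm_stage(bsm),
         vocab = attr(bsm, "vocab"), dim = dim(bsm)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_bsm_png
#' @export
read_bsm_png <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  v <- png::readPNG(path)
  bsm <- new_bsm(v, meta$stage, meta$vocab)
  attr(bsm, "label") <- meta$label
  attr(bsm, "source") <- meta$source
  bsm
}

# Minimal 16-bit grayscale PNG encoder (png::writePNG is 8-bit only).
# values in [0, 1], matrix rows = image rows. memCompress(type = "gzip")
# emits a zlib (RFC 1950) stream, which is what IDAT requires.
write_png16 <- function(values, path) {
  stopifnot(all(values >= 0 & values <= 1))
  h <- nrow(values); w <- ncol(values)
  q <- t(round(values * 65535))                        # row-major pixel order
  px <- as.raw(as.vector(rbind(as.vector(q) %/% 256, as.vector(q) %% 256)))
  scan <- rbind(matrix(as.raw(0), 1, h),               # filter byte per row
                matrix(px, nrow = 2 * w))
  idat <- memCompress(as.vector(scan), "gzip")
  int_be <- function(x) as.raw(c(x %/% 16777216, x %/% 65536, x %/% 256, x) %% 256)
  chunk <- function(type, data) {
    body <- c(charToRaw(type), data)
    c(int_be(length(data)), body, int_be(png_crc32(body)))
  }
  ihdr <- c(int_be(w), int_be(h), as.raw(c(16, 0, 0, 0, 0)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           chunk("IHDR", ihdr), chunk("IDAT", idat), chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

# CRC-32 (PNG polynomial) on unsigned 32-bit values carried in doubles;
# 16-bit halves go through bitwXor, which only accepts ints
xor32 <- function(a, b) {
  bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536)) * 65536 +
    bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
}

png_crc_env <- new.env()

png_crc32 <- function(bytes) {
  if (is.null(png_crc_env$tab)) {
    tab <- numeric(256)
    for (i in 0:255) {
      c <- i
      for (k in 1:8) {
        c <- if (c %% 2 == 1) xor32(3988292384, c %/% 2) else c %/% 2
      }
      tab[i + 1] <- c
    }
    png_crc_env$tab <- tab
  }
  tab <- png_crc_env$tab
  crc <- 4294967295
  for (x in as.integer(bytes)) {
    crc <- xor32(tab[bitwXor(as.integer(crc %% 256), x) + 1], crc %/% 256)
  }
  xor32(crc, 4294967295)
}
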