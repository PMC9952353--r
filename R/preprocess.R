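#' Denoise a whole record
#'
#' Applies [remove_baseline()] (level 9) then [remove_highfreq()] (level 6)
#' to the record's samples. Denoising is done on whole records before
#' windowing so 10-s slices carry no per-window edge artefacts.
#'
#' @param record an `ecg_record`
#' @param baseline_level,highfreq_level decomposition depths
#' @param wavelet mother wavelet
#' @return The record with denoised samples.
#' @export
denoise_record <- function(record, baseline_level = 9, highfreq_level = 6,
                           wavelet = "db4") {
  stopifnot(inherits(record, "ecg_record"))
  s <- remove_baseline(record$samples, record$fs, baseline_level, wavelet)
  record$samples <- remove_highfreq(s, record$fs, highfreq_level, wavelet)
  record
}

#' Assign a rhythm label to a window span
#'
#' Strict-majority rule: the label of the rhythm region covering more than
#' half of the window; `NA` (window dropped) when no region reaches a
#' majority, including exact 50/50 ties at rhythm boundaries.
#'
#' @param span `c(start, end)` half-open sample interval
#' @param regions rhythm regions data.frame (`start`, `end`, `label`)
#' @return A rhythm symbol, or `NA_character_`.
#' @export
assign_label <- function(span, regions) {
  if (nrow(regions) == 0) return(NA_character_)
  ov <- pmax(0, pmin(span[2], regions$end) - pmax(span[1], regions$start))
  best <- which.max(ov)
  if (ov[best] > (span[2] - span[1]) / 2) regions$label[best] else NA_character_
}

#' Cut a record into labelled rhythm windows
#'
#' Slides a `window_s`-second window with `stride_s`-second stride over the
#' record (starts at 0, stride, 2*stride, ... while a full window fits).
#' Each window is labelled by [assign_label()]; unlabelled windows are
#' dropped. Beats whose R peak falls inside the window are attached with
#' window-relative positions.
#'
#' @param record a (denoised) `ecg_record`
#' @param window_s window length in seconds (default 10)
#' @param stride_s stride in seconds (default 1)
#' @return List of `rhythm_window` objects, each with `source_record`,
#'   `start` (absolute sample index), `fs`, `signal`, `label` and `beats`
#'   (`position` relative to window start, `label`).
#' @export
slide_windows <- function(record, window_s = 10, stride_s = 1) {
  stopifnot(inherits(record, "ecg_record"))
  n <- length(record$samples)
  w <- round(window_s * record$fs)
  stride <- round(stride_s * record$fs)
  if (n < w) return(list())
  starts <- seq(0L, n - w, by = stride)
  out <- lapply(starts, function(s0) {
    lab <- assign_label(c(s0, s0 + w), record$regions)
    if (is.na(lab)) return(NULL)
    inside <- record$beats$position >= s0 & record$beats$position < s0 + w
    structure(list(
      source_record = record$record_id, start = s0, fs = record$fs,
      signal = record$samples[(s0 + 1):(s0 + w)], label = lab,
      beats = data.frame(position = record$beats$position[inside] - s0,
                         label = record$beats$label[inside])
    ), class = "rhythm_window")
  })
  out[!vapply(out, is.null, TRUE)]
}

#' @export
print.rhythm_window <- function(x, ...) {
  cat(sprintf("<rhythm_window %s @ %d> %s, %d samples, %d beats\n",
              x$source_record, x$start, x$label, length(x$signal),
              nrow(x$beats)))
  invisible(x)
}
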