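#' Construct an annotated single-lead ECG record
#'
#' The uniform in-memory record model used throughout the package: the signal
#' of one lead plus its beat annotations (R-peak sample positions and beat
#' symbols) and rhythm regions (half-open, 0-based sample intervals).
#'
#' @param samples numeric vector of signal values in mV
#' @param fs sampling rate in Hz (positive); MIT-BIH records use 360
#' @param record_id short identifier
#' @param lead_name lead label, e.g. "MLII"
#' @param beats data.frame with columns `position` (0-based sample index of
#'   the R peak, strictly increasing) and `label` (beat vocabulary symbol)
#' @param regions data.frame with columns `start`, `end` (half-open, 0-based
#'   sample interval) and `label` (rhythm vocabulary symbol); non-overlapping
#' @param beat_vocab,rhythm_vocab permitted symbol sets
#' @return A list of class `ecg_record` with elements `record_id`, `fs`,
#'   `samples`, `lead_name`, `beats`, `regions`.
#' @export
ecg_record <- function(samples, fs, record_id = "rec", lead_name = "MLII",
                       beats = empty_beats(), regions = empty_regions(),
                       beat_vocab = beat_vocabulary(),
                       rhythm_vocab = rhythm_vocabulary()) {
  stopifnot(is.numeric(samples), length(samples) > 0, is.numeric(fs), fs > 0)
  beats <- as.data.frame(beats)
  beats$position <- as.integer(beats$position)
  beats$label <- as.character(beats$label)
  regions <- as.data.frame(regions)
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  regions$label <- as.character(regions$label)
  fs <- as.numeric(fs)
  validate_beats(beats, length(samples), beat_vocab)
  validate_regions(regions, rhythm_vocab)
  structure(list(
    record_id = as.character(record_id), fs = fs,
    samples = as.numeric(samples), lead_name = as.character(lead_name),
    beats = beats, regions = regions
  ), class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s> lead %s, %d samples @ %g Hz (%.1f s), %d beats, %d rhythm regions\n",
              x$record_id, x$lead_name, length(x$samples), x$fs,
              length(x$samples) / x$fs, nrow(x$beats), nrow(x$regions)))
  invisible(x)
}

empty_beats <- function() {
  data.frame(position = integer(), label = character())
}

empty_regions <- function() {
  data.frame(start = integer(), end = integer(), label = character())
}

validate_beats <- function(beats, n, vocab) {
  stopifnot(all(c("position", "label") %in% names(beats)))
  if (nrow(beats) == 0) return(invisible(TRUE))
  if (any(beats$position < 0 | beats$position >= n)) {
    stop("beat position outside record [0, ", n, ")")
  }
  if (any(diff(beats$position) <= 0)) {
    stop("beat positions must be strictly increasing")
  }
  bad <- setdiff(unique(beats$label), vocab)
  if (length(bad)) stop("beat labels outside vocabulary: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

validate_regions <- function(regions, vocab) {
  stopifnot(all(c("start", "end", "label") %in% names(regions)))
  if (nrow(regions) == 0) return(invisible(TRUE))
  if (any(regions$start >= regions$end)) stop("region start must be < end")
  r <- regions[order(regions$start), ]
  if (nrow(r) > 1 && any(r$start[-1] < r$end[-nrow(r)])) {
    stop("rhythm regions overlap")
  }
  bad <- setdiff(unique(regions$label), vocab)
  if (length(bad)) stop("rhythm labels outside vocabulary: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Reconstruct rhythm regions from rhythm-change markers
#'
#' A marker `(X` at sample p opens region X from p until the next marker or
#' the end of the record, mirroring how WFDB `+` annotations with aux strings
#' delimit rhythm episodes. Signal before the first marker carries no rhythm
#' label and yields no region.
#'
#' @param positions integer sample positions of the markers (ascending)
#' @param labels rhythm symbols, one per marker (aux strings already stripped
#'   of the leading parenthesis)
#' @param record_length total number of samples
#' @return regions data.frame (`start`, `end`, `label`)
#' @export
regions_from_markers <- function(positions, labels, record_length) {
  stopifnot(length(positions) == length(labels))
  if (length(positions) == 0) return(empty_regions())
  o <- order(positions)
  positions <- positions[o]; labels <- labels[o]
  data.frame(
    start = as.integer(positions),
    end = as.integer(c(positions[-1], record_length)),
    label = as.character(labels)
  )
}

#' Read an annotated ECG record
#'
#' Reads either a WFDB record (`.hea`/`.dat`/`.atr` triplet; format 212 or
#' 16) or the package's plain-text dialect (three CSVs plus a JSON metadata
#' sidecar, see [write_record()]). Beats labelled `"?"` (unreadable) are
#' dropped; any other symbol outside the beat vocabulary is rejected with a
#' warning and counted, never silently kept. Rhythm regions are
#' reconstructed from the rhythm-change markers.
#'
#' @param path record path: for WFDB the header path or its stem, for the
#'   text dialect the stem of the `<stem>_signal.csv` etc. files
#' @param lead which lead to extract (WFDB records may have several)
#' @param format "auto", "wfdb" or "text"
#' @param beat_vocab,rhythm_vocab permitted symbol sets
#' @return An `ecg_record`, with attribute `dropped_beats` giving the number
#'   of annotations discarded ('?' plus out-of-vocabulary symbols).
#' @export
read_record <- function(path, lead = "MLII", format = c("auto", "wfdb", "text"),
                        beat_vocab = beat_vocabulary(),
                        rhythm_vocab = rhythm_vocabulary()) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (file.exists(paste0(sub("\\.hea$", "", path), ".hea"))) "wfdb" else "text"
  }
  if (format == "wfdb") {
    read_wfdb_record(path, lead, beat_vocab, rhythm_vocab)
  } else {
    read_text_record(path, lead, beat_vocab, rhythm_vocab)
  }
}

#' Write an annotated ECG record
#'
#' The text dialect writes `<stem>_signal.csv` (one `value` column),
#' `<stem>_beats.csv` (`position,label`), `<stem>_regions.csv`
#' (`start,end,label`) and `<stem>_meta.json` (record id, fs, lead). A
#' record written and re-read round-trips exactly (sample values are printed
#' with full precision).
#'
#' @param record an `ecg_record`
#' @param path output stem (text dialect) or header stem (wfdb)
#' @param format "text" or "wfdb"
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, format = c("text", "wfdb")) {
  format <- match.arg(format)
  stopifnot(inherits(record, "ecg_record"))
  if (format == "wfdb") return(write_wfdb_record(record, path))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(value = format_full(record$samples)),
                   paste0(path, "_signal.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(record$beats, paste0(path, "_beats.csv"),
                   row.names = FALSE, quote = TRUE)
  utils::write.csv(record$regions, paste0(path, "_regions.csv"),
                   row.names = FALSE, quote = TRUE)
  jsonlite::write_json(
    list(record_id = record$record_id, fs = record$fs, lead = record$lead_name),
    paste0(path, "_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

format_full <- function(x) formatC(x, format = "g", digits = 17)

read_text_record <- function(path, lead, beat_vocab, rhythm_vocab) {
  meta_path <- paste0(path, "_meta.json")
  if (!file.exists(meta_path)) stop("text record not found at stem: ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!is.null(meta$lead) && !identical(meta$lead, lead)) {
    stop("lead not found: record has '", meta$lead, "', requested '", lead, "'")
  }
  samples <- utils::read.csv(paste0(path, "_signal.csv"))$value
  beats <- utils::read.csv(paste0(path, "_beats.csv"),
                           colClasses = c("integer", "character"))
  regions <- utils::read.csv(paste0(path, "_regions.csv"),
                             colClasses = c("integer", "integer", "character"))
  res <- filter_beats(beats, beat_vocab)
  rec <- ecg_record(samples, as.numeric(meta$fs), meta$record_id, lead,
                    res$beats, regions, beat_vocab, rhythm_vocab)
  attr(rec, "dropped_beats") <- res$dropped
  rec
}

# drop '?' silently-but-counted; other unknown symbols additionally warn
filter_beats <- function(beats, vocab) {
  keep <- beats$label %in% vocab
  unknown <- !keep & beats$label != "?"
  if (any(unknown)) {
    warning(sum(unknown), " beat annotation(s) with symbols outside the vocabulary dropped: ",
            paste(unique(beats$label[unknown]), collapse = " "))
  }
  list(beats = beats[keep, , drop = FALSE], dropped = sum(!keep))
}
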