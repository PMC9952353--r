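# Minimal native WFDB support: header (.hea), signal (.dat, formats 212 and
# 16) and MIT annotation (.atr) files, covering what MIT-BIH style records
# need — multi-signal format-212 frames, beat codes, and '+' rhythm-change
# markers carrying "(LABEL" aux strings.

# WFDB annotation code -> display symbol (beat codes + the ones we must
# recognise to skip or interpret)
wfdb_code_symbol <- function() {
  c(`1` = "N", `2` = "L", `3` = "R", `4` = "a", `5` = "V", `6` = "F",
    `7` = "J", `8` = "A", `9` = "S", `10` = "E", `11` = "j", `12` = "/",
    `13` = "Q", `28` = "+", `30` = "?", `35` = "e", `38` = "f")
}
wfdb_symbol_code <- function() {
  syms <- wfdb_code_symbol()
  stats::setNames(as.integer(names(syms)), syms)
}
WFDB_RHYTHM_CODE <- 28L  # '+'
WFDB_SKIP <- 59L; WFDB_NUM <- 60L; WFDB_SUB <- 61L; WFDB_CHN <- 62L; WFDB_AUX <- 63L

read_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(rec[2])
  fs <- as.numeric(strsplit(rec[3], "/")[[1]][1])
  nsamp <- if (length(rec) >= 4) as.integer(rec[4]) else NA_integer_
  sig <- lapply(lines[seq_len(nsig) + 1L], function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    gain_field <- strsplit(f[3], "/")[[1]][1]           # strip "/mV"
    baseline <- NA_real_
    if (grepl("\\(", gain_field)) {
      baseline <- as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_field))
      gain_field <- sub("\\(.*", "", gain_field)
    }
    gain <- as.numeric(gain_field)
    if (is.na(gain) || gain == 0) gain <- 200           # WFDB default
    adc_zero <- if (length(f) >= 5) as.numeric(f[5]) else 0
    if (is.na(baseline)) baseline <- adc_zero
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else ""
    list(file = f[1], format = f[2], gain = gain, baseline = baseline,
         desc = desc)
  })
  list(record = rec[1], nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

# decode format-212 bytes into an nsig-column matrix of adc units
decode_fmt212 <- function(bytes, nsig, nsamp) {
  n_total <- nsamp * nsig
  n_pairs <- ceiling(n_total / 2)
  bytes <- as.integer(bytes[seq_len(n_pairs * 3)])
  b0 <- bytes[seq(1, length(bytes), 3)]
  b1 <- bytes[seq(2, length(bytes), 3)]
  b2 <- bytes[seq(3, length(bytes), 3)]
  s1 <- b0 + bitwShiftL(bitwAnd(b1, 0x0F), 8)
  s2 <- b2 + bitwShiftL(bitwAnd(b1, 0xF0), 4)
  s1 <- ifelse(s1 >= 2048, s1 - 4096, s1)
  s2 <- ifelse(s2 >= 2048, s2 - 4096, s2)
  v <- as.vector(rbind(s1, s2))[seq_len(n_total)]
  matrix(v, ncol = nsig, byrow = TRUE)
}

encode_fmt212 <- function(values) {
  v <- as.integer(round(values))
  if (any(v < -2048 | v > 2047)) stop("sample out of 12-bit range for format 212")
  if (length(v) %% 2 == 1) v <- c(v, 0L)
  v <- ifelse(v < 0, v + 4096L, v)
  s1 <- v[seq(1, length(v), 2)]
  s2 <- v[seq(2, length(v), 2)]
  as.raw(as.vector(rbind(
    bitwAnd(s1, 0xFF),
    bitwOr(bitwShiftR(s1, 8), bitwShiftL(bitwShiftR(s2, 8), 4)),
    bitwAnd(s2, 0xFF)
  )))
}

read_wfdb_signal <- function(stem, hdr) {
  dat_path <- file.path(dirname(stem), hdr$signals[[1]]$file)
  if (!file.exists(dat_path)) dat_path <- paste0(stem, ".dat")
  bytes <- readBin(dat_path, "raw", n = file.info(dat_path)$size)
  fmt <- hdr$signals[[1]]$format
  nsamp <- hdr$nsamp
  if (fmt == "212") {
    if (is.na(nsamp)) nsamp <- floor(length(bytes) * 2 / 3 / hdr$nsig)
    decode_fmt212(bytes, hdr$nsig, nsamp)
  } else if (fmt == "16") {
    v <- readBin(bytes, "integer", n = length(bytes) %/% 2, size = 2,
                 signed = TRUE, endian = "little")
    if (is.na(nsamp)) nsamp <- length(v) %/% hdr$nsig
    matrix(v[seq_len(nsamp * hdr$nsig)], ncol = hdr$nsig, byrow = TRUE)
  } else {
    stop("unsupported WFDB signal format: ", fmt)
  }
}

# Parse a MIT-format annotation stream into (position, symbol, aux)
read_wfdb_annotations <- function(atr_path) {
  bytes <- as.integer(readBin(atr_path, "raw", n = file.info(atr_path)$size))
  pos <- integer(); sym <- character(); aux <- character()
  t_cur <- 0; i <- 1; n <- length(bytes)
  codes <- wfdb_code_symbol()
  pending_skip <- 0
  while (i + 1 <= n) {
    word <- bytes[i] + bitwShiftL(bytes[i + 1], 8)
    i <- i + 2
    code <- bitwShiftR(word, 10)
    data <- bitwAnd(word, 1023L)
    if (code == 0 && data == 0) break                  # EOF
    if (code == WFDB_SKIP) {
      hi <- bytes[i] + bitwShiftL(bytes[i + 1], 8)
      lo <- bytes[i + 2] + bitwShiftL(bytes[i + 3], 8)
      i <- i + 4
      pending_skip <- pending_skip + hi * 65536 + lo
    } else if (code == WFDB_AUX) {
      s <- rawToChar(as.raw(bytes[i:(i + data - 1)]))
      s <- gsub("[^ -~]", "", s)                       # strip NULs/padding
      i <- i + data + (data %% 2)                      # aux padded to even
      if (length(sym)) aux[length(sym)] <- s
    } else if (code %in% c(WFDB_NUM, WFDB_SUB, WFDB_CHN)) {
      # per-annotation attributes we do not use
    } else {
      t_cur <- t_cur + data + pending_skip
      pending_skip <- 0
      pos <- c(pos, t_cur)
      sym <- c(sym, if (as.character(code) %in% names(codes))
        codes[[as.character(code)]] else sprintf("<%d>", code))
      aux <- c(aux, NA_character_)
    }
  }
  data.frame(position = pos, symbol = sym, aux = aux,
             stringsAsFactors = FALSE)
}

read_wfdb_record <- function(path, lead, beat_vocab, rhythm_vocab) {
  stem <- sub("\\.hea$", "", path)
  hdr <- read_wfdb_header(paste0(stem, ".hea"))
  leads <- vapply(hdr$signals, `[[`, "", "desc")
  k <- match(lead, leads)
  if (is.na(k)) {
    stop("lead not found: record has [", paste(leads, collapse = ", "),
         "], requested '", lead, "'")
  }
  adc <- read_wfdb_signal(stem, hdr)[, k]
  sg <- hdr$signals[[k]]
  samples <- (adc - sg$baseline) / sg$gain
  ann <- read_wfdb_annotations(paste0(stem, ".atr"))
  is_marker <- ann$symbol == "+"
  rhythm_idx <- which(is_marker & !is.na(ann$aux) & startsWith(ann$aux, "("))
  regions <- regions_from_markers(ann$position[rhythm_idx],
                                  sub("^\\(", "", ann$aux[rhythm_idx]),
                                  length(samples))
  regions <- regions[regions$label %in% rhythm_vocab, , drop = FALSE]
  is_beat <- ann$symbol %in% c(beat_vocab, "?")
  beats <- data.frame(position = ann$position[is_beat],
                      label = ann$symbol[is_beat])
  res <- filter_beats(beats, beat_vocab)
  rec <- ecg_record(samples, hdr$fs, hdr$record, lead, res$beats, regions,
                    beat_vocab, rhythm_vocab)
  attr(rec, "dropped_beats") <- res$dropped
  rec
}

write_wfdb_annotations <- function(atr_path, events) {
  # events: data.frame(position, code, aux) sorted by position
  con <- file(atr_path, "wb")
  on.exit(close(con))
  t_prev <- 0
  for (r in seq_len(nrow(events))) {
    delta <- events$position[r] - t_prev
    if (delta > 1023) {
      writeBin(as.integer(bitwShiftL(WFDB_SKIP, 10)), con, size = 2,
               endian = "little")
      writeBin(as.integer(delta %/% 65536), con, size = 2, endian = "little")
      writeBin(as.integer(delta %% 65536), con, size = 2, endian = "little")
      delta <- 0
    }
    writeBin(as.integer(bitwShiftL(events$code[r], 10) + delta), con,
             size = 2, endian = "little")
    t_prev <- events$position[r]
    a <- events$aux[r]
    if (!is.na(a) && nzchar(a)) {
      ab <- charToRaw(a)
      writeBin(as.integer(bitwShiftL(WFDB_AUX, 10) + length(ab)), con,
               size = 2, endian = "little")
      writeBin(ab, con)
      if (length(ab) %% 2 == 1) writeBin(as.raw(0), con)
    }
  }
  writeBin(0L, con, size = 2, endian = "little")       # EOF word
  invisible(atr_path)
}

write_wfdb_record <- function(record, path, gain = 200) {
  stem <- sub("\\.hea$", "", path)
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  base <- basename(stem)
  n <- length(record$samples)
  adc <- round(record$samples * gain)
  writeLines(c(
    sprintf("%s 1 %g %d", base, record$fs, n),
    sprintf("%s.dat 212 %g(0)/mV 12 0 %d 0 0 %s", base, gain, as.integer(adc[1]),
            record$lead_name)
  ), paste0(stem, ".hea"))
  writeBin(encode_fmt212(adc), paste0(stem, ".dat"))
  codes <- wfdb_symbol_code()
  ev <- rbind(
    if (nrow(record$beats)) data.frame(position = record$beats$position,
                                       code = codes[record$beats$label],
                                       aux = NA_character_),
    if (nrow(record$regions)) data.frame(position = record$regions$start,
                                         code = WFDB_RHYTHM_CODE,
                                         aux = paste0("(", record$regions$label))
  )
  if (is.null(ev)) ev <- data.frame(position = integer(), code = integer(),
                                    aux = character())
  ev <- ev[order(ev$position, ev$code != WFDB_RHYTHM_CODE), , drop = FALSE]
  write_wfdb_annotations(paste0(stem, ".atr"), ev)
  invisible(stem)
}
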