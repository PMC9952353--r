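test_that("text dialect round-trips random records exactly", {
  for (seed in 1:25) {
    rec <- rand_record(seed)
    stem <- file.path(withr::local_tempdir(), "rec")
    write_record(rec, stem)
    back <- read_record(stem, format = "text")
    expect_identical(back$beats$position, rec$beats$position)
    expect_identical(back$beats$label, rec$beats$label)
    expect_identical(back$regions, rec$regions)
    expect_equal(back$samples, rec$samples, tolerance = 0)
    expect_identical(back$fs, rec$fs)
    expect_identical(back$record_id, rec$record_id)
  }
})

test_that("rhythm regions reconstructed from markers tile to record end", {
  r1 <- regions_from_markers(0, "AFIB", 3600)
  expect_equal(r1, data.frame(start = 0L, end = 3600L, label = "AFIB"))
  r2 <- regions_from_markers(c(0, 1800), c("N", "AFIB"), 3600)
  expect_equal(r2$start, c(0L, 1800L))
  expect_equal(r2$end, c(1800L, 3600L))
  expect_equal(r2$label, c("N", "AFIB"))
  # property: markers at random positions tile [first, end) without gaps
  set.seed(4)
  for (i in 1:20) {
    pos <- sort(sample(0:5000, sample(1:6, 1)))
    rr <- regions_from_markers(pos, rep("N", length(pos)), 6000)
    expect_equal(rr$start[1], pos[1])
    expect_equal(rr$end[nrow(rr)], 6000L)
    if (nrow(rr) > 1) expect_equal(rr$start[-1], rr$end[-nrow(rr)])
  }
})

test_that("unreadable and out-of-vocabulary beats are dropped, not kept", {
  rec <- rand_record(1)
  dir <- withr::local_tempdir()
  stem <- file.path(dir, "rec")
  write_record(rec, stem)
  # inject a '?' and a bogus symbol into the beats CSV
  beats <- read.csv(paste0(stem, "_beats.csv"))
  beats$label[1] <- "?"
  extra <- data.frame(position = max(beats$position) + 5, label = "Z")
  write.csv(rbind(beats, extra), paste0(stem, "_beats.csv"), row.names = FALSE)
  expect_warning(back <- read_record(stem, format = "text"), "Z")
  expect_equal(attr(back, "dropped_beats"), 2L)
  expect_false("?" %in% back$beats$label)
  expect_true(all(back$beats$label %in% beat_vocabulary()))
})

test_that("format-212 signal bytes decode against hand-packed values", {
  # adc samples packed by hand: s1 low byte; shared byte = high nibbles;
  # s2 low byte; negatives in 12-bit two's complement
  adc <- c(100L, -200L, 300L, 50L, 0L, 2047L, -2048L, 1L)
  u <- ifelse(adc < 0, adc + 4096L, adc)
  bytes <- integer(0)
  for (p in seq(1, 8, by = 2)) {
    s1 <- u[p]; s2 <- u[p + 1]
    bytes <- c(bytes, s1 %% 256, (s1 %/% 256) + 16 * (s2 %/% 256), s2 %% 256)
  }
  dir <- withr::local_tempdir()
  writeLines(c("t1 1 360 8", "t1.dat 212 200(0)/mV 12 0 100 0 0 MLII"),
             file.path(dir, "t1.hea"))
  writeBin(as.raw(bytes), file.path(dir, "t1.dat"))
  writeBin(as.raw(c(0, 0)), file.path(dir, "t1.atr"))   # empty annotations
  rec <- read_record(file.path(dir, "t1"), lead = "MLII")
  expect_equal(rec$samples, adc / 200)
  expect_equal(rec$fs, 360)
})

test_that("MIT annotation words decode against hand-built bytes", {
  # '+' at 0 with aux "(AFIB", then a normal beat at t = 10, then EOF
  word <- function(code, data) c((code * 1024 + data) %% 256,
                                 (code * 1024 + data) %/% 256)
  bytes <- c(word(28, 0),                    # rhythm change marker
             word(63, 5), utf8ToInt("(AFIB"), 0,  # aux, padded to even
             word(1, 10),                    # beat 'N', delta 10
             0, 0)                           # EOF
  dir <- withr::local_tempdir()
  n <- 16
  writeLines(c(sprintf("t2 1 360 %d", n), "t2.dat 212 200(0)/mV 12 0 0 0 0 MLII"),
             file.path(dir, "t2.hea"))
  writeBin(as.raw(rep(0, 24)), file.path(dir, "t2.dat"))
  writeBin(as.raw(bytes), file.path(dir, "t2.atr"))
  rec <- read_record(file.path(dir, "t2"), lead = "MLII")
  expect_equal(rec$regions,
               data.frame(start = 0L, end = 16L, label = "AFIB"))
  expect_equal(rec$beats, data.frame(position = 10, label = "N"))
})

test_that("WFDB write/read round-trips beats, regions, and quantized signal", {
  for (seed in c(3, 8)) {
    rec <- rand_record(seed, n = 4000)
    stem <- file.path(withr::local_tempdir(), "w1")
    write_record(rec, stem, format = "wfdb")
    back <- read_record(stem, lead = "MLII")
    expect_equal(back$beats$position, rec$beats$position)
    expect_equal(back$beats$label, rec$beats$label)
    expect_equal(back$regions$start, rec$regions$start)
    expect_equal(back$regions$label, rec$regions$label)
    expect_lt(max(abs(back$samples - rec$samples)), 1 / 200 / 2 + 1e-9)
  }
})

test_that("requesting a missing lead fails with the available leads named", {
  rec <- rand_record(2)
  stem <- file.path(withr::local_tempdir(), "rec")
  write_record(rec, stem)
  expect_error(read_record(stem, lead = "V5", format = "text"), "lead")
})

test_that("record constructor enforces invariants", {
  expect_error(ecg_record(numeric(0), 360), "length")
  expect_error(ecg_record(1:10, 360,
                          beats = data.frame(position = c(5, 5),
                                             label = c("N", "N"))),
               "increasing")
  expect_error(ecg_record(1:10, 360,
                          beats = data.frame(position = 3, label = "ZZ")),
               "vocabulary")
  expect_error(ecg_record(1:10, 360,
                          regions = data.frame(start = c(0, 4), end = c(6, 8),
                                               label = c("N", "AFIB"))),
               "overlap")
})
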