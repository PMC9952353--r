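test_that("interval padding places score vectors exactly at R positions", {
  w0 <- make_window(integer(0), character(0))
  b0 <- build_bsm(w0, NULL)
  expect_equal(dim(b0), c(3600, 15))
  expect_true(all(b0 == 0))
  w1 <- make_window(1800, "N")
  sv <- matrix(as.numeric(beat_vocabulary() == "N"), 1)
  b1 <- build_bsm(w1, sv)
  expect_equal(sum(b1 != 0), 1)
  expect_equal(b1[1801, which(beat_vocabulary() == "N")], 1)
  # 12 beats: nonzero rows reproduce the R-R intervals exactly
  set.seed(8)
  pos <- sort(sample(0:3599, 12))
  w12 <- make_window(pos, rep("N", 12))
  sc <- matrix(runif(12 * 15), 12)
  sc <- sc / rowSums(sc)
  b12 <- build_bsm(w12, sc)
  nz <- which(rowSums(unclass(b12)) > 0) - 1L
  expect_equal(nz, pos)
  expect_equal(diff(nz), diff(pos))
  expect_error(build_bsm(w1, rbind(sv, sv)), "score vectors")
  expect_error(build_bsm(make_window(3600, "N"), sv), "position")
})

test_that("time reduction equals the brute-force block max oracle", {
  set.seed(21)
  for (i in 1:10) {
    m <- matrix(0, 3600, 15)
    n_beats <- sample(1:25, 1)
    m[sample(3600, n_beats), ] <- matrix(runif(n_beats * 15), n_beats)
    bsm <- bsmecg:::new_bsm(m, "raw", beat_vocabulary())
    red <- reduce_time(bsm, 10)
    expect_equal(unclass(red), brute_block_max(m, 10), ignore_attr = TRUE)
  }
  # dense random matrix too (not just sparse BSM structure)
  m <- matrix(runif(600 * 15), 600)
  bsm <- bsmecg:::new_bsm(m, "raw", beat_vocabulary())
  expect_equal(unclass(reduce_time(bsm, 10)), brute_block_max(m, 10),
               ignore_attr = TRUE)
})

test_that("beats sharing a block merge to the elementwise max", {
  w <- make_window(c(100, 105), c("N", "V"))
  sc <- rbind(runif(15), runif(15))
  sc <- sc / rowSums(sc)
  red <- reduce_time(build_bsm(w, sc), 10)
  expect_equal(dim(red), c(360, 15))
  nz <- which(rowSums(unclass(red)) > 0)
  expect_equal(nz, 11L)                                 # block [100, 110)
  expect_equal(unclass(red)[11, ], pmax(sc[1, ], sc[2, ]))
})

test_that("single beat survives reduction with values unchanged", {
  w <- make_window(1805, "V")
  sv <- matrix(runif(15), 1); sv <- sv / sum(sv)
  red <- reduce_time(build_bsm(w, sv))
  expect_equal(which(rowSums(unclass(red)) > 0), 181L)
  expect_equal(unclass(red)[181, ], sv[1, ])
})

test_that("resize replicates each class column ten times", {
  w <- make_window(c(500, 2000), c("N", "V"))
  sv <- diag(15)[match(c("N", "V"), beat_vocabulary()), ]
  red <- reduce_time(build_bsm(w, sv))
  rs <- resize_image(red)
  expect_equal(dim(rs), c(360, 150))
  expect_setequal(unique(as.vector(unclass(rs))), unique(as.vector(unclass(red))))
  iN <- which(beat_vocabulary() == "N")
  expect_true(all(unclass(rs)[51, ((iN - 1) * 10 + 1):(iN * 10)] == 1))
  z <- resize_image(reduce_time(build_bsm(make_window(integer(0), character(0)),
                                          NULL)))
  expect_true(all(z == 0))
})

test_that("stage tracking forbids reprocessing", {
  w <- make_window(100, "N")
  sv <- matrix(runif(15), 1); sv <- sv / sum(sv)
  raw <- build_bsm(w, sv)
  red <- reduce_time(raw)
  rs <- resize_image(red)
  expect_error(reduce_time(red), "raw")
  expect_error(resize_image(rs), "reduced")
  expect_error(resize_image(raw), "reduced")
})

test_that("R-R intervals are recoverable from the reduced matrix", {
  set.seed(77)
  for (i in 1:200) {
    n_beats <- sample(4:14, 1)
    pos <- sort(sample(0:3599, n_beats))
    blocks <- pos %/% 10
    if (any(duplicated(blocks))) next                  # merged-block case excluded
    w <- make_window(pos, sample(beat_vocabulary(), n_beats, replace = TRUE))
    sc <- matrix(runif(n_beats * 15) + 0.01, n_beats)
    sc <- sc / rowSums(sc)
    red <- reduce_time(build_bsm(w, sc))
    nz <- which(rowSums(unclass(red)) > 0) - 1L
    expect_equal(length(nz), n_beats)                  # conservation
    expect_true(all(abs(nz * 10 - pos) < 10))          # within one block
    expect_true(all(abs(diff(nz * 10) - diff(pos)) < 10))
  }
})

test_that("window_to_bsm composes the per-stage operations (oracle scores)", {
  rec <- generate_record(list(list(spec = default_rhythm_specs()$B,
                                   duration_s = 14)), seed = 44)
  rec <- denoise_record(rec)
  w <- slide_windows(rec)[[1]]
  img <- window_to_bsm(rec, w, oracle_beat_model())
  expect_equal(dim(img), c(360, 150))
  expect_equal(attr(img, "stage"), "resized")
  nz_rows <- which(rowSums(unclass(img)) > 0) - 1L
  expect_equal(nz_rows, w$beats$position %/% 10)
  for (b in seq_len(nrow(w$beats))) {
    band <- (match(w$beats$label[b], beat_vocabulary()) - 1) * 10 + 1:10
    expect_true(all(unclass(img)[nz_rows[b] + 1, band] == 1))
  }
  img2 <- window_to_bsm(rec, w, oracle_beat_model())
  expect_identical(img, img2)
})

test_that("16-bit PNG persistence round-trips BSM values", {
  w <- make_window(sort(sample(0:3599, 7)), sample(beat_vocabulary(), 7,
                                                   replace = TRUE))
  sc <- matrix(runif(7 * 15), 7); sc <- sc / rowSums(sc)
  img <- resize_image(reduce_time(build_bsm(w, sc)))
  path <- file.path(withr::local_tempdir(), "b.png")
  write_bsm_png(img, path, label = "N", source = "w@0")
  back <- read_bsm_png(path)
  expect_equal(dim(back), dim(img))
  expect_lt(max(abs(unclass(back) - unclass(img))), 1 / 65535)
  expect_equal(attr(back, "label"), "N")
  expect_equal(attr(back, "stage"), "resized")
  expect_equal(attr(back, "vocab"), beat_vocabulary())
})
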