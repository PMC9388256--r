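test_that("a written record reads back within one ADC step", {
  dir <- withr::local_tempdir()
  set.seed(1)
  ann <- tibble::tibble(sample = c(120L, 500L, 2000L, 3500L),
                        symbol = c("N", "V", "A", "/"))
  rec <- ecg_record("t01", 360, sin(seq(0, 40, length.out = 4000)) +
                      rnorm(4000, 0, 0.05), annotations = ann)
  write_record(rec, dir, gain = 200)
  back <- read_record(file.path(dir, "t01"))
  expect_equal(back$fs, 360)
  expect_equal(back$record_id, "t01")
  expect_lte(max(abs(back$signal - rec$signal)), 1 / (2 * 200) + 1e-12)
  expect_equal(back$annotations, ann)
})

test_that("annotation gaps beyond the 10-bit delta survive a round trip", {
  dir <- withr::local_tempdir()
  ann <- tibble::tibble(sample = c(50L, 2000L, 90000L),
                        symbol = c("N", "F", "E"))
  rec <- ecg_record("gap", 360, rnorm(100000), annotations = ann)
  write_record(rec, dir)
  expect_equal(read_record(file.path(dir, "gap"))$annotations, ann)
})

test_that("truncated signal files and bad channels raise clear errors", {
  dir <- withr::local_tempdir()
  rec <- ecg_record("t02", 360, rnorm(1000))
  base <- write_record(rec, dir)
  # truncate the .dat file
  dat <- paste0(base, ".dat")
  raw <- readBin(dat, "raw", file.info(dat)$size)
  writeBin(raw[1:100], dat)
  expect_error(read_record(base), "truncated")
  expect_error(read_record(file.path(dir, "nope")), "not found")
  rec2 <- ecg_record("t03", 360, rnorm(1000))
  base2 <- write_record(rec2, dir)
  expect_error(read_record(base2, channel = 2), "out of range")
})

test_that("format 212 packing decodes both samples of each byte triplet", {
  dir <- withr::local_tempdir()
  # hand-build a two-channel 212 record with known ADC values
  adc1 <- c(10L, -10L, 100L, -2048L, 2047L, 0L)
  adc2 <- c(5L, 7L, -100L, 300L, -300L, 1L)
  n <- length(adc1)
  writeLines(c(sprintf("p212 2 360 %d", n),
               "p212.dat 212 200 12 0 10 0 0 ch1",
               "p212.dat 212 200 12 0 5 0 0 ch2"),
             file.path(dir, "p212.hea"))
  to12 <- function(v) ifelse(v < 0, v + 4096L, v)
  bytes <- raw(0)
  for (i in seq_len(n)) {
    s1 <- to12(adc1[i]); s2 <- to12(adc2[i])
    bytes <- c(bytes, as.raw(c(s1 %% 256,
                               (s1 %/% 256) + 16 * (s2 %/% 256),
                               s2 %% 256)))
  }
  writeBin(bytes, file.path(dir, "p212.dat"))
  r1 <- read_record(file.path(dir, "p212"), channel = 1)
  r2 <- read_record(file.path(dir, "p212"), channel = 2)
  expect_equal(r1$signal * 200, adc1)
  expect_equal(r2$signal * 200, adc2)
})

test_that("beat CSV persistence is lossless and validates labels", {
  f <- withr::local_tempfile(fileext = ".csv")
  beats <- synth_beats(c(N = 2, V = 1), seed = 3)
  write_beats(beats, f)
  back <- read_beats(f)
  expect_equal(as.data.frame(back), as.data.frame(beats), tolerance = 1e-12)

  # corrupt one label -> error naming the row
  lines <- readLines(f)
  lines[3] <- sub("^synth,NA,N", "synth,NA,X", lines[3])
  writeLines(lines, f)
  expect_error(read_beats(f), "row 2")

  # empty dataset: header-only file reads back empty
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_beats(beats[0, ], f2)
  expect_equal(nrow(read_beats(f2)), 0L)
})
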