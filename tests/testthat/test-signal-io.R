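test_that("unit conversion divides by standard gravity and round-trips", {
  expect_equal(convert_to_g(0), 0)
  expect_equal(convert_to_g(9.81), 1)
  expect_equal(round(convert_to_g(-100), 2), -10.19)
  x <- c(-250, -1.3, 0, 0.02, 97)
  expect_equal(convert_to_g(x) * 9.81, x, tolerance = 1e-12)
})

test_that("read_recording parses the CSV dialect and converts units", {
  f <- withr::local_tempfile(fileext = ".csv")
  acc <- matrix(0, 3, 3); acc[, 1] <- 9.81
  write_sensor_csv(f, n = 3, acc = acc)
  rec <- read_recording(f, unit_hint = "m_s2")
  expect_s3_class(rec, "sensor_recording")
  expect_equal(rec$acc[, 1], rep(1, 3))
  expect_equal(nrow(rec$acc), 3L)

  acc2 <- matrix(0, 5, 3); acc2[3, 2] <- -100
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_sensor_csv(f2, n = 5, acc = acc2)
  rec2 <- read_recording(f2, unit_hint = "m_s2")
  expect_equal(round(min(rec2$acc[, 2]), 2), -10.19)
})

test_that("read_recording reports format and integrity violations", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_sensor_csv(f, n = 4, drop_col = "Gyr_Z")
  expect_error(read_recording(f), class = "strokesense_format_error",
               regexp = "Gyr_Z")

  f2 <- withr::local_tempfile(fileext = ".csv")
  write_sensor_csv(f2, n = 4, timestamps = c(0, 2, 1, 3) / 60)
  expect_error(read_recording(f2), class = "strokesense_integrity_error")
})

test_that("pairing matches sens1/sens2 per recording and partitions inputs", {
  res <- pair_recordings(c("P07_forehand_sens1.csv", "P07_forehand_sens2.csv"))
  expect_equal(nrow(res$pairs), 1L)
  expect_equal(res$pairs$participant_id, "07")
  expect_equal(nrow(res$unpaired), 0L)

  res1 <- pair_recordings("P07_forehand_sens1.csv")
  expect_equal(nrow(res1$pairs), 0L)
  expect_equal(nrow(res1$unpaired), 1L)

  # 39 participants x 2 files -> 39 pairs; partition property holds
  files <- as.vector(vapply(sprintf("P%02d", 1:39), function(p) {
    paste0(p, "_service_sens", 1:2, ".csv")
  }, character(2)))
  files <- c(files, "oddball.txt")
  res39 <- pair_recordings(files)
  expect_equal(nrow(res39$pairs), 39L)
  expect_equal(nrow(res39$unpaired), 1L)
  expect_equal(2L * nrow(res39$pairs) + nrow(res39$unpaired), length(files))

  expect_error(
    pair_recordings(c("a/P01_fh_sens1.csv", "b/P01_fh_sens1.csv",
                      "P01_fh_sens2.csv")),
    class = "strokesense_ambiguity_error")
})

test_that("synchronize aligns by nearest timestamp over the overlap", {
  t_len <- 120L
  ts <- (seq_len(t_len) - 1) / 60
  mk <- function(role, ts) sensor_recording("P01", role, ts,
                                            matrix(rnorm(3 * length(ts)), ncol = 3),
                                            matrix(0, length(ts), 3))
  set.seed(1)
  a <- mk("dominant", ts); b <- mk("non_dominant", ts)
  expect_equal(nrow(synchronize(a, b)$data), t_len)

  b10 <- mk("non_dominant", ts + 10 / 60)   # shifted by exactly 10 samples
  expect_equal(nrow(synchronize(a, b10)$data), t_len - 10L)
  # overlap length is symmetric in the argument order
  expect_equal(nrow(synchronize(b10, a)$data), t_len - 10L)

  b_far <- mk("non_dominant", ts + 10)      # disjoint time ranges
  expect_error(synchronize(a, b_far), class = "strokesense_sync_error")
  expect_error(synchronize(a, mk("dominant", ts)),
               class = "strokesense_sync_error")
})

test_that("synchronized data keeps the dominant wrist in columns 1-6", {
  ts <- (0:49) / 60
  acc_d <- matrix(5, 50, 3); acc_n <- matrix(1, 50, 3)
  a <- sensor_recording("P01", "non_dominant", ts, acc_n, matrix(0, 50, 3))
  b <- sensor_recording("P01", "dominant", ts, acc_d, matrix(0, 50, 3))
  bil <- synchronize(a, b)   # argument order must not matter
  expect_equal(unname(bil$data[1, 1]), 5)
  expect_equal(unname(bil$data[1, 7]), 1)
})

test_that("tensor containers round-trip bit-identically", {
  tensor <- toy_tensor(5)
  f <- withr::local_tempfile(fileext = ".rds")
  save_tensor(tensor, f)
  back <- load_tensor(f)
  expect_identical(back$windows, tensor$windows)
  expect_identical(back$meta, tensor$meta)

  empty <- assemble_tensor(list())
  f2 <- withr::local_tempfile(fileext = ".rds")
  save_tensor(empty, f2)
  expect_equal(dim(load_tensor(f2)$windows), c(0L, 100L, 12L, 1L))

  f3 <- withr::local_tempfile(fileext = ".rds")
  writeLines("not a tensor", f3)
  expect_error(load_tensor(f3), class = "strokesense_io_error")
})

test_that("channel layout is a bijection over the 12 channels", {
  cl <- channel_layout()
  expect_equal(nrow(cl), 12L)
  expect_equal(anyDuplicated(cl$channel), 0L)
  expect_equal(anyDuplicated(cl[, c("wrist", "modality", "axis")]), 0L)
})
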