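# Oracle for the calibration: the affine map evaluated directly, frozen for
# the headline case: digital range [-32768, 32767], physical range
# [-1000, 1000] µV, d = 0 gives -1000 + 32768 * 2000 / 65535 =
# 0.015259021896667946 µV.

test_that("digital/physical calibration matches the affine oracle", {
  expect_equal(digital_to_physical(-32768, -1000, 1000), -1000)  # boundary
  expect_equal(digital_to_physical(32767, -1000, 1000), 1000)    # boundary
  expect_equal(digital_to_physical(0, -1000, 1000), 0.015259021896667946)
  # inverse: rounds to nearest and clamps
  expect_equal(physical_to_digital(-1000, -1000, 1000), -32768)
  expect_equal(physical_to_digital(1000, -1000, 1000), 32767)
  expect_equal(physical_to_digital(2000, -1000, 1000), 32767)    # clamped
  expect_equal(physical_to_digital(-2000, -1000, 1000), -32768)  # clamped
  # round trip within one quantization step
  step <- 2000 / 65535
  d <- c(-32768L, -1L, 0L, 1L, 12345L, 32767L)
  p <- digital_to_physical(d, -1000, 1000)
  expect_identical(physical_to_digital(p, -1000, 1000), as.numeric(d))
  expect_error(digital_to_physical(0, 5, 5), class = "eegbids_invariant_error")
})

test_that("EDF header arithmetic and payload width are exact", {
  r <- make_recording(n_channels = 4, sfreq = 256, duration_s = 10,
                      noise_sd_uv = 2, seed = 11)
  f <- tempfile(fileext = ".edf")
  on.exit(unlink(f))
  h <- write_edf(r, f)
  expect_equal(h$header_bytes, 1280)  # 256 * (4 + 1)
  expect_equal(h$n_records, 10)
  expect_equal(h$samples_per_record, 256)
  # payload is exactly 16 bits per sample
  bits <- 8 * (file.size(f) - h$header_bytes) /
    (4 * h$n_records * h$samples_per_record)
  expect_identical(bits, 16)
  # file size identity
  expect_equal(file.size(f),
               h$header_bytes + h$n_records * 4 * h$samples_per_record * 2)
})

test_that("EDF write/read round trip stays within one quantization step", {
  for (seed in 1:10) {
    set.seed(seed)
    r <- make_recording(n_channels = sample(1:8, 1),
                        sfreq = sample(c(100, 250, 500), 1),
                        duration_s = stats::runif(1, 0.5, 3),
                        noise_sd_uv = stats::runif(1, 0, 20),
                        seed = seed)
    f <- tempfile(fileext = ".edf")
    h <- write_edf(r, f)
    r2 <- read_edf(f)
    expect_identical(r2$channel_names, r$channel_names)
    expect_equal(r2$sfreq, r$sfreq)
    n <- ncol(r$data)
    step <- (h$physical_max - h$physical_min) / 65535
    err <- apply(abs(r$data - r2$data[, seq_len(n), drop = FALSE]), 1, max)
    expect_true(all(err <= step), label = sprintf("seed %d round-trip bound", seed))
    unlink(f)
  }
})

test_that("a constant-zero channel maps back to zero within one step", {
  r <- new_recording(matrix(0, 1, 500), 100)
  f <- tempfile(fileext = ".edf")
  on.exit(unlink(f))
  write_edf(r, f)
  r2 <- read_edf(f)
  expect_true(max(abs(r2$data)) <= 2 / 65535)  # all-zero range is [-1, 1]
})

test_that("written EDF headers are printable ASCII and re-read verbatim", {
  r <- make_recording(n_channels = 3, seed = 5)
  f <- tempfile(fileext = ".edf")
  on.exit(unlink(f))
  write_edf(r, f)
  hdr_bytes <- readBin(f, "raw", 256 * 4)
  expect_true(all(hdr_bytes >= as.raw(0x20) & hdr_bytes <= as.raw(0x7e)))
  h <- read_edf_header(f)
  expect_equal(h$version, "0")
  expect_equal(h$start_date, "01.01.00")
  expect_equal(h$start_time, "00.00.00")
  expect_equal(h$label, r$channel_names)
  expect_equal(h$digital_min, rep(-32768, 3))
  expect_equal(h$digital_max, rep(32767, 3))
  # second write of the same recording is byte-identical (no wall clock)
  f2 <- tempfile(fileext = ".edf")
  on.exit(unlink(f2), add = TRUE)
  write_edf(r, f2)
  expect_identical(readBin(f, "raw", file.size(f)), readBin(f2, "raw", file.size(f2)))
})

test_that("partial final records are padded and the count rounded up", {
  # 2.5 s at 100 Hz with 1 s records -> 3 records, padded with last value
  r <- new_recording(matrix(seq_len(250) / 10, 1, 250), 100)
  f <- tempfile(fileext = ".edf")
  on.exit(unlink(f))
  h <- write_edf(r, f)
  expect_equal(h$n_records, 3)
  r2 <- read_edf(f)
  expect_equal(ncol(r2$data), 300)
  step <- 2 * h$physical_max[1] / 65535
  expect_true(all(abs(r2$data[1, 251:300] - 25) <= step))
})

test_that("malformed EDF files raise format errors naming the problem", {
  r <- make_recording(n_channels = 2, seed = 3)
  f <- tempfile(fileext = ".edf")
  on.exit(unlink(f))
  write_edf(r, f)
  # truncate mid-record
  full <- readBin(f, "raw", file.size(f))
  writeBin(full[seq_len(length(full) - 101)], f)
  err <- tryCatch(read_edf(f), error = function(e) e)
  expect_s3_class(err, "eegbids_format_error")
  expect_match(conditionMessage(err), "offset")
  # bad version field
  full[1] <- charToRaw("9")
  writeBin(full, f)
  expect_error(read_edf(f), class = "eegbids_format_error")
  # header_bytes inconsistent with n_signals
  full[1] <- charToRaw("0")
  full[185:192] <- charToRaw(sprintf("%-8d", 9999))
  writeBin(full, f)
  expect_error(read_edf(f), class = "eegbids_format_error")
})

test_that("non-integer sampling frequencies pick an integral record duration", {
  r <- new_recording(matrix(rnorm(256), 1, 256), 102.4)  # 102.4 * 5 = 512
  f <- tempfile(fileext = ".edf")
  on.exit(unlink(f))
  h <- write_edf(r, f)
  expect_equal(h$record_duration, 5)
  expect_equal(h$samples_per_record, 512)
  expect_equal(read_edf(f)$sfreq, 102.4)
})
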