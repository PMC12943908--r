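test_that("imu_sequence enforces its invariants", {
  s <- imu_sequence(ax = 1:3, ay = 4:6, az = 7:9)
  expect_s3_class(s, "imu_sequence")
  expect_length(s, 3L)
  expect_equal(s$timestamps, c(0, 0.02, 0.04))
  expect_error(imu_sequence(numeric(0), numeric(0), numeric(0)),
               "empty sequence")
  expect_error(imu_sequence(1:3, 1:2, 1:3), "length mismatch")
  expect_error(imu_sequence(1:3, 1:3, 1:3, dt = 0), "dt must be")
  expect_error(imu_sequence(1:3, 1:3, 1:3, timestamps = c(0, 0.04, 0.08)),
               "sampling-interval mismatch")
})

test_that("read_imu_csv parses valid files and reports bad cells", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,ax,ay,az", "0,0.1,0.2,9.8", "0.02,0.2,0.3,9.7",
               "0.04,0.1,0.2,9.9"), f)
  s <- read_imu_csv(f)
  expect_length(s, 3L)
  expect_equal(s$az, c(9.8, 9.7, 9.9))

  # unit conversion at read time
  sg <- read_imu_csv(f, scale = 9.81)
  expect_equal(sg$az, c(9.8, 9.7, 9.9) * 9.81)

  writeLines("time,ax,ay,az", f)
  expect_error(read_imu_csv(f), "empty sequence")

  writeLines(c("time,ax,ay,az", "0,0.1,0.2,9.8", "0.02,oops,0.3,9.7"), f)
  expect_error(read_imu_csv(f), "non-numeric cell.*row 2")

  writeLines(c("time,ax,ay,az", "0,1,2,3", "0.04,1,2,3"), f)
  expect_error(read_imu_csv(f), "sampling-interval mismatch")

  writeLines(c("time,ax,ay", "0,1,2"), f)
  expect_error(read_imu_csv(f), "missing column")
  expect_error(read_imu_csv(file.path(tempdir(), "nope.csv")),
               "missing file")
})

test_that("stride-event files are validated on read", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0", "120", "245"), f)
  ev <- read_stride_events(f, n_samples = 300)
  expect_equal(ev$indices, c(0L, 120L, 245L))

  writeLines(c("0", "300"), f)
  expect_error(read_stride_events(f, n_samples = 300), "out of range")

  writeLines("50", f)
  expect_error(read_stride_events(f, n_samples = 300), "fewer than 2")

  writeLines(c("10", "10", "20"), f)
  expect_error(read_stride_events(f, n_samples = 300), "non-monotone")

  writeLines(c("1", "121", "246"), f)
  ev1 <- read_stride_events(f, n_samples = 300, one_based = TRUE)
  expect_equal(ev1$indices, c(0L, 120L, 245L))
})

test_that("segment_strides tiles the record half-open", {
  x <- seq_len(300)
  ev <- stride_events(c(0, 120, 245), 300)
  segs <- segment_strides(x, ev)
  expect_length(segs, 2L)
  expect_equal(vapply(segs, function(s) length(s$samples), 1L), c(120L, 125L))
  # concatenation reproduces the slice between first and last event
  expect_equal(unlist(lapply(segs, `[[`, "samples")), x[1:245])
  expect_equal(sum(vapply(segs, function(s) s$end - s$start, 1L)), 245L)

  expect_error(segment_strides(x, stride_events(c(0, 2), 300)),
               "shorter than 3")
  one <- segment_strides(x, stride_events(c(0, 299), 300))
  expect_length(one, 1L)
  expect_equal(one[[1L]]$samples, x[1:299])
})

test_that("estimate tables round-trip through CSV exactly", {
  est <- stride_estimates(c(1.23456789012345, 0.987654321),
                          reference_length = c(1.2, NA))
  expect_equal(est$error_percent[1L],
               abs(1.2 - 1.23456789012345) / 1.2 * 100)
  expect_true(is.na(est$error_percent[2L]))
  f <- withr::local_tempfile(fileext = ".csv")
  write_estimates(est, f)
  back <- read_estimates(f)
  expect_equal(back, est, tolerance = 1e-12)
  expect_error(stride_estimates(c(-0.1)), "non-negative")
})
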