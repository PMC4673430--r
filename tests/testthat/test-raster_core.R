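test_that("event-list construction places events and nothing else", {
  r <- raster_from_events(rbind(c(0, 3), c(0, 7), c(1, 3)), 2, 10)
  expect_equal(r$events[1, 4], 1L)
  expect_equal(r$events[1, 8], 1L)
  expect_equal(r$events[2, 4], 1L)
  expect_equal(sum(r$events), 3L)
})

test_that("empty event list with declared shape loads as all zeros", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("channel,time_ms", f)
  r <- load_raster(f, "event_list", n_channels = 2, duration_ms = 100)
  expect_equal(dim(r$events), c(2L, 100L))
  expect_equal(sum(r$events), 0L)
})

test_that("save/load round trip is bit-exact for both dialects", {
  set.seed(42)
  m <- matrix(rbinom(59 * 1000, 1, 0.02), 59, 1000)
  r <- mua_raster(m, paste0("ch", 1:59))
  for (fmt in c("event_list", "dense")) {
    f <- withr::local_tempfile(fileext = ".csv")
    save_raster(r, f, fmt)
    r2 <- load_raster(f, fmt,
                      n_channels = if (fmt == "event_list") 59 else NULL,
                      duration_ms = if (fmt == "event_list") 1000 else NULL)
    expect_identical(unname(r2$events), unname(r$events), label = fmt)
  }
  # dense also preserves channel ids
  f <- withr::local_tempfile(fileext = ".csv")
  save_raster(r, f, "dense")
  expect_identical(load_raster(f, "dense")$channel_ids, r$channel_ids)
})

test_that("malformed and duplicate event lists are reported", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("channel,time_ms", "0,1", "oops"), f)
  expect_error(load_raster(f, "event_list"), "line 3")
  writeLines(c("channel,time_ms", "0,5", "0,5"), f)
  expect_warning(r <- load_raster(f, "event_list"), "duplicate")
  expect_equal(sum(r$events), 1L)
})

test_that("high-pass filter removes DC and matches the analytic Butterworth response", {
  fs <- 1000
  t <- seq_len(2000)
  rec_const <- voltage_recording(matrix(10, 1, 2000), sampling_rate_hz = fs)
  out <- highpass_filter(rec_const)
  expect_lt(max(abs(out$signal[1, 500:2000])), 1e-6)

  for (f_hz in c(5, 400)) {
    x <- sin(2 * pi * f_hz * t / fs)
    rec <- voltage_recording(matrix(x, 1), sampling_rate_hz = fs)
    y <- highpass_filter(rec, zero_phase = TRUE)$signal[1, ]
    gain <- steady_rms(y, 500) / steady_rms(x, 500)
    if (f_hz == 5) {
      # analytic oracle: |H(5)| = 1/sqrt(1+(200/5)^4), far below 1/60
      expect_lt(butter_hp_gain(5, 200), 1 / 60)
      expect_lt(gain, 1 / 60)
    } else {
      # 400 Hz is in the passband: within 3 dB of unity
      expect_gt(butter_hp_gain(400, 200), 10^(-3 / 20))
      expect_gt(gain, 10^(-3 / 20))
    }
  }
  expect_error(highpass_filter(rec_const, cutoff_hz = 600), "Nyquist")
})

test_that("MUA detection finds negative deflections and is one-sided", {
  expect_equal(sum(detect_mua(
    voltage_recording(matrix(0, 3, 500)))$events), 0L)

  set.seed(7)
  x <- rnorm(100000, sd = 5)
  pos <- seq(100, 99900, by = 200)   # 500 spikes, well separated
  spikes <- pos[1:50]
  x[spikes] <- x[spikes] - 60
  rec <- voltage_recording(matrix(x, 1))
  r <- detect_mua(rec, k = 5)
  expect_true(all(r$events[1, spikes] == 1L))
  # false positives bounded by the Gaussian tail beyond theta ~ -25 uV:
  # expected n * pnorm(-5) ~ 0.03 events
  expect_lte(sum(r$events) - 50, 2)

  x_pos <- abs(rnorm(10000, sd = 5))
  x_pos[seq(100, 9900, 200)] <- 60    # only positive deflections
  r_pos <- detect_mua(voltage_recording(matrix(x_pos, 1)), k = 5)
  expect_equal(sum(r_pos$events), 0L)
})

test_that("MUA event count is non-increasing in the threshold multiplier k", {
  set.seed(1)
  rec <- voltage_recording(matrix(rnorm(2 * 20000, sd = 5), 2))
  counts <- vapply(c(2, 3, 4, 5, 6),
                   function(k) sum(detect_mua(rec, k = k)$events), 1)
  expect_true(all(diff(counts) <= 0))
})

test_that("dead time suppresses crossings that follow an accepted event", {
  set.seed(9)
  x <- rnorm(1000, sd = 2)
  x[c(10, 11, 12, 500)] <- -100
  rec <- voltage_recording(matrix(x, 1))
  r <- detect_mua(rec, k = 5, dead_time_ms = 2)
  expect_equal(which(r$events[1, ] == 1L), c(10, 500))
  r0 <- detect_mua(rec, k = 5, dead_time_ms = 0)
  expect_equal(which(r0$events[1, ] == 1L), c(10, 11, 12, 500))
})

test_that("channel QC removes low-count channels and rate outliers", {
  # one channel with a single event
  m <- matrix(0L, 3, 1000)
  m[1, 1] <- 1L                       # 1 event -> removed
  m[2, c(1, 500)] <- 1L
  m[3, seq(1, 1000, 10)] <- 1L
  qc <- qc_channels(mua_raster(m))
  expect_equal(qc$report$removed_low_count, "0")
  expect_true("1" %in% qc$report$kept)

  # identical rates: SD = 0, nothing removed by the rate rule
  m2 <- matrix(0L, 10, 1000)
  m2[, seq(1, 1000, 100)] <- 1L
  qc2 <- qc_channels(mua_raster(m2))
  expect_length(qc2$report$removed_rate_outlier, 0)

  # 40 channels at 1 Hz plus one at 10 Hz: the outlier sits at
  # (10 - 50/41) / sd = 6.25 sample SDs above the mean (hand-computed),
  # beyond the 5 SD cut
  m3 <- matrix(0L, 41, 10000)
  m3[1:40, seq(1, 10000, 1000)] <- 1L          # 1 Hz
  m3[41, seq(1, 10000, 100)] <- 1L             # 10 Hz
  rates <- rowSums(m3) / 10
  z <- (rates[41] - mean(rates)) / sd(rates)
  expect_equal(round(z, 2), 6.25)
  qc3 <- qc_channels(mua_raster(m3))
  expect_equal(qc3$report$removed_rate_outlier, "40")
  expect_length(qc3$report$kept, 40)

  expect_error(qc_channels(mua_raster(matrix(0L, 2, 100))), "unusable")
})

test_that("binning marks presence, drops partial bins, and B=1 is identity", {
  r <- raster_from_events(rbind(c(0, 3), c(0, 7)), 1, 10)
  z <- bin_raster(r, 10)
  expect_equal(ncol(z$presence), 1L)
  expect_equal(z$presence[1, 1], 1L)            # presence, not a count

  r0 <- mua_raster(matrix(0L, 3, 100))
  expect_equal(sum(bin_raster(r0, 10)$presence), 0L)

  ev <- cbind(0, seq(0, 1190, 10))              # one event per 10 ms bin
  r1 <- raster_from_events(ev, 1, 1200)
  expect_equal(sum(bin_raster(r1, 10)$presence), 120L)

  set.seed(3)
  m <- matrix(rbinom(5 * 97, 1, 0.2), 5, 97)
  r2 <- mua_raster(m)
  expect_identical(bin_raster(r2, 1)$presence, r2$events)
  expect_equal(ncol(bin_raster(r2, 10)$presence), 9L)  # trailing bin dropped
  expect_error(bin_raster(r2, 98), "exceeds")
})

test_that("downsampling reduces the rate by the declared factor", {
  rec <- voltage_recording(matrix(seq_len(25), 1), sampling_rate_hz = 5000)
  d <- downsample_recording(rec, 5)
  expect_equal(d$sampling_rate_hz, 1000)
  expect_equal(d$signal[1, ], c(1, 6, 11, 16, 21))
})
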