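test_that("256 to 90 Hz resampling gives the expected length and N = 5400", {
  rec <- make_recording(256 * 60, "O1", rate = 256)
  out <- resample_recording(rec, 90)
  expect_equal(nrow(out), 5400L)
  expect_equal(sampling_rate(out), 90)
  expect_error(resample_recording(out, 256), "upsampling|below")
})

test_that("resampling preserves DC and is phase-accurate on a sinusoid", {
  rec <- eeg_recording(matrix(3.7, 2560, 1), 256, "O1")
  out <- resample_recording(rec, 90)
  expect_lt(max(abs(unclass(out) - 3.7)), 1e-3)

  t_in <- (0:(256 * 60 - 1)) / 256
  rec2 <- eeg_recording(cbind(sin(2 * pi * 5 * t_in)), 256, "O1")
  out2 <- resample_recording(rec2, 90)
  # sample-wise agreement with the ideal resampled sinusoid (zero phase)
  t_out <- (0:(nrow(out2) - 1)) / 90
  expect_lt(max(abs(unclass(out2)[, 1] - sin(2 * pi * 5 * t_out))), 1e-3)
  # periodogram peak at 5 +/- 0.2 Hz
  n <- nrow(out2)
  pg <- Mod(stats::fft(unclass(out2)[, 1]))^2
  f <- (0:(n - 1)) * 90 / n
  peak <- f[2:(n %/% 2)][which.max(pg[2:(n %/% 2)])]
  expect_lt(abs(peak - 5), 0.2)
})

test_that("band-limited energy survives 256 to 90 Hz within 2 percent", {
  set.seed(11)
  # white noise low-passed sharply below the new Nyquist (< 40 Hz)
  b <- signal::butter(8, 30 / 128)
  x <- as.numeric(signal::filter(b, rnorm(256 * 120)))
  rec <- eeg_recording(cbind(x), 256, "O1")
  out <- resample_recording(rec, 90)
  expect_lt(abs(stats::var(unclass(out)[, 1]) / stats::var(x) - 1), 0.02)
})
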