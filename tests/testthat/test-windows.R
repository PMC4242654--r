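test_that("sliding-window counts follow floor((dur - win)/step) + 1", {
  # 300 s at 90 Hz, 60 s window, 5 s step -> 49 windows, last start 240 s
  rec <- make_recording(300 * 90, "O1", rate = 90)
  w <- sliding_windows(rec, 60, 5)
  expect_length(w, 49L)
  expect_equal(attr(w[[49]], "start_time"), 240)
  # boundary cases
  expect_length(sliding_windows(make_recording(60 * 90, "O1"), 60, 5), 1L)
  expect_length(sliding_windows(make_recording(59 * 90, "O1"), 60, 5), 0L)
})

test_that("window coverage: starts step uniformly and windows stay inside", {
  rec <- make_recording(137 * 90, c("O1", "F3"), rate = 90)
  w <- sliding_windows(rec, 60, 5)
  starts <- vapply(w, attr, numeric(1), "start_time")
  expect_equal(diff(starts), rep(5, length(w) - 1))
  expect_true(all(starts + 60 <= duration(rec) + 1e-9))
  expect_true(all(vapply(w, nrow, integer(1)) == 60 * 90))
})

test_that("normalization gives exact zero mean and unit variance", {
  w <- analysis_window(cbind(c(1, 2, 3, 4)), 0, 90)
  nw <- normalize_window(w)
  expect_lt(abs(mean(nw)), 1e-10)
  expect_lt(abs(mean(unclass(nw)^2) - 1), 1e-8)  # population variance

  # idempotence
  again <- normalize_window(nw)
  expect_equal(unclass(again), unclass(nw), tolerance = 1e-12)

  # constant channel errors with channel name and window start
  bad <- analysis_window(cbind(O1 = rnorm(10), F3 = rep(2, 10)), 7.5, 90)
  expect_error(normalize_window(bad), "F3")
  expect_error(normalize_window(bad), "7.5")
})

test_that("sliding windows come out normalized", {
  rec <- make_recording(70 * 90, c("O1", "F3"), rate = 90, seed = 5)
  w <- sliding_windows(rec, 60, 5)[[1]]
  expect_true(attr(w, "normalized"))
  expect_true(all(abs(colMeans(unclass(w))) < 1e-10))
  expect_true(all(abs(colMeans(unclass(w)^2) - 1) < 1e-8))
})
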