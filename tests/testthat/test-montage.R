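test_that("montage validation rejects self-neighbors and unknown labels", {
  expect_error(montage(list(F3 = c("F3", "F4"), F4 = "F3")), "itself")
  expect_error(montage(list(F3 = "Pz")), "unknown label")
  expect_error(montage(list(F3 = character(0), F4 = "F3")), "no neighbors")
  m <- default_montage()
  expect_setequal(names(m), ten_twenty_labels())
  expect_equal(sort(m$O1), sort(c("P3", "T5")))
  expect_equal(sort(m$F3), sort(c("Fp1", "F7", "C3", "Fz")))
})

test_that("hjorth re-referencing subtracts the local neighbor average", {
  # identical channels: signal equals neighbor mean everywhere -> zero
  rec <- eeg_recording(matrix(3.7, 50, 3), 90, c("F3", "F4", "Cz"))
  out <- hjorth_rereference(rec, tri_montage())
  expect_true(all(out == 0))
  expect_equal(attr(out, "reference"), "hjorth")

  # fully mutually neighboring trio, one sample row (1, 2, 3)
  rec2 <- eeg_recording(matrix(c(1, 2, 3), 1, 3), 90, c("F3", "F4", "Cz"))
  out2 <- hjorth_rereference(rec2, tri_montage())
  expect_equal(as.numeric(out2), c(1 - 2.5, 2 - 2, 3 - 1.5))
})

test_that("hjorth re-referencing is linear and names missing channels", {
  mt <- tri_montage()
  x <- make_recording(40, c("F3", "F4", "Cz"), seed = 2)
  y <- make_recording(40, c("F3", "F4", "Cz"), seed = 3)
  lhs <- hjorth_rereference(
    eeg_recording(2 * unclass(x) + 5 * unclass(y), 90, channel_labels(x)), mt)
  rhs <- 2 * unclass(hjorth_rereference(x, mt)) +
    5 * unclass(hjorth_rereference(y, mt))
  expect_equal(unclass(lhs), rhs, tolerance = 1e-12)

  expect_error(hjorth_rereference(make_recording(10, c("F3", "Pz")), mt),
               "Pz")
  expect_error(hjorth_rereference(hjorth_rereference(x, mt), mt),
               "already re-referenced")
})

test_that("Cz exclusion leaves 18 channels for VAR fitting", {
  rec <- make_recording(400, ten_twenty_labels(), rate = 90, seed = 4)
  cfg <- run_config(order = 2)
  pre <- preprocess_recording(rec, cfg)
  expect_equal(ncol(pre), 18L)
  expect_false("Cz" %in% channel_labels(pre))
  m <- fit_var(sliding_windows(pre, 4, 4)[[1]], 2)
  expect_length(m$channel_labels, 18L)
})
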