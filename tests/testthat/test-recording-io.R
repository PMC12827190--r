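test_that("recording constructor enforces its invariants", {
  m <- matrix(rnorm(20), nrow = 2)
  rec <- multichannel_recording(m, 100, c("ch1", "ch2"))
  expect_s3_class(rec, "multichannel_recording")
  expect_equal(dim(rec), c(2, 10))
  expect_error(multichannel_recording(m, 100, c("a", "a")), "duplicate")
  expect_error(multichannel_recording(m, -1, c("a", "b")), "rate")
  expect_error(multichannel_recording(m, 100, c("a", "b"), c("other", "nope")),
               "unknown channel role")
  expect_error(multichannel_recording(m[0, , drop = FALSE], 100, character(0)),
               class = "mecg_empty_input")
})

test_that("CSV round trip: time column infers the rate", {
  rec <- multichannel_recording(matrix(seq_len(20) / 7, nrow = 2), 50,
                                c("ch1", "ch2"))
  f <- withr::local_tempfile(fileext = ".csv")
  save_recording(rec, f)
  back <- load_recording(f, format = "csv")
  expect_equal(back$rate, 50)
  expect_equal(back$channel_names, c("ch1", "ch2"))
  expect_equal(back$samples, rec$samples, tolerance = 1e-12)
  # no time column -> rate is mandatory
  df <- utils::read.csv(f)[-1]
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, f2, row.names = FALSE)
  expect_error(load_recording(f2, format = "csv"), "rate",
               class = "mecg_format_error")
  expect_equal(load_recording(f2, format = "csv", rate = 50)$rate, 50)
})

test_that("CSV with duplicate channel names is rejected", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,ch,ch", "0,1,2", "0.1,3,4"), f)
  expect_error(load_recording(f, format = "csv"), "duplicate")
})

test_that("serialized container round-trips samples, rate, names, roles exactly", {
  rec <- multichannel_recording(matrix(rnorm(300), nrow = 3), 123.5,
                                c("MLT31", "BR1", "ECG"),
                                c("meg_gradiometer", "reference", "ecg_bipolar"))
  f <- withr::local_tempfile(fileext = ".rds")
  save_recording(rec, f)
  back <- load_recording(f, format = "rds")
  expect_identical(back$samples, rec$samples)
  expect_identical(back$rate, rec$rate)
  expect_identical(back$channel_names, rec$channel_names)
  expect_identical(back$channel_roles, rec$channel_roles)
})

test_that("channel selection follows glob semantics and is idempotent", {
  rec <- multichannel_recording(matrix(rnorm(40), nrow = 4), 100,
                                c("MLT31", "MRT31", "EEG1", "MLT58"))
  expect_equal(select_channels(rec, "MLT*")$channel_names, c("MLT31", "MLT58"))
  expect_equal(select_channels(rec, "EEG1")$channel_names, "EEG1")
  expect_error(select_channels(rec, "XX*"), class = "mecg_selection_error")
  # default pattern matches the MRT/MLT 31-58 temporal set
  expect_equal(select_channels(rec)$channel_names, c("MLT31", "MRT31", "MLT58"))
  once <- select_channels(rec, "MLT*")
  expect_identical(select_channels(once, "MLT*"), once)
})

test_that("ECG channel extraction handles ambiguity", {
  m <- matrix(rnorm(30), nrow = 3)
  rec1 <- multichannel_recording(m, 100, c("a", "b", "ecg"),
                                 c("other", "other", "ecg_bipolar"))
  tr <- extract_ecg_channel(rec1)
  expect_identical(tr$source, "I-ECG")
  expect_false(tr$normalized)
  expect_equal(tr$values, m[3, ])
  rec2 <- multichannel_recording(m, 100, c("a", "e1", "e2"),
                                 c("other", "ecg_bipolar", "ecg_bipolar"))
  expect_error(extract_ecg_channel(rec2), class = "mecg_ambiguity_error")
  expect_equal(extract_ecg_channel(rec2, "e2")$values, m[3, ])
})

test_that("FIF input is read through the MNE bridge with roles inferred", {
  py <- Sys.which("python")
  expect_true(nzchar(py))
  fif <- file.path(withr::local_tempdir(), "sim_raw.fif")
  script <- sprintf("
import mne, numpy as np
info = mne.create_info(['MLT31','BR1','ECG'], 250.0, ['mag','ref_meg','ecg'])
data = np.vstack([np.sin(np.arange(500)/9.0), np.cos(np.arange(500)/9.0),
                  np.arange(500)/500.0])
mne.io.RawArray(data, info, verbose='error').save('%s', verbose='error')
", fif)
  sf <- withr::local_tempfile(fileext = ".py")
  writeLines(script, sf)
  res <- system2(py, sf, stdout = TRUE, stderr = TRUE)
  expect_null(attr(res, "status"))
  rec <- load_recording(fif, format = "fif")
  expect_equal(rec$rate, 250)
  expect_equal(rec$channel_roles,
               c("meg_gradiometer", "reference", "ecg_bipolar"))
  expect_lt(max(abs(rec$samples[1, ] - sin((0:499) / 9))), 1e-6)
})

test_that("unreadable paths and unknown formats raise format errors", {
  expect_error(load_recording("/nonexistent/x.csv"), class = "mecg_format_error")
  expect_error(load_recording("/nonexistent/x.xyz"), class = "mecg_format_error")
})
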