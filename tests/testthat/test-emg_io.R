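test_that("MAT v5 round trip preserves numeric arrays, compressed and not", {
  emg <- matrix(sin(seq_len(60)) * 1.7, 20, 3)
  stim <- matrix(as.numeric(rep(c(0, 2, 0, 5), each = 5)), ncol = 1)
  for (comp in c(FALSE, TRUE)) {
    path <- withr::local_tempfile(fileext = ".mat")
    write_mat5(list(emg = emg, stimulus = stim, subject = matrix(3)), path,
               compress = comp)
    back <- read_mat5(path)
    expect_equal(back$emg, emg)
    expect_equal(back$stimulus, stim)
    expect_equal(back$subject, matrix(3))
  }
})

test_that("MAT reader agrees with an independently written file", {
  # scipy writes the same format from a different code base; integer dtypes
  # and compression exercise paths our own writer does not produce.
  skip_if(Sys.which("python") == "", "python not on PATH")
  path <- withr::local_tempfile(fileext = ".mat")
  script <- sprintf(paste0(
    "import scipy.io, numpy as np\n",
    "emg = np.arange(24, dtype=float).reshape(8, 3) / 7.0\n",
    "stim = np.array([0, 0, 1, 1, 1, 2, 2, 0], dtype=np.int16).reshape(-1, 1)\n",
    "scipy.io.savemat(%s, {'emg': emg, 'stimulus': stim}, do_compression=True)\n"),
    deparse(path))
  res <- system2("python", "-", input = script, stdout = TRUE, stderr = TRUE)
  skip_if(!file.exists(path), "python/scipy unavailable")
  back <- read_mat5(path)
  expect_equal(back$emg, matrix(0:23, 8, 3, byrow = TRUE) / 7.0)
  expect_equal(as.vector(back$stimulus), c(0, 0, 1, 1, 1, 2, 2, 0))
})

test_that("read_ninapro_mat maps fields, checks alignment, keeps order", {
  path <- withr::local_tempfile(fileext = ".mat")
  ramp <- seq_len(30)                      # injected ramp channel
  emg <- cbind(rnorm(30), ramp, rnorm(30))
  stim <- matrix(rep(c(0, 4, 0), each = 10), ncol = 1)
  write_mat5(list(EMG = emg, Stimulus = stim, subject = matrix(7)), path)
  rec <- read_ninapro_mat(path)            # case-insensitive field match
  expect_s3_class(rec, "emg_recording")
  expect_equal(ncol(rec$signal), 3L)
  expect_equal(rec$fs, 100)
  expect_equal(rec$signal[, 2], ramp)      # no channel/sample reordering
  expect_equal(rec$labels, rep(c(0L, 4L, 0L), each = 10))
  expect_equal(rec$subject_id, "7")

  nolab <- withr::local_tempfile(fileext = ".mat")
  write_mat5(list(emg = emg), nolab)
  expect_error(read_ninapro_mat(nolab), "stimulus")

  bad <- withr::local_tempfile(fileext = ".mat")
  write_mat5(list(emg = emg, stimulus = matrix(c(0, 1))), bad)
  expect_error(read_ninapro_mat(bad), "integrity")
})

test_that("HDF5 recording round trip is exact in shape, fs and labels", {
  rec <- emg_recording(matrix(rnorm(300), 100, 3), fs = 100,
                       labels = rep(c(0L, 3L), 50), subject_id = "s2",
                       exercise_id = "e1")
  path <- withr::local_tempfile(fileext = ".h5")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$signal, rec$signal)
  expect_identical(back$labels, rec$labels)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$subject_id, "s2")
  expect_error(write_recording(rec, file.path(tempdir(), "no/such/dir/x.h5")))
})

test_that("degenerate recordings are rejected before write", {
  expect_error(emg_recording(matrix(numeric(0), 0, 3), fs = 100),
               ">= 1 sample")
  expect_error(emg_recording(matrix(1:10, 5, 2), fs = 100, labels = 1:3),
               "labels length")
  expect_error(emg_recording(matrix(1:10, 5, 2), fs = 0), "positive")
  expect_error(emg_recording(matrix(1:10, 5, 2), fs = 100,
                             labels = c(-1L, 0L, 0L, 0L, 0L)), "non-negative")
})

test_that("mode tensors survive the HDF5 round trip", {
  t <- seq(0.01, 3, by = 0.01)
  x <- cbind(cos(2 * pi * 6 * t), sin(2 * pi * 6 * t))
  mt <- mvmd_decompose(x, mvmd_settings(K = 2), fs = 100)
  path <- withr::local_tempfile(fileext = ".h5")
  write_modes(mt, path)
  back <- read_modes(path)
  expect_equal(back$modes, mt$modes, tolerance = 1e-12)
  expect_equal(back$center_freqs, mt$center_freqs)
  expect_equal(back$converged, mt$converged)
})

test_that("configuration loading fills defaults and rejects bad keys", {
  empty <- withr::local_tempfile(fileext = ".yaml")
  writeLines(character(0), empty)
  cfg <- load_config(empty)
  expect_equal(cfg$window_ms, 400)
  expect_equal(cfg$n_modes, 4L)

  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("seed: 42", f)
  expect_equal(load_config(f)$seed, 42L)

  writeLines("n_modes: 0", f)
  expect_error(load_config(f), "K")
  writeLines("frobnicate: 1", f)
  expect_error(load_config(f), "unknown configuration key")
  writeLines(c("window_ms: -5"), f)
  expect_error(load_config(f), "window_ms")
})

test_that("feature tables round trip through CSV", {
  ds <- small_dataset()
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ds$features, path)
  back <- read_feature_table(path)
  expect_equal(back$label, ds$features$label)
  expect_equal(back[["ch1_RMS"]], ds$features[["ch1_RMS"]], tolerance = 1e-12)
})
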