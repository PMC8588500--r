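tone_mix <- function(fs = 100, dur = 10) {
  t <- seq(1 / fs, dur, by = 1 / fs)
  list(t = t,
       low = cos(2 * pi * 5 * t),
       high = cos(2 * pi * 20 * t))
}

test_that("a single tone is recovered as the unique minimum-bandwidth mode", {
  tm <- tone_mix()
  x <- cbind(cos(2 * pi * 10 * tm$t), 0.5 * cos(2 * pi * 10 * tm$t))
  mt <- mvmd_decompose(x, mvmd_settings(K = 1), fs = 100)
  expect_lt(abs(mt$center_freqs - 10), 0.5)
  expect_lt(sqrt(sum((mt$modes[1, , ] - x)^2) / sum(x^2)), 0.05)
  expect_true(mt$converged)
})

test_that("a 5 + 20 Hz mixture separates into its source tones", {
  tm <- tone_mix()
  x <- cbind(tm$low + 0.5 * tm$high, 0.7 * tm$low + 1.2 * tm$high)
  mt <- mvmd_decompose(x, mvmd_settings(K = 2), fs = 100)
  expect_lt(abs(mt$center_freqs[1] - 5), 1)
  expect_lt(abs(mt$center_freqs[2] - 20), 1)
  for (ch in 1:2) {
    expect_gt(cor(mt$modes[1, , ch], tm$low), 0.95)
    expect_gt(cor(mt$modes[2, , ch], tm$high), 0.95)
  }
  expect_lt(sqrt(sum((reconstruct(mt, include_residual = FALSE) - x)^2) /
                   sum(x^2)), 0.05)
  # modes + residual give the input back exactly
  expect_equal(reconstruct(mt), x, tolerance = 1e-10)
  # low_frequency_mode picks the 5 Hz component
  expect_gt(cor(low_frequency_mode(mt)[, 1], tm$low), 0.95)
})

test_that("zero signal decomposes into zero modes with zero residual", {
  mt <- mvmd_decompose(matrix(0, 64, 2), mvmd_settings(K = 2), fs = 100)
  expect_true(all(mt$modes == 0))
  expect_true(all(mt$residual == 0))
  expect_true(mt$converged)
})

test_that("channel permutation only permutes mode channels", {
  tm <- tone_mix(dur = 4)
  x <- cbind(tm$low + 0.3 * tm$high, 2 * tm$low - tm$high,
             0.5 * tm$high)
  st <- mvmd_settings(K = 2)
  mt <- mvmd_decompose(x, st, fs = 100)
  perm <- c(3L, 1L, 2L)
  mtp <- mvmd_decompose(x[, perm], st, fs = 100)
  expect_equal(mtp$center_freqs, mt$center_freqs, tolerance = 1e-8)
  expect_equal(mtp$modes, mt$modes[, , perm], tolerance = 1e-8)
})

test_that("decomposition is linear in amplitude with fixed initialization", {
  tm <- tone_mix(dur = 4)
  x <- cbind(tm$low + 0.4 * tm$high, tm$high)
  st <- mvmd_settings(K = 2)
  mt <- mvmd_decompose(x, st, fs = 100)
  mta <- mvmd_decompose(3.5 * x, st, fs = 100)
  expect_equal(mta$modes, 3.5 * mt$modes, tolerance = 1e-6)
  expect_equal(mta$center_freqs, mt$center_freqs, tolerance = 1e-6)
})

test_that("the bandwidth objective does not increase over the run", {
  tm <- tone_mix(dur = 4)
  x <- cbind(tm$low + 0.5 * tm$high, tm$low - tm$high)
  mt <- mvmd_decompose(x, mvmd_settings(K = 2), fs = 100)
  tr <- mt$objective_trace
  expect_lte(tr[length(tr)], tr[1])
})

test_that("single-channel MVMD reduces to univariate VMD", {
  set.seed(3)
  t <- (1:256) / 100
  x <- cos(2 * pi * 7 * t) + 0.6 * cos(2 * pi * 23 * t)
  st <- mvmd_settings(K = 2, alpha = 2000, tau = 0, tol = 1e-7)
  mt <- mvmd_decompose(matrix(x, ncol = 1), st, fs = 100)
  or <- vmd_oracle(x, K = 2, alpha = 2000, tau = 0, tol = 1e-7)
  expect_lt(max(abs(mt$modes[1, , 1] - or$modes[, 1])), 1e-6)
  expect_lt(max(abs(mt$modes[2, , 1] - or$modes[, 2])), 1e-6)
  expect_equal(mt$center_freqs / 100, or$omega, tolerance = 1e-8)
})

test_that("mode spectra satisfy Parseval and peak at the center frequency", {
  tm <- tone_mix()
  x <- cbind(tm$low + 0.5 * tm$high, tm$high)
  mt <- mvmd_decompose(x, mvmd_settings(K = 2), fs = 100)
  sp <- mode_spectrum(mt, 1L, 1L)
  expect_equal(sum(sp$power), sum(mt$modes[1, , 1]^2),
               tolerance = 1e-6)
  expect_lt(abs(sp$freqs[which.max(sp$power)] - mt$center_freqs[1]), 1)
  # zero mode has zero power
  mt0 <- mvmd_decompose(matrix(0, 64, 1), mvmd_settings(K = 1), fs = 100)
  expect_true(all(mode_spectrum(mt0, 1L, 1L)$power == 0))
  expect_error(mode_spectrum(mt, 5L, 1L), "out of range")
})

test_that("invalid inputs are rejected", {
  expect_error(mvmd_decompose(matrix(c(1, NA, 3, 4), 2), mvmd_settings(K = 1),
                              fs = 100), "finite")
  expect_error(mvmd_decompose(matrix(rnorm(6), 3), mvmd_settings(K = 2),
                              fs = 100), "2\\*K")
  expect_error(mvmd_settings(K = 1, alpha = -1))
})
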