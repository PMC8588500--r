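test_that("z-score standardizes every channel and is idempotent", {
  rec <- emg_recording(cbind(1:50, rnorm(50, 10, 4)), fs = 100)
  z <- zscore(rec)
  expect_true(all(abs(colMeans(z$signal)) < 1e-9))
  expect_true(all(abs(apply(z$signal, 2, sd) - 1) < 1e-9))
  z2 <- zscore(z)
  expect_equal(z2$signal, z$signal, tolerance = 1e-9)
  const <- emg_recording(cbind(rnorm(20), rep(2, 20)), fs = 100)
  expect_error(zscore(const), "channel")
})

test_that("Teager operator matches its closed forms", {
  expect_true(all(teager_energy(rep(3.7, 12)) == 0))
  expect_true(all(teager_energy(as.numeric(0:20)) == 1))
  A <- 2; w <- 0.3
  psi <- teager_energy(A * cos(w * (0:199) + 0.4))
  expect_true(max(abs(psi[2:199] - A^2 * sin(w)^2)) < 1e-9)
  expect_error(teager_energy(c(1, 2)), "3 samples")
  expect_length(teager_energy(rnorm(10)), 10L)
})

test_that("Teager operator is scale-quadratic", {
  set.seed(42)
  for (i in 1:5) {
    x <- rnorm(50)
    a <- runif(1, -3, 3)
    expect_equal(teager_energy(a * x), a^2 * teager_energy(x),
                 tolerance = 1e-12)
  }
})

test_that("smoothed channel energy averages channels then time", {
  # single channel, N = 1: identity with the raw operator
  x <- rnorm(40)
  rec1 <- emg_recording(matrix(x, ncol = 1), fs = 100)
  expect_equal(smoothed_channel_energy(rec1, 1L), teager_energy(x))
  # ramps have exactly unit Teager energy; scaling one by sqrt(3) gives
  # channel energies (1, 3) and a cross-channel average of 2
  rec2 <- emg_recording(cbind(1:40, sqrt(3) * (1:40)), fs = 100)
  expect_equal(smoothed_channel_energy(rec2, 1L), rep(2, 40),
               tolerance = 1e-12)
  # constant energy survives any smoothing width
  expect_equal(smoothed_channel_energy(rec2, 15L), rep(2, 40),
               tolerance = 1e-12)
  expect_error(smoothed_channel_energy(rec2, 41L), "exceeds")
})

test_that("activity detection follows the threshold/duration rule", {
  e <- rep(0, 400); e[101:200] <- 1
  acts <- detect_active(e, threshold = 0.5, min_dur = 3L)
  expect_equal(acts$intervals$start_sample, 100L)
  expect_equal(acts$intervals$end_sample, 200L)
  # all-quiet stream
  expect_equal(nrow(detect_active(rep(0, 100), 0.5, 3L)$intervals), 0L)
  # supra-threshold blip one sample too short
  e2 <- rep(0, 100); e2[50:51] <- 1
  expect_equal(nrow(detect_active(e2, 0.5, 3L)$intervals), 0L)
})

test_that("only crossings and run lengths matter, not values in between", {
  set.seed(7)
  base <- rep(c(0, 1, 0, 1, 0), c(30, 20, 15, 25, 30))
  a1 <- detect_active(base, 0.5, 5L)
  wobble <- base
  wobble[base > 0.5] <- runif(sum(base > 0.5), 0.6, 40)  # any supra values
  wobble[base < 0.5] <- runif(sum(base < 0.5), 0, 0.4)   # any sub values
  a2 <- detect_active(wobble, 0.5, 5L)
  expect_equal(a2$intervals, a1$intervals)
})

test_that("relabel is a fixed point on exact intervals and rests elsewhere", {
  labels <- rep(c(0L, 2L, 0L, 5L, 0L), each = 40)
  rec <- emg_recording(matrix(rnorm(400), ncol = 2), fs = 100, labels = labels)
  iv <- data.frame(start_sample = c(40L, 120L), end_sample = c(80L, 160L))
  expect_identical(relabel(rec, iv)$labels, labels)
  # empty interval set -> all rest
  empty <- data.frame(start_sample = integer(0), end_sample = integer(0))
  expect_true(all(relabel(rec, empty)$labels == 0L))
  # majority vote inside a shifted interval
  shifted <- data.frame(start_sample = 30L, end_sample = 85L)
  expect_true(all(relabel(rec, shifted)$labels[41:80] == 2L))
  # unlabeled interval borrows the nearest labeled interval's id
  orphan <- data.frame(start_sample = c(40L, 178L), end_sample = c(80L, 195L))
  expect_warning(out <- relabel(rec, orphan), "nearest")
  expect_true(all(out$labels[179:195] == 2L))
  expect_error(relabel(rec, data.frame(start_sample = -5L, end_sample = 3L)),
               "bounds")
})

test_that("Teager relabeling recovers true onsets better than jittered labels", {
  plan <- small_plan(seed = 31L, label_jitter_ms = 200)
  rec <- simulate_recording(plan)
  tv <- true_intervals(plan)
  res <- teager_relabel(zscore(rec), emg_config())
  iv <- res$intervals$intervals
  expect_equal(nrow(iv), nrow(tv))
  onset_mae <- function(on) mean(abs(on - tv$start_sample))
  r <- rle(rec$labels)
  jit_on <- c(0L, cumsum(r$lengths)[-length(r$lengths)])[r$values > 0L]
  expect_lt(onset_mae(iv$start_sample), onset_mae(jit_on))
})

test_that("segmentation cuts label-pure windows and drops partials", {
  labels <- c(rep(3L, 100), rep(0L, 10), rep(4L, 35))
  rec <- emg_recording(matrix(rnorm(2 * 145), ncol = 2), fs = 100,
                       labels = labels)
  wins <- segment_windows(rec, window_ms = 400)   # 40 samples at 100 Hz
  expect_length(wins, 2L)                          # floor(100/40), run 4 too short
  expect_true(all(vapply(wins, `[[`, integer(1), "label") == 3L))
  # alternating labels, window = run length: one window per run
  labels2 <- rep(c(1L, 2L, 1L, 2L), each = 40)
  rec2 <- emg_recording(matrix(rnorm(2 * 160), ncol = 2), fs = 100,
                        labels = labels2)
  wins2 <- segment_windows(rec2, 400)
  expect_equal(vapply(wins2, `[[`, integer(1), "label"), c(1L, 2L, 1L, 2L))
  # windows restart at run boundaries: no window straddles two labels
  for (w in wins2) {
    run <- rec2$labels[(w$start_sample + 1L):(w$start_sample + 40L)]
    expect_length(unique(run), 1L)
  }
  # emitted samples never exceed labeled samples
  total <- sum(vapply(wins2, function(w) nrow(w$data), numeric(1)))
  expect_lte(total, sum(labels2 > 0L))
})
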