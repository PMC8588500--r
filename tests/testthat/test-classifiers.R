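test_that("convolution parameter counts match the architecture table", {
  # separable counts at input depth 1; standard Conv1 count at depth 4
  expect_identical(count_separable_params(3, 1, 32), 73L)
  expect_identical(count_separable_params(3, 32, 64), 2400L)
  expect_identical(count_separable_params(3, 64, 128), 8896L)
  expect_identical(count_standard_params(3, 4, 32), 1184L)
  expect_identical(count_standard_params(3, 32, 64), 18496L)
  expect_identical(count_standard_params(3, 64, 128), 73856L)
  # degenerate size where separable exceeds standard
  expect_identical(count_separable_params(1, 1, 1), 3L)
  expect_identical(count_standard_params(1, 1, 1), 2L)
})

test_that("the assembled network reproduces every table cell", {
  m1 <- build_scnn(scnn_spec(c(30, 10, 1), n_classes = 12))
  tab1 <- m1$layers
  cell <- function(tab, layer, col) tab[[col]][tab$layer == layer]
  expect_identical(cell(tab1, "Convolution1", "params_separable"), 73L)
  expect_identical(cell(tab1, "Convolution2", "params_separable"), 2400L)
  expect_identical(cell(tab1, "Convolution3", "params_separable"), 8896L)
  expect_identical(cell(tab1, "Convolution2", "params_standard"), 18496L)
  expect_identical(cell(tab1, "Convolution3", "params_standard"), 73856L)
  expect_identical(cell(tab1, "Dense", "params_standard"), 344192L)
  expect_identical(cell(tab1, "Softmax", "params_standard"), 1548L)
  m4 <- build_scnn(scnn_spec(c(30, 10, 4), n_classes = 12))
  expect_identical(cell(m4$layers, "Convolution1", "params_standard"), 1184L)
  # dense count comes from the traced 7 x 3 x 128 flattened map
  expect_identical(m1$spec$flat_dim, 7L * 3L * 128L)
})

test_that("parameter ratio matches the bias-free count ratio", {
  expect_equal(param_ratio(3, 32, 64), 18432 / 2336, tolerance = 1e-12)
  expect_equal(param_ratio(1, 4, 1), 0.5)
  for (kcn in list(c(3, 32, 64), c(3, 64, 128), c(5, 8, 16))) {
    k <- kcn[1]; c <- kcn[2]; N <- kcn[3]
    bias_free <- (count_standard_params(k, c, N) - N) /
      (count_separable_params(k, c, N) - N)
    expect_equal(param_ratio(k, c, N), bias_free, tolerance = 1e-12)
  }
  # ratio tends to k^2 for wide layers
  expect_lt(abs(param_ratio(3, 16, 1e6) - 9) / 9, 0.01)
})

test_that("spatial collapse and bad class counts are rejected", {
  expect_error(scnn_spec(c(2, 2, 1)), "collapse")
  expect_error(scnn_spec(c(30, 10, 1), n_classes = 1), "n_classes")
})

test_that("backpropagation matches finite differences", {
  spec <- scnn_spec(c(8, 4, 2), n_classes = 3)
  spec$dropout_rate <- 0                      # deterministic loss for FD
  w <- emgflow:::scnn_init_weights(spec, 2L)
  set.seed(14)
  xb <- array(rnorm(8 * 4 * 5 * 2), c(8, 4, 5, 2))
  yb <- c(1L, 2L, 3L, 1L, 2L)
  fw <- emgflow:::scnn_forward(w, spec, xb, train = TRUE)
  sm <- emgflow:::softmax_ce(fw$logits, yb)
  g <- emgflow:::scnn_backward(w, spec, xb, fw$cache, sm$dlogits)
  loss_at <- function(w) emgflow:::softmax_ce(
    emgflow:::scnn_forward(w, spec, xb)$logits, yb)$loss
  for (nm in names(g)) {
    for (r in 1:2) {
      i <- sample(length(w[[nm]]), 1L)
      eps <- 1e-5
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
      fd <- (loss_at(wp) - loss_at(wm)) / (2 * eps)
      expect_lt(abs(fd - g[[nm]][i]) / max(1e-6, abs(fd) + abs(g[[nm]][i])),
                1e-4)
    }
  }
})

test_that("standard and separable variants both train the same interface", {
  # tiny class-separable images: per-class mean pattern plus noise
  set.seed(20)
  n_per <- 24L
  mk_class <- function(mu) {
    arr <- array(rnorm(n_per * 12 * 4 * 1, sd = 0.3), c(n_per, 12, 4, 1))
    sweep(arr, c(2, 3, 4), mu, "+")
  }
  mus <- list(outer(sin(1:12 / 2), c(1, 0.5, 0, 0)),
              outer(cos(1:12 / 2), c(0, 0, 0.5, 1)))
  x <- array(0, c(2L * n_per, 12, 4, 1))
  x[1:n_per, , , 1] <- mk_class(mus[[1]])[, , , 1]
  x[(n_per + 1):(2 * n_per), , , 1] <- mk_class(mus[[2]])[, , , 1]
  y <- rep(c(4L, 9L), each = n_per)          # arbitrary gesture ids
  cfg <- emg_config(seed = 2L, epochs = 10L, patience = 4L)
  for (sep in c(TRUE, FALSE)) {
    spec <- scnn_spec(c(12, 4, 1), n_classes = 2L, separable = sep)
    m <- train_stage2(x, y, spec = spec, config = cfg)
    expect_gt(mean(predict(m, x) == y), 0.8)
    expect_true(all(predict(m, x) %in% c(4L, 9L)))
  }
})

test_that("stage-2 training is deterministic under a fixed seed", {
  set.seed(33)
  x <- array(rnorm(20 * 8 * 4 * 2), c(20, 8, 4, 2))
  y <- rep(1:2, 10)
  cfg <- emg_config(seed = 5L, epochs = 2L)
  m1 <- train_stage2(x, y, config = cfg)
  m2 <- train_stage2(x, y, config = cfg)
  expect_identical(m1$history$loss[1], m2$history$loss[1])
  expect_identical(m1$weights, m2$weights)
})

test_that("stage-2 input validation catches label/spec mismatches", {
  x <- array(rnorm(10 * 8 * 4 * 1), c(10, 8, 4, 1))
  expect_error(train_stage2(x, rep(1L, 10)), "2 classes")
  spec <- scnn_spec(c(8, 4, 1), n_classes = 3L)
  expect_error(train_stage2(x, rep(1:2, 5), spec = spec), "classes present")
  x[1] <- NA
  expect_error(train_stage2(x, rep(1:2, 5)), "finite")
})

test_that("stage-1 learns force-separable superclasses with every method", {
  set.seed(8)
  # feature vectors whose magnitude encodes force level, 3 superclasses
  mk <- function(scale, n) matrix(rnorm(n * 6, mean = scale, sd = 0.25 * scale),
                                  n, 6)
  X <- rbind(mk(1, 40), mk(3, 40), mk(9, 40))
  colnames(X) <- paste0("ch", 1:6, "_RMS")
  y <- rep(1:3, each = 40)
  tr <- c(1:30, 41:70, 81:110)
  te <- setdiff(seq_len(120), tr)
  for (method in c("svm", "rf", "dt", "knn", "nb", "lda")) {
    m <- train_stage1(X[tr, ], superclass = y[tr], method = method, seed = 4L)
    acc <- mean(predict(m, X[te, ]) == y[te])
    expect_gt(acc, 0.9)
  }
  expect_error(train_stage1(X, superclass = rep(1L, 120)), "2 superclasses")
})

test_that("duplicating every training vector leaves the SVM unchanged", {
  set.seed(9)
  X <- rbind(matrix(rnorm(60, 1, 0.3), 10, 6), matrix(rnorm(60, 4, 0.5), 10, 6))
  y <- rep(1:2, each = 10)
  m1 <- train_stage1(X, superclass = y, method = "svm", seed = 1L)
  m2 <- train_stage1(rbind(X, X), superclass = c(y, y), method = "svm",
                     seed = 1L)
  probe <- matrix(rnorm(300, 2, 1.5), 50, 6)
  expect_identical(predict(m1, probe), predict(m2, probe))
})

test_that("stage-1 accuracy grows with inter-superclass force separation", {
  set.seed(10)
  run_at <- function(ratio) {
    scales <- c(1, ratio, ratio^2)
    mk <- function(s, n) matrix(rnorm(n * 4, mean = s, sd = 0.8 * s), n, 4)
    X <- do.call(rbind, lapply(scales, mk, n = 60))
    y <- rep(1:3, each = 60)
    idx <- sample(180)
    tr <- idx[1:120]; te <- idx[121:180]
    m <- train_stage1(X[tr, ], superclass = y[tr], method = "svm", seed = 2L)
    mean(predict(m, X[te, ]) == y[te])
  }
  accs <- vapply(c(1.2, 2, 4), run_at, numeric(1))
  expect_true(all(diff(accs) >= -0.02))   # monotone up to small noise
  expect_gt(accs[3], accs[1])
})
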