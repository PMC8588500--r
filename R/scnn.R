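#' Specification of the stage-2 separable convolutional network
#'
#' The fixed stack: Conv1 (3x3, 32) - Dropout - Conv2 (3x3, 64) -
#' MaxPool 2x2 - Conv3 (3x3, 128) - ZeroPad (one column each side of the
#' width axis) - MaxPool 2x2 - Flatten - Dropout - Dense 128 - Softmax.
#' Convolutions use 'same' zero padding and can be standard or
#' depthwise-separable (a per-channel 3x3 depthwise step without bias
#' followed by a 1x1 pointwise step with biases).
#'
#' @param input_shape `(height, width, depth)`: window samples, electrode
#'   channels, stacked decomposition modes (depth 1 for the
#'   low-frequency-only variant).
#' @param n_classes Number of gestures the softmax resolves (>= 2).
#' @param conv_filters Filter counts of the three convolution layers.
#' @param dense_units Width of the dense layer.
#' @param dropout_rate Dropout probability (both dropout layers).
#' @param separable Use depthwise-separable convolutions (the lightweight
#'   variant) instead of standard ones.
#' @return An `scnn_spec` list, including the traced spatial dimensions.
#' @export
scnn_spec <- function(input_shape = c(30, 10, 1), n_classes = 12L,
                      conv_filters = c(32L, 64L, 128L), dense_units = 128L,
                      dropout_rate = 0.5, separable = TRUE) {
  stopifnot(length(input_shape) == 3L, all(input_shape >= 1L),
            length(conv_filters) == 3L, dense_units >= 1L,
            dropout_rate >= 0, dropout_rate < 1)
  if (n_classes < 2L) stop("n_classes must be >= 2", call. = FALSE)
  H <- as.integer(input_shape[1]); W <- as.integer(input_shape[2])
  # 'same' convolutions keep H x W; trace the pooling / padding stack.
  H1 <- H %/% 2L; W1 <- W %/% 2L            # after MaxPool1
  W1p <- W1 + 2L                            # after ZeroPad (0,1)
  H2 <- H1 %/% 2L; W2 <- W1p %/% 2L         # after MaxPool2
  if (H1 < 1L || W1 < 1L || H2 < 1L || W2 < 1L)
    stop("spec error: spatial dimensions collapse below 1 through the stack",
         call. = FALSE)
  structure(list(input_shape = as.integer(input_shape),
                 n_classes = as.integer(n_classes),
                 conv_filters = as.integer(conv_filters),
                 dense_units = as.integer(dense_units),
                 dropout_rate = dropout_rate,
                 separable = isTRUE(separable),
                 kernel = c(3L, 3L),
                 pooled_shape = c(H2, W2),
                 flat_dim = H2 * W2 * as.integer(conv_filters[3])),
            class = "scnn_spec")
}

#' Trainable-parameter counts of convolution layers
#'
#' For a `k x k` kernel on `c` input channels producing `N` filters:
#' separable = `k*k*c + c*N + N` (depthwise weights without bias, pointwise
#' weights, pointwise biases); standard = `k*k*c*N + N`.
#'
#' @param k Kernel side, `c` input channels, `N` filters (all >= 1).
#' @return Integer parameter count.
#' @examples
#' count_separable_params(3, 32, 64)  # 2400
#' count_standard_params(3, 32, 64)   # 18496
#' @export
count_separable_params <- function(k, c, N) {
  stopifnot(k >= 1, c >= 1, N >= 1)
  as.integer(k * k * c + c * N + N)
}

#' @rdname count_separable_params
#' @export
count_standard_params <- function(k, c, N) {
  stopifnot(k >= 1, c >= 1, N >= 1)
  as.integer(k * k * c * N + N)
}

#' Bias-free standard/separable parameter ratio
#'
#' `k^2 * c * N / (k^2 * c + c * N)`; tends to `k^2` as `N` grows.
#'
#' @inheritParams count_separable_params
#' @return Numeric ratio.
#' @export
param_ratio <- function(k, c, N) {
  stopifnot(k >= 1, c >= 1, N >= 1)
  (k * k * c * N) / (k * k * c + c * N)
}

scnn_param_table <- function(spec) {
  f <- spec$conv_filters
  C0 <- spec$input_shape[3]
  conv <- function(cin, n) c(count_standard_params(3, cin, n),
                             count_separable_params(3, cin, n))
  c1 <- conv(C0, f[1]); c2 <- conv(f[1], f[2]); c3 <- conv(f[2], f[3])
  dense <- spec$flat_dim * spec$dense_units + spec$dense_units
  softm <- spec$dense_units * spec$n_classes + spec$n_classes
  data.frame(
    layer = c("Input", "Convolution1", "Dropout", "Convolution2",
              "Maxpooling1", "Convolution3", "Zeropadding", "Maxpooling2",
              "Flatten", "Dropout", "Dense", "Softmax"),
    size = c(sprintf("(%d,%d,%d)", spec$input_shape[1], spec$input_shape[2],
                     spec$input_shape[3]),
             "(3,3)", "-", "(3,3)", "(2,2)", "(3,3)", "(0,1)", "(2,2)", "-",
             "-", as.character(spec$dense_units),
             as.character(spec$n_classes)),
    channels = c(C0, f[1], NA, f[2], f[2], f[3], f[3], f[3], NA, NA, NA, NA),
    params_standard = c(0L, c1[1], NA, c2[1], NA, c3[1], NA, NA, NA, NA,
                        as.integer(dense), as.integer(softm)),
    params_separable = c(0L, c1[2], NA, c2[2], NA, c3[2], NA, NA, NA, NA,
                         as.integer(dense), as.integer(softm)))
}

scnn_init_weights <- function(spec, seed) {
  set.seed(seed)
  f <- spec$conv_filters
  C0 <- spec$input_shape[3]
  he <- function(dims, fan_in) array(stats::rnorm(prod(dims), 0,
                                                  sqrt(2 / fan_in)), dims)
  w <- list()
  cins <- c(C0, f[1], f[2])
  for (l in 1:3) {
    cin <- cins[l]; n <- f[l]
    if (spec$separable) {
      w[[paste0("dw", l)]] <- he(c(3L, 3L, cin), 9)
      w[[paste0("pw", l)]] <- he(c(cin, n), cin)
    } else {
      w[[paste0("cw", l)]] <- he(c(9L * cin, n), 9 * cin)
    }
    w[[paste0("cb", l)]] <- numeric(n)
  }
  w$wd <- he(c(spec$flat_dim, spec$dense_units), spec$flat_dim)
  w$bd <- numeric(spec$dense_units)
  w$wo <- he(c(spec$dense_units, spec$n_classes), spec$dense_units)
  w$bo <- numeric(spec$n_classes)
  w
}

#' Assemble the stage-2 network and account for its parameters
#'
#' Builds the network of [scnn_spec()] (initialized, untrained) and returns
#' alongside it the per-layer trainable-parameter table for both the
#' standard and the separable variant of each convolution layer, counted
#' from the actual weight arrays of the assembled variant and the closed
#' form for its counterfactual.
#'
#' @param spec An [scnn_spec()].
#' @param seed Seed for weight initialization.
#' @return An `scnn_model` with elements `spec`, `weights`, `layers` (the
#'   parameter table), `trained = FALSE`.
#' @export
build_scnn <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "scnn_spec"))
  weights <- scnn_init_weights(spec, seed)
  tab <- scnn_param_table(spec)
  # Cross-check the assembled variant's column against the actual arrays.
  col <- if (spec$separable) "params_separable" else "params_standard"
  conv_rows <- match(paste0("Convolution", 1:3), tab$layer)
  for (l in 1:3) {
    actual <- if (spec$separable)
      length(weights[[paste0("dw", l)]]) + length(weights[[paste0("pw", l)]]) +
        length(weights[[paste0("cb", l)]])
    else
      length(weights[[paste0("cw", l)]]) + length(weights[[paste0("cb", l)]])
    stopifnot(actual == tab[[col]][conv_rows[l]])
  }
  structure(list(spec = spec, weights = weights, layers = tab,
                 trained = FALSE, classes = NULL, history = NULL,
                 seed = as.integer(seed)),
            class = "scnn_model")
}

#' @export
print.scnn_model <- function(x, ...) {
  v <- if (x$spec$separable) "separable" else "standard"
  cat(sprintf("<scnn_model> %s convolutions, input (%s), %d classes%s\n",
              v, paste(x$spec$input_shape, collapse = ","), x$spec$n_classes,
              if (x$trained) ", trained" else ""))
  print(x$layers, row.names = FALSE)
  invisible(x)
}

# Forward pass; returns caches when train = TRUE (for backprop).
# x: (H, W, B, depth).
scnn_forward <- function(w, spec, x, train = FALSE) {
  cache <- list()
  conv <- function(x, l) {
    if (spec$separable) {
      dwo <- dw_conv_fwd(x, w[[paste0("dw", l)]])
      pw <- mm_conv_fwd(dwo, w[[paste0("pw", l)]], w[[paste0("cb", l)]])
      cache[[paste0("c", l)]] <<- list(x = x, xmat = pw$xmat)
      pw$out
    } else {
      xc <- im2col3(x)
      pw <- mm_conv_fwd(xc, w[[paste0("cw", l)]], w[[paste0("cb", l)]])
      cache[[paste0("c", l)]] <<- list(in_dim = dim(x), xmat = pw$xmat)
      pw$out
    }
  }
  r1 <- relu_fwd(conv(x, 1L)); cache$r1 <- r1$mask
  dr1 <- dropout_fwd(r1$out, spec$dropout_rate, train); cache$d1 <- dr1$mask
  r2 <- relu_fwd(conv(dr1$out, 2L)); cache$r2 <- r2$mask
  p1 <- maxpool_fwd(r2$out); cache$p1 <- p1
  r3 <- relu_fwd(conv(p1$out, 3L)); cache$r3 <- r3$mask
  zp <- zeropad_w_fwd(r3$out)
  p2 <- maxpool_fwd(zp); cache$p2 <- p2
  B <- dim(p2$out)[3]
  cache$flat_dim <- dim(p2$out)
  fm <- flatten_fwd(p2$out)                    # (B, flat_dim)
  dr2 <- dropout_fwd(fm, spec$dropout_rate, train); cache$d2 <- dr2$mask
  cache$fm <- dr2$out
  r4 <- relu_fwd(dr2$out %*% w$wd + rep(w$bd, each = B)); cache$r4 <- r4$mask
  cache$h4 <- r4$out
  logits <- r4$out %*% w$wo + rep(w$bo, each = B)
  list(logits = logits, cache = if (train) cache else NULL)
}

scnn_backward <- function(w, spec, x, cache, dlogits) {
  g <- list()
  g$wo <- crossprod(cache$h4, dlogits)
  g$bo <- colSums(dlogits)
  dh4 <- tcrossprod(dlogits, w$wo) * cache$r4
  g$wd <- crossprod(cache$fm, dh4)
  g$bd <- colSums(dh4)
  dfm <- tcrossprod(dh4, w$wd)
  if (!is.null(cache$d2)) dfm <- dfm * cache$d2
  dflat <- flatten_bwd(dfm, cache$flat_dim)
  dzp <- maxpool_bwd(cache$p2, dflat)
  dr3 <- zeropad_w_bwd(dzp) * cache$r3
  conv_bwd <- function(l, dout, need_dx = TRUE) {
    cc <- cache[[paste0("c", l)]]
    if (spec$separable) {
      mm <- mm_conv_bwd(cc$xmat, dout, w[[paste0("pw", l)]])
      g[[paste0("pw", l)]] <<- mm$dw
      g[[paste0("cb", l)]] <<- mm$db
      ddwo <- from_mat(mm$dxmat, dim(dout)[1], dim(dout)[2], dim(dout)[3])
      dw <- dw_conv_bwd(cc$x, ddwo, w[[paste0("dw", l)]], need_dx = need_dx)
      g[[paste0("dw", l)]] <<- dw$dw
      dw$dx
    } else {
      mm <- mm_conv_bwd(cc$xmat, dout, w[[paste0("cw", l)]])
      g[[paste0("cw", l)]] <<- mm$dw
      g[[paste0("cb", l)]] <<- mm$db
      if (!need_dx) return(NULL)
      dcol <- from_mat(mm$dxmat, dim(dout)[1], dim(dout)[2], dim(dout)[3])
      col2im3(dcol, cc$in_dim[1], cc$in_dim[2], cc$in_dim[4])
    }
  }
  dp1 <- conv_bwd(3L, dr3)
  dr2 <- maxpool_bwd(cache$p1, dp1) * cache$r2
  dd1 <- conv_bwd(2L, dr2)
  if (!is.null(cache$d1)) dd1 <- dd1 * cache$d1
  dr1 <- dd1 * cache$r1
  conv_bwd(1L, dr1, need_dx = FALSE)
  g
}

# images: (n, H, W, depth) -> internal (H, W, n, depth)
stack_to_internal <- function(images) {
  stopifnot(length(dim(images)) == 4L)
  aperm(images, c(2L, 3L, 1L, 4L))
}

#' Train the stage-2 network
#'
#' Fits the network on mode-stacked window images with minibatch Adam
#' (batch size 256 by default), categorical cross-entropy, and early
#' stopping on validation loss with best-weight restore. A fixed seed fixes
#' the weight initialization, the train/validation split, the shuffling and
#' the dropout masks.
#'
#' @param images Numeric array `(n, height, width, depth)` of window images
#'   (e.g. MVMD mode stacks, depth = K, or the low-frequency mode, depth 1).
#' @param labels Integer gesture ids, length `n` (>= 2 distinct values).
#' @param spec An [scnn_spec()]; `NULL` derives one from the image
#'   dimensions and label set.
#' @param config An [emg_config()] supplying epochs, batch size, learning
#'   rate, patience, validation fraction and seed.
#' @return A trained `scnn_model` with `classes` (gesture id of each softmax
#'   unit) and `history` (per-epoch loss/accuracy data.frame).
#' @export
train_stage2 <- function(images, labels, spec = NULL, config = emg_config()) {
  stopifnot(length(dim(images)) == 4L, dim(images)[1] == length(labels))
  if (!all(is.finite(images))) stop("images must be finite", call. = FALSE)
  classes <- sort(unique(as.integer(labels)))
  if (length(classes) < 2L)
    stop("training needs at least 2 classes", call. = FALSE)
  if (is.null(spec)) {
    spec <- scnn_spec(input_shape = dim(images)[2:4],
                      n_classes = length(classes))
  } else if (spec$n_classes != length(classes)) {
    stop(sprintf("spec error: spec$n_classes = %d but %d classes present",
                 spec$n_classes, length(classes)), call. = FALSE)
  }
  y <- match(as.integer(labels), classes)
  x_all <- stack_to_internal(images)
  n <- length(y)
  set.seed(config$seed)
  w <- scnn_init_weights(spec, config$seed)
  perm <- sample.int(n)
  n_val <- min(n - 2L, round(config$val_fraction * n))
  val_idx <- if (n_val >= 2L) perm[seq_len(n_val)] else integer(0)
  tr_idx <- setdiff(perm, val_idx)
  state <- adam_init(w)
  best <- list(loss = Inf, w = w, epoch = 0L)
  wait <- 0L
  hist <- list()
  eval_split <- function(idx) {
    fw <- scnn_forward(w, spec, x_all[, , idx, , drop = FALSE], train = FALSE)
    sm <- softmax_ce(fw$logits, y[idx])
    c(loss = sm$loss,
      acc = mean(max.col(sm$probs, ties.method = "first") == y[idx]))
  }
  for (epoch in seq_len(config$epochs)) {
    ord <- tr_idx[sample.int(length(tr_idx))]
    bstarts <- seq(1L, length(ord), by = config$batch_size)
    ep_loss <- ep_acc <- 0
    for (bs in bstarts) {
      bi <- ord[bs:min(bs + config$batch_size - 1L, length(ord))]
      xb <- x_all[, , bi, , drop = FALSE]
      fw <- scnn_forward(w, spec, xb, train = TRUE)
      sm <- softmax_ce(fw$logits, y[bi])
      g <- scnn_backward(w, spec, xb, fw$cache, sm$dlogits)
      up <- adam_step(w, g, state, config$learning_rate)
      w <- up$params; state <- up$state
      ep_loss <- ep_loss + sm$loss * length(bi)
      ep_acc <- ep_acc +
        sum(max.col(sm$probs, ties.method = "first") == y[bi])
    }
    ep_loss <- ep_loss / length(ord)
    ep_acc <- ep_acc / length(ord)
    if (length(val_idx)) {
      vm <- eval_split(val_idx)
      monitor <- vm[["loss"]]
    } else {
      vm <- c(loss = NA_real_, acc = NA_real_)
      monitor <- ep_loss
    }
    hist[[epoch]] <- data.frame(epoch = epoch, loss = ep_loss, acc = ep_acc,
                                val_loss = vm[["loss"]], val_acc = vm[["acc"]])
    if (monitor < best$loss - 1e-9) {
      best <- list(loss = monitor, w = w, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  structure(list(spec = spec, weights = best$w, layers = scnn_param_table(spec),
                 trained = TRUE, classes = classes,
                 history = do.call(rbind, hist), best_epoch = best$epoch,
                 seed = config$seed),
            class = "scnn_model")
}

#' Predict gestures with a trained stage-2 network
#' @param object A trained `scnn_model`.
#' @param images Array `(n, height, width, depth)`.
#' @param type `"class"` for gesture ids, `"prob"` for the softmax matrix.
#' @param ... Unused.
#' @return Integer gesture ids or a probability matrix.
#' @export
predict.scnn_model <- function(object, images, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (!object$trained && is.null(object$classes))
    object$classes <- seq_len(object$spec$n_classes)
  x <- stack_to_internal(images)
  # Chunked forward pass to bound memory on large inputs.
  n <- dim(x)[3]
  probs <- NULL
  for (bs in seq(1L, n, by = 512L)) {
    bi <- bs:min(bs + 511L, n)
    fw <- scnn_forward(object$weights, object$spec,
                       x[, , bi, , drop = FALSE], train = FALSE)
    z <- fw$logits - apply(fw$logits, 1L, max)
    p <- exp(z) / rowSums(exp(z))
    probs <- rbind(probs, p)
  }
  if (type == "prob") {
    colnames(probs) <- object$classes
    return(probs)
  }
  object$classes[max.col(probs, ties.method = "first")]
}
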