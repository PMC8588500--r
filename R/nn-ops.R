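# Array primitives for the stage-2 network. Feature maps are stored as
# (H, W, B, C) arrays (height = time samples, width = electrode channels,
# B = batch, C = feature channels); with channels last, the im2col matrix
# view needed by the BLAS matrix multiply is a zero-copy reshape. Depthwise
# 3x3 convolution is computed by shift-and-add over the 9 kernel offsets;
# pointwise (1x1) and standard 3x3 convolutions reduce to one matrix
# multiply.

# Valid target/source row+col ranges for an offset (di, dj) under zero 'same'
# padding: target (ri, rj) reads source (ri + di, rj + dj).
shift_ranges <- function(H, W, di, dj) {
  list(ri = max(1L, 1L - di):min(H, H - di),
       rj = max(1L, 1L - dj):min(W, W - dj))
}

# x: (H,W,B,C); w: (3,3,C). 'same' zero padding. Compiled hot loop.
dw_conv_fwd <- function(x, w) {
  dw_conv_fwd_cpp(x, w, dim(x))
}

# need_dx = FALSE skips the input gradient (first layer).
dw_conv_bwd <- function(x, dout, w, need_dx = TRUE) {
  dw_conv_bwd_cpp(x, dout, w, dim(x), need_dx)
}

# (H,W,B,C) <-> matrix (H*W*B, C): plain dim changes, no copy.
to_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2] * d[3], d[4])
  x
}

from_mat <- function(m, H, W, B) {
  dim(m) <- c(H, W, B, ncol(m))
  m
}

# Stack the 9 shifted copies channel-wise: (H,W,B,9C).
im2col3 <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; B <- d[3]; C <- d[4]
  out <- array(0, c(H, W, B, 9L * C))
  blk <- 0L
  for (dj in -1:1) for (di in -1:1) {
    r <- shift_ranges(H, W, di, dj)
    out[r$ri, r$rj, , blk * C + seq_len(C)] <-
      x[r$ri + di, r$rj + dj, , , drop = FALSE]
    blk <- blk + 1L
  }
  out
}

col2im3 <- function(dcol, H, W, C) {
  d <- dim(dcol); B <- d[3]
  dx <- array(0, c(H, W, B, C))
  blk <- 0L
  for (dj in -1:1) for (di in -1:1) {
    r <- shift_ranges(H, W, di, dj)
    dx[r$ri + di, r$rj + dj, , ] <- dx[r$ri + di, r$rj + dj, , , drop = FALSE] +
      dcol[r$ri, r$rj, , blk * C + seq_len(C), drop = FALSE]
    blk <- blk + 1L
  }
  dx
}

# Pointwise core shared by 1x1 and (via im2col) 3x3 standard convolution.
# w: (C_in, N); b: length N.
mm_conv_fwd <- function(x, w, b) {
  d <- dim(x)
  m <- to_mat(x)
  y <- m %*% w
  y <- y + rep(b, each = nrow(y))
  list(out = from_mat(y, d[1], d[2], d[3]), xmat = m)
}

mm_conv_bwd <- function(cache_xmat, dout, w) {
  dm <- to_mat(dout)
  list(dw = crossprod(cache_xmat, dm),
       db = colSums(dm),
       dxmat = tcrossprod(dm, w))
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(out = x * mask, mask = mask)
}

dropout_fwd <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(out = x, mask = NULL))
  mask <- (stats::runif(length(x)) >= rate) / (1 - rate)
  dim(mask) <- dim(x)
  list(out = x * mask, mask = mask)
}

# 2x2 max pooling, stride 2, floor semantics (trailing odd row/col dropped).
maxpool_fwd <- function(x) {
  d <- dim(x); Ho <- d[1] %/% 2L; Wo <- d[2] %/% 2L
  ri <- seq_len(Ho) * 2L - 1L
  rj <- seq_len(Wo) * 2L - 1L
  a <- list(x[ri, rj, , , drop = FALSE],      x[ri + 1L, rj, , , drop = FALSE],
            x[ri, rj + 1L, , , drop = FALSE], x[ri + 1L, rj + 1L, , , drop = FALSE])
  m <- pmax(a[[1]], a[[2]], a[[3]], a[[4]])
  s1 <- a[[1]] == m
  s2 <- a[[2]] == m & !s1
  s3 <- a[[3]] == m & !(s1 | s2)
  s4 <- !(s1 | s2 | s3)
  list(out = m, sel = list(s1, s2, s3, s4), in_dim = d)
}

maxpool_bwd <- function(cache, dout) {
  d <- cache$in_dim
  Ho <- d[1] %/% 2L; Wo <- d[2] %/% 2L
  ri <- seq_len(Ho) * 2L - 1L
  rj <- seq_len(Wo) * 2L - 1L
  dx <- array(0, d)
  dx[ri, rj, , ]           <- dout * cache$sel[[1]]
  dx[ri + 1L, rj, , ]      <- dout * cache$sel[[2]]
  dx[ri, rj + 1L, , ]      <- dout * cache$sel[[3]]
  dx[ri + 1L, rj + 1L, , ] <- dout * cache$sel[[4]]
  dx
}

# Zero-pad one column on each side of the width (electrode) axis.
zeropad_w_fwd <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1], d[2] + 2L, d[3], d[4]))
  out[, 2L:(d[2] + 1L), , ] <- x
  out
}

zeropad_w_bwd <- function(dout) {
  d <- dim(dout)
  dout[, 2L:(d[2] - 1L), , , drop = FALSE]
}

# (H,W,B,C) -> (B, H*W*C) and back, consistent ordering.
flatten_fwd <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(3L, 1L, 2L, 4L))
  dim(m) <- c(d[3], d[1] * d[2] * d[4])
  m
}

flatten_bwd <- function(dm, in_dim) {
  dim(dm) <- c(in_dim[3], in_dim[1], in_dim[2], in_dim[4])
  aperm(dm, c(2L, 3L, 1L, 4L))
}

# logits: (B, n_classes); y: integer class index 1..n.
softmax_ce <- function(logits, y) {
  z <- logits - apply(logits, 1L, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  B <- nrow(p)
  idx <- cbind(seq_len(B), y)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, probs = p, dlogits = dlogits / B)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
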