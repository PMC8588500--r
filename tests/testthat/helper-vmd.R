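# Independent univariate VMD oracle, written in the textbook full-spectrum
# style (centered frequency axis, negative half zeroed) rather than the
# package's one-sided formulation; used to cross-check the single-channel
# reduction of the multivariate decomposition.
vmd_oracle <- function(x, K, alpha, tau = 0, tol = 1e-7, max_iter = 500,
                       omega_init = NULL) {
  Tn <- length(x)
  half <- Tn %/% 2
  xm <- c(rev(x[1:half]), x, rev(x[(Tn - half + 1):Tn]))
  Tm <- length(xm)
  freqs <- (seq_len(Tm) - 1) / Tm        # 0 .. 1-1/Tm
  freqs[freqs >= 0.5] <- freqs[freqs >= 0.5] - 1   # centered axis
  f_hat <- fft(xm)
  f_hat_plus <- f_hat
  f_hat_plus[freqs < 0] <- 0
  if (is.null(omega_init)) omega_init <- 0.5 * (seq_len(K) - 0.5) / K
  omega <- omega_init
  U <- matrix(0i, Tm, K)
  lambda <- rep(0i, Tm)
  pos <- freqs >= 0
  for (it in seq_len(max_iter)) {
    U_old <- U
    S <- rowSums(U)
    for (k in seq_len(K)) {
      S <- S - U[, k]
      Unew <- (f_hat_plus - S + lambda / 2) / (1 + 2 * alpha * (freqs - omega[k])^2)
      Unew[!pos] <- 0
      U[, k] <- Unew
      S <- S + Unew
      pw <- Mod(Unew[pos])^2
      if (sum(pw) > 0) omega[k] <- sum(freqs[pos] * pw) / sum(pw)
    }
    if (tau > 0) lambda <- lambda + tau * (f_hat_plus - S)
    dnum <- 0
    for (k in seq_len(K)) {
      dk <- sum(Mod(U[, k] - U_old[, k])^2)
      den <- sum(Mod(U_old[, k])^2)
      if (den > 0) dnum <- dnum + dk / den else if (dk > 0) dnum <- dnum + Inf
    }
    if (dnum < tol) break
  }
  modes <- matrix(0, Tn, K)
  for (k in seq_len(K)) {
    Ff <- U[, k]
    # hermitian symmetrization of the one-sided spectrum
    full <- Ff
    idx <- which(freqs > 0)
    full[Tm + 2 - idx] <- Conj(Ff[idx])
    ut <- Re(fft(full, inverse = TRUE)) / Tm
    modes[, k] <- ut[(half + 1):(half + Tn)]
  }
  ord <- order(omega)
  list(modes = modes[, ord, drop = FALSE], omega = omega[ord])
}
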