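#' MVMD settings
#'
#' @param K Number of modes (>= 1).
#' @param alpha Bandwidth penalty weighting the quadratic distance of each
#'   mode's spectrum from its center frequency (larger = narrower modes).
#' @param tau Dual-ascent step for the Lagrange multiplier; 0 disables exact
#'   reconstruction enforcement, which is the robust choice for noisy data.
#' @param tol Relative squared-change convergence threshold.
#' @param max_iter Iteration cap.
#' @param init Center-frequency initialization: `"uniform"` (midpoints of a
#'   uniform grid over (0, 0.5) normalized frequency), `"octave"`
#'   (geometric), or `"random"`.
#' @param seed Seed, used only for `init = "random"`.
#' @return An `mvmd_settings` list.
#' @export
mvmd_settings <- function(K = 4L, alpha = 2000, tau = 0, tol = 1e-7,
                          max_iter = 500L, init = c("uniform", "octave", "random"),
                          seed = 1L) {
  init <- match.arg(init)
  stopifnot(K >= 1L, alpha > 0, tau >= 0, tol > 0, max_iter >= 1L)
  structure(list(K = as.integer(K), alpha = alpha, tau = tau, tol = tol,
                 max_iter = as.integer(max_iter), init = init,
                 seed = as.integer(seed)), class = "mvmd_settings")
}

mvmd_init_omega <- function(K, init, seed) {
  switch(init,
         uniform = 0.5 * (seq_len(K) - 0.5) / K,
         octave = 0.5 / 2^(K + 1L - seq_len(K)),
         random = {
           set.seed(seed)
           sort(stats::runif(K, 0, 0.5))
         })
}

#' Multivariate variational mode decomposition
#'
#' Decomposes a multichannel signal into `K` narrow-band multivariate
#' oscillations with one joint center frequency per mode. The constrained
#' bandwidth-minimization problem is solved by ADMM in the one-sided
#' frequency domain: per channel, each mode is updated by Wiener filtering
#' the signal residual around the mode's current center frequency
#' (successive/Gauss-Seidel over modes), the shared center frequency is the
#' power-weighted mean frequency pooled over channels, and a Lagrange
#' multiplier enforces reconstruction when `tau > 0`. Iteration stops when
#' the summed relative squared change of all mode spectra falls below `tol`.
#'
#' The signal is mirror-extended by half its length on each side before the
#' FFT and the central portion is returned, which suppresses boundary
#' splitting artifacts.
#'
#' @param x An [emg_recording()] or a numeric matrix (samples x channels).
#' @param settings An [mvmd_settings()].
#' @param fs Sampling rate in Hz (taken from the recording when given one).
#' @return A `mode_tensor`: `modes` (K x samples x channels, sorted by
#'   ascending center frequency), `center_freqs` (Hz), `residual`
#'   (`x - sum(modes)`), `n_iterations`, `converged`, `objective_trace`
#'   (bandwidth objective per iteration), `fs`.
#' @examples
#' t <- seq(0, 2, by = 0.01)[-1]
#' x <- cbind(cos(2 * pi * 10 * t), 0.5 * cos(2 * pi * 10 * t))
#' mt <- mvmd_decompose(x, mvmd_settings(K = 1), fs = 100)
#' mt$center_freqs
#' @export
mvmd_decompose <- function(x, settings = mvmd_settings(), fs = NULL) {
  if (inherits(x, "emg_recording")) {
    fs <- x$fs
    x <- x$signal
  }
  if (is.null(fs)) stop("fs required when x is a plain matrix", call. = FALSE)
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("MVMD input must be finite-valued", call. = FALSE)
  Tn <- nrow(x); C <- ncol(x); K <- settings$K
  if (Tn < 2L * K)
    stop("need at least 2*K samples for a K-mode decomposition", call. = FALSE)

  half <- Tn %/% 2L
  xm <- rbind(x[half:1L, , drop = FALSE], x,
              x[Tn:(Tn - half + 1L), , drop = FALSE])
  Tm <- nrow(xm)
  nb <- Tm %/% 2L + 1L                       # one-sided bins, omega in [0, 0.5]
  omega_grid <- (seq_len(nb) - 1L) / Tm
  Xf <- stats::mvfft(xm)[seq_len(nb), , drop = FALSE]

  U <- array(0i, dim = c(nb, C, K))
  lambda <- matrix(0i, nb, C)
  omega <- mvmd_init_omega(K, settings$init, settings$seed)
  obj_trace <- numeric(0)
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(settings$max_iter)) {
    n_iter <- it
    U_old <- U
    S <- matrix(0i, nb, C)                   # running sum of current iterates
    for (k in seq_len(K)) S <- S + U[, , k]
    for (k in seq_len(K)) {
      S <- S - U[, , k]
      denom <- 1 + 2 * settings$alpha * (omega_grid - omega[k])^2
      Unew <- (Xf - S + lambda / 2) / denom
      U[, , k] <- Unew
      S <- S + Unew
      pw <- Re(Unew * Conj(Unew))            # |u|^2 per bin x channel
      den <- sum(pw)
      if (den > 0) omega[k] <- sum(omega_grid * rowSums(pw)) / den
    }
    if (settings$tau > 0) lambda <- lambda + settings$tau * (Xf - S)
    obj_trace <- c(obj_trace, mvmd_objective(U, omega, omega_grid))
    num <- den <- 0
    for (k in seq_len(K)) {
      dk <- U[, , k] - U_old[, , k]
      num_k <- sum(Re(dk * Conj(dk)))
      den_k <- sum(Re(U_old[, , k] * Conj(U_old[, , k])))
      if (den_k > 0) {
        num <- num + num_k / den_k
      } else if (num_k > 0) {
        num <- num + Inf
      }
    }
    if (num < settings$tol) {
      converged <- TRUE
      break
    }
  }

  # Back to time domain: hermitian-symmetric full spectrum, crop the mirror.
  modes <- array(0, dim = c(K, Tn, C))
  keep <- (half + 1L):(half + Tn)
  for (k in seq_len(K)) {
    Ff <- matrix(0i, Tm, C)
    Ff[seq_len(nb), ] <- U[, , k]
    if (nb > 2L) {
      mid <- 2L:(nb - 1L)
      Ff[Tm + 2L - mid, ] <- Conj(U[mid, , k])
    }
    if (Tm %% 2L == 0L) Ff[nb, ] <- Re(U[nb, , k])  # real Nyquist bin
    ut <- Re(stats::mvfft(Ff, inverse = TRUE)) / Tm
    modes[k, , ] <- ut[keep, , drop = FALSE]
  }
  ord <- order(omega)
  modes <- modes[ord, , , drop = FALSE]
  omega <- omega[ord]
  recon <- apply(modes, c(2, 3), sum)
  structure(list(modes = modes,
                 center_freqs = omega * fs,
                 residual = x - recon,
                 n_iterations = n_iter,
                 converged = converged,
                 objective_trace = obj_trace,
                 fs = fs),
            class = "mode_tensor")
}

# Bandwidth objective: sum_k sum_c integral (omega - omega_k)^2 |u_hat|^2.
mvmd_objective <- function(U, omega, omega_grid) {
  K <- dim(U)[3]
  tot <- 0
  for (k in seq_len(K)) {
    pw <- Re(U[, , k] * Conj(U[, , k]))
    tot <- tot + sum((omega_grid - omega[k])^2 * pw)
  }
  tot
}

#' @export
print.mode_tensor <- function(x, ...) {
  cat(sprintf("<mode_tensor> K=%d modes, %d samples x %d channels @ %g Hz\n",
              dim(x$modes)[1], dim(x$modes)[2], dim(x$modes)[3], x$fs))
  cat("  center frequencies (Hz):",
      paste(sprintf("%.3f", x$center_freqs), collapse = ", "), "\n")
  cat(sprintf("  %d iterations, converged: %s\n", x$n_iterations, x$converged))
  invisible(x)
}

#' Reconstruct the signal from a mode tensor
#' @param mt A `mode_tensor`.
#' @param include_residual Add the stored residual (gives the original signal
#'   to floating tolerance).
#' @return Numeric matrix samples x channels.
#' @export
reconstruct <- function(mt, include_residual = TRUE) {
  stopifnot(inherits(mt, "mode_tensor"))
  out <- apply(mt$modes, c(2, 3), sum)
  if (include_residual) out <- out + mt$residual
  out
}

#' The lowest-frequency mode ("modified EMG")
#'
#' Returns the mode with the smallest center frequency — the component that
#' carries most of the movement-related information and serves as the
#' stage-2 network input in the single-mode variant.
#'
#' @param mt A `mode_tensor`.
#' @return Numeric matrix samples x channels.
#' @export
low_frequency_mode <- function(mt) {
  stopifnot(inherits(mt, "mode_tensor"))
  k <- which.min(mt$center_freqs)
  mt$modes[k, , , drop = TRUE]
}

#' One-sided periodogram of a single mode channel
#'
#' Power scaled so that the one-sided sum equals the mode's time-domain
#' energy `sum(u^2)` (Parseval).
#'
#' @param mt A `mode_tensor`.
#' @param k Mode index.
#' @param c Channel index.
#' @return List with `freqs` (Hz) and `power`.
#' @export
mode_spectrum <- function(mt, k, c) {
  stopifnot(inherits(mt, "mode_tensor"))
  d <- dim(mt$modes)
  if (k < 1L || k > d[1] || c < 1L || c > d[3])
    stop("mode or channel index out of range", call. = FALSE)
  u <- mt$modes[k, , c]
  n <- length(u)
  X <- stats::fft(u)
  nb <- n %/% 2L + 1L
  pw <- Mod(X[seq_len(nb)])^2 / n
  dbl <- 2L:(if (n %% 2L == 0L) nb - 1L else nb)
  pw[dbl] <- 2 * pw[dbl]
  list(freqs = (seq_len(nb) - 1L) / n * mt$fs, power = pw)
}
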