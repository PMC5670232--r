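# Low-level numeric helpers shared across modules.

#' Analytic signal via the frequency-domain Hilbert method
#'
#' Returns the complex analytic signal whose modulus is the instantaneous
#' amplitude envelope of `x`.
#'
#' @param x Numeric vector (a real-valued signal).
#' @return Complex vector of the same length.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) abort("signal too short for an analytic transform")
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# FFT-based linear convolution, "same" alignment with a centered kernel.
# For a symmetric (linear-phase) kernel this is a single zero-phase pass.
conv_same <- function(kernel, x) {
  nk <- length(kernel)
  nx <- length(x)
  nfft <- stats::nextn(nx + nk - 1L, 2)
  y <- Re(fft(fft(c(kernel, numeric(nfft - nk))) *
               fft(c(x, numeric(nfft - nx))), inverse = TRUE)) / nfft
  half <- (nk - 1L) %/% 2L
  y[(half + 1L):(half + nx)]
}

#' Zero-phase FIR filtering
#'
#' Applies a linear-phase FIR filter forward and backward (the zero-phase
#' scheme), so the effective magnitude response is the square of the
#' single-pass design and phase distortion is nil. Edges are handled by
#' reflection padding.
#'
#' @param b FIR coefficients (odd length, symmetric).
#' @param x Numeric vector.
#' @return Filtered vector, same length as `x`.
#' @keywords internal
fir_filtfilt <- function(b, x) {
  nb <- length(b)
  nx <- length(x)
  if (nx <= 3L * nb) abort("recording shorter than 3 x filter order")
  np <- min(3L * nb, nx - 1L)
  xp <- c(2 * x[1] - x[(np + 1L):2L], x,
          2 * x[nx] - x[(nx - 1L):(nx - np)])
  y <- conv_same(b, conv_same(b, xp))
  y[(np + 1L):(np + nx)]
}

# One-FFT-round zero-phase filter bank. Each FIR design is applied as its
# forward-backward (magnitude-squared) frequency response; responses multiply,
# so a whole bank costs one forward FFT plus one inverse FFT per output.
# Reflection padding keeps the circular wrap-around inside the pad region.
# With `analytic = TRUE` the Hilbert multiplier is fused in and the complex
# analytic band signal is returned.
fft_zero_phase_bank <- function(x, filters, analytic = FALSE,
                                combine = FALSE, resp = NULL) {
  nb <- max(vapply(filters, length, integer(1)))
  nx <- length(x)
  if (nx <= 3L * nb) abort("recording shorter than 3 x filter order")
  np <- min(3L * nb, nx - 1L)
  xp <- c(2 * x[1] - x[(np + 1L):2L], x,
          2 * x[nx] - x[(nx - 1L):(nx - np)])
  nfft <- stats::nextn(length(xp), 2)
  X <- fft(c(xp, numeric(nfft - length(xp))))
  if (is.null(resp)) resp <- bank_responses(filters, nfft, combine)
  h <- NULL
  if (analytic) {
    h <- numeric(nfft)
    h[1] <- 1; h[nfft / 2 + 1] <- 1
    h[2:(nfft / 2)] <- 2
  }
  keep <- (np + 1L):(np + nx)
  out <- lapply(resp, function(r) {
    if (analytic) {
      (fft(X * r * h, inverse = TRUE) / nfft)[keep]
    } else {
      Re(fft(X * r, inverse = TRUE) / nfft)[keep]
    }
  })
  if (length(out) == 1L) out[[1]] else out
}

# magnitude-squared (forward-backward) responses of a filter bank on an
# nfft grid; shared across channels of equal length
bank_responses <- function(filters, nfft, combine = FALSE) {
  resp <- lapply(filters, function(b)
    Mod(fft(c(b, numeric(nfft - length(b)))))^2)
  if (combine) resp <- list(Reduce(`*`, resp))
  resp
}

# nfft used by fft_zero_phase_bank for a signal of length nx
bank_nfft <- function(nx, nb) {
  np <- min(3L * nb, nx - 1L)
  stats::nextn(nx + 2L * np, 2)
}

#' Smooth a trace with a unit-area triangular window
#'
#' Convolution with a symmetric triangular kernel of the given width. Near the
#' edges the kernel is renormalized over its valid support, so a constant
#' trace is returned unchanged everywhere.
#'
#' @param trace Numeric vector.
#' @param width_ms Kernel width in milliseconds (base of the triangle).
#' @param rate Sampling rate in Hz.
#' @return Smoothed vector, same length as `trace`.
#' @export
#' @examples
#' smooth_triangular(c(0, 0, 1, 0, 0), width_ms = 5000, rate = 1000)
smooth_triangular <- function(trace, width_ms, rate) {
  n <- length(trace)
  w <- round(width_ms / 1000 * rate)
  if (w < 2L) abort("triangular width must span at least 2 samples")
  if (w > n) abort("triangular width exceeds trace length")
  if (w %% 2 == 0) w <- w + 1L  # symmetric kernel needs odd support
  half <- (w - 1L) %/% 2L
  k <- (half + 1L) - abs(seq(-half, half))
  k <- k / sum(k)
  num <- conv_same(k, trace)
  # edge renormalization: divide by the local kernel mass actually inside
  mass <- conv_same(k, rep(1, n))
  num / mass
}

# derive a child seed from a parent seed and a stage label (stays < 2^31)
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) %% 1000003L) * 1009L + (h %% 9973L)
}

# dB of an amplitude ratio (the convention used throughout: 10*log10)
amp_db <- function(ratio) 10 * log10(ratio)
db_amp <- function(db) 10^(db / 10)

`%||%` <- function(a, b) if (is.null(a)) b else a
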