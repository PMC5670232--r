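# High-frequency broadband (HFB, high-gamma) amplitude extraction.
#
# The HFB trace is the mean normalized amplitude envelope of 60-160 Hz
# activity, computed in five 20-Hz sub-bands so that the 1/f spectral decay
# does not let the lowest band dominate: (1) zero-phase FIR band-pass per
# band; (2) envelope = |analytic signal|; (3) each band envelope divided by
# its own mean; (4) average of the normalized envelopes; (5) rescaled by the
# mean amplitude across bands, back into volts.

#' Default HFB band specification
#'
#' @param bands Two-column matrix of band edges in Hz (default the five
#'   contiguous 20-Hz bands spanning 60-160 Hz).
#' @param filter_order FIR order (default 138).
#' @return A `band_spec` list.
#' @export
band_spec <- function(bands = cbind(seq(60, 140, 20), seq(80, 160, 20)),
                      filter_order = 138) {
  bands <- as.matrix(bands)
  if (any(bands[, 2] <= bands[, 1])) abort("band edges must be increasing")
  if (nrow(bands) > 1 && any(bands[-1, 1] != bands[-nrow(bands), 2]))
    abort("bands must be contiguous and non-overlapping")
  structure(list(bands = bands, filter_order = filter_order,
                 window_type = "hamming"),
            class = "band_spec")
}

new_hfb_signal <- function(amplitude, rate, state, runs = NULL, t0 = 0) {
  structure(list(amplitude = amplitude, rate = rate, state = state,
                 runs = runs, t0 = t0),
            class = "hfb_signal")
}

#' @export
print.hfb_signal <- function(x, ...) {
  cat("<hfb_signal>", ncol(x$amplitude), "electrodes x", nrow(x$amplitude),
      sprintf("samples @ %g Hz, state = %s\n", x$rate, x$state))
  invisible(x)
}

#' Extract the HFB amplitude envelope
#'
#' Runs the five-step band-bank procedure on every channel. Samples flagged
#' in `mask` are excluded from the per-band means of steps 3 and 5 but remain
#' in the output trace, preserving event alignment.
#'
#' @param recording A preprocessed `ecog_recording`.
#' @param spec A [band_spec()].
#' @param mask Optional `artifact_mask`.
#' @return An `hfb_signal` in state `"volts"` (same length as the input).
#' @export
hfb_amplitude <- function(recording, spec = band_spec(), mask = NULL) {
  rate <- recording$rate
  nyq <- rate / 2
  if (max(spec$bands) >= nyq * 0.96)
    abort("sampling rate too low for the requested bands")
  if (!all(is.finite(recording$data))) abort("NaNs in input")
  if (n_samples(recording) < 3 * spec$filter_order)
    abort("recording shorter than 3 x filter order")
  keep <- if (is.null(mask)) rep(TRUE, n_samples(recording)) else !mask$excluded

  filters <- lapply(seq_len(nrow(spec$bands)), function(b) {
    as.numeric(signal::fir1(spec$filter_order, spec$bands[b, ] / nyq,
                            type = "pass"))
  })
  out <- matrix(0, n_samples(recording), ncol(recording$data))
  colnames(out) <- recording$channel_ids
  # cosine taper over one filter length at each end: filter edge transients
  # otherwise bleed through the global Hilbert step into quiet bands
  ntap <- spec$filter_order + 1L
  taper <- rep(1, n_samples(recording))
  ramp <- 0.5 - 0.5 * cos(pi * seq_len(ntap) / (ntap + 1))
  taper[seq_len(ntap)] <- ramp
  taper[n_samples(recording) + 1L - seq_len(ntap)] <- ramp
  resp <- bank_responses(filters,
                         bank_nfft(n_samples(recording),
                                   spec$filter_order + 1L))
  for (j in seq_len(ncol(recording$data))) {
    x <- recording$data[, j] * taper
    analytic <- fft_zero_phase_bank(x, filters, analytic = TRUE, resp = resp)
    env_sum <- numeric(length(x))
    band_means <- numeric(length(filters))
    for (b in seq_along(filters)) {
      env <- Mod(analytic[[b]])
      band_means[b] <- mean(env[keep])
      env_sum <- env_sum + env / band_means[b]
    }
    out[, j] <- env_sum / length(filters) * mean(band_means)
  }
  new_hfb_signal(out, rate, "volts", t0 = recording$t0)
}

#' Normalize HFB amplitude to the resting-state geometric mean
#'
#' Divides every sample by the geometric mean amplitude (`exp(mean(log))`)
#' over the unmasked rest-period samples of its run; each run is normalized
#' by its own rest baseline.
#'
#' @param hfb An `hfb_signal` in state `"volts"`.
#' @param runs Run intervals from [run_intervals()] (columns `run`, `start`,
#'   `end`, `rest_start`, `rest_end`).
#' @param mask Optional `artifact_mask`.
#' @param min_rest_s Minimum unmasked rest required per run (default 30 s).
#' @return An `hfb_signal` in state `"rest_ratio"` with `runs` attached.
#' @export
normalize_to_rest <- function(hfb, runs, mask = NULL, min_rest_s = 30) {
  if (hfb$state != "volts") abort("normalize_to_rest expects state 'volts'")
  n <- nrow(hfb$amplitude)
  keep <- if (is.null(mask)) rep(TRUE, n) else !mask$excluded
  out <- hfb$amplitude
  for (r in seq_len(nrow(runs))) {
    rest_idx <- sample_range(runs$rest_start[r], runs$rest_end[r], hfb$rate, n)
    rest_idx <- rest_idx[keep[rest_idx]]
    if (length(rest_idx) < min_rest_s * hfb$rate)
      abort("fewer than the required unmasked rest samples in a run")
    run_idx <- sample_range(runs$start[r], runs$end[r], hfb$rate, n)
    for (j in seq_len(ncol(out))) {
      a <- hfb$amplitude[rest_idx, j]
      if (any(a <= 0)) abort("non-positive amplitudes in rest")
      out[run_idx, j] <- hfb$amplitude[run_idx, j] / exp(mean(log(a)))
    }
  }
  new_hfb_signal(out, hfb$rate, "rest_ratio", runs = runs, t0 = hfb$t0)
}

# sample indices covering [start, end)
sample_range <- function(start, end, rate, n) {
  i0 <- max(1L, floor(start * rate) + 1L)
  i1 <- min(n, ceiling(end * rate))
  i0:i1
}

#' Convert an amplitude-ratio HFB signal to decibels
#'
#' `x -> 10 * log10(x)`; amplitude ratios are close to log-normal, so the dB
#' transform makes them approximately normal for parametric testing.
#'
#' @param hfb An `hfb_signal` in state `"rest_ratio"` or `"prestim_ratio"`,
#'   or a bare numeric vector/matrix of ratios.
#' @return The signal in state `"db"` (or the transformed numeric object).
#' @export
to_db <- function(hfb) {
  if (is.numeric(hfb)) {
    if (any(hfb <= 0)) abort("non-positive input to dB transform")
    return(amp_db(hfb))
  }
  if (!hfb$state %in% c("rest_ratio", "prestim_ratio"))
    abort("to_db expects a ratio-state signal")
  if (any(hfb$amplitude <= 0)) abort("non-positive input to dB transform")
  new_hfb_signal(amp_db(hfb$amplitude), hfb$rate, "db",
                 runs = hfb$runs, t0 = hfb$t0)
}

#' Smooth every electrode trace of an HFB signal
#'
#' @param hfb An `hfb_signal`.
#' @param width_ms Triangular window width (default 1000 ms).
#' @return The smoothed signal (state unchanged).
#' @export
smooth_hfb <- function(hfb, width_ms = 1000) {
  out <- apply(hfb$amplitude, 2, smooth_triangular, width_ms = width_ms,
               rate = hfb$rate)
  dimnames(out) <- dimnames(hfb$amplitude)
  new_hfb_signal(out, hfb$rate, hfb$state, runs = hfb$runs, t0 = hfb$t0)
}
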