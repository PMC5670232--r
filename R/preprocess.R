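# Preprocessing: line-noise removal, common-average re-reference, bad-channel
# rejection, and transient-artifact masking.

#' Remove line noise and its harmonics
#'
#' Applies zero-phase Hamming-windowed FIR band-stop filters at the line
#' frequency and every harmonic below `min(max_hz, Nyquist)`. Each notch is a
#' linear-phase design applied forward and backward, so the passband stays
#' within a fraction of a dB while the notch frequencies are attenuated by
#' tens of dB.
#'
#' @param recording An `ecog_recording`.
#' @param line_hz Line frequency (default 60).
#' @param max_hz Highest harmonic to remove (default `Inf`, i.e. all below
#'   Nyquist).
#' @param halfwidth_hz Half-width of each stop band (default 2 Hz).
#' @param order FIR order of each notch (default 500).
#' @return The filtered recording.
#' @export
notch_line_noise <- function(recording, line_hz = 60, max_hz = Inf,
                             halfwidth_hz = 2, order = 500) {
  nyq <- recording$rate / 2
  if (line_hz >= nyq) abort("line frequency must be below Nyquist")
  harmonics <- seq(line_hz, min(max_hz, nyq - halfwidth_hz - 1e-9), by = line_hz)
  harmonics <- harmonics[harmonics + halfwidth_hz < nyq]
  data <- recording$data
  filters <- lapply(harmonics, function(h)
    as.numeric(signal::fir1(order, c(h - halfwidth_hz, h + halfwidth_hz) / nyq,
                            type = "stop")))
  resp <- bank_responses(filters, bank_nfft(nrow(data), order + 1L),
                         combine = TRUE)
  for (j in seq_len(ncol(data))) {
    data[, j] <- fft_zero_phase_bank(data[, j], filters, combine = TRUE,
                                     resp = resp)
  }
  new_recording(data, recording$rate, recording$channel_ids, recording$t0)
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample, the mean over all non-excluded channels from
#' every channel (excluded channels are kept in the output but do not enter
#' the average).
#'
#' @param recording An `ecog_recording`.
#' @param exclude_ids Channel ids left out of the average (corrupted/bad
#'   channels).
#' @return The re-referenced recording.
#' @export
common_average_reference <- function(recording, exclude_ids = character(0)) {
  keep <- !(recording$channel_ids %in% exclude_ids)
  if (sum(keep) < 2) abort("need at least two channels in the common average")
  avg <- rowMeans(recording$data[, keep, drop = FALSE])
  new_recording(recording$data - avg, recording$rate,
                recording$channel_ids, recording$t0)
}

#' Detect corrupted channels by extreme-tail voltage
#'
#' A channel is rejected when the mean of its absolute voltage over the
#' samples above that channel's own 99th percentile (of absolute voltage)
#' exceeds `thresh_uv`.
#'
#' @param recording An `ecog_recording`.
#' @param thresh_uv Tail-mean threshold in microvolts (default 500).
#' @return Character vector of bad channel ids.
#' @export
detect_bad_channels <- function(recording, thresh_uv = 500) {
  if (n_samples(recording) < 100)
    abort("need at least 100 samples for a 99th percentile")
  tail_means <- apply(abs(recording$data), 2, function(v) {
    q <- quantile(v, 0.99, names = FALSE)
    above <- v > q
    if (!any(above)) return(0)
    mean(v[above])
  })
  recording$channel_ids[tail_means > thresh_uv]
}

#' Detect transient electrical artifacts
#'
#' Flags samples at which at least `frac_channels` of the channels show
#' either an absolute voltage beyond `sd_thresh` standard deviations of that
#' channel (computed over the whole recording) or an absolute voltage
#' gradient beyond `grad_thresh_uv_per_ms`. A window of `window_ms`
#' (centered, so +/- `window_ms`/2) around each flagged sample is marked for
#' exclusion from downstream statistics; the time base is never cut.
#'
#' @param recording An `ecog_recording`.
#' @param sd_thresh SD multiple for the voltage criterion (default 5).
#' @param grad_thresh_uv_per_ms Gradient threshold (default 30 microvolt/ms).
#' @param frac_channels Minimum fraction of channels that must co-express the
#'   outlier (default 0.10).
#' @param window_ms Length of the exclusion window logged around each outlier
#'   event (default 200 ms).
#' @return An `artifact_mask`: list with `bad_channels` (empty here; fill via
#'   [detect_bad_channels()]), logical `excluded` per sample, and `window_ms`.
#' @export
detect_transient_artifacts <- function(recording, sd_thresh = 5,
                                       grad_thresh_uv_per_ms = 30,
                                       frac_channels = 0.10,
                                       window_ms = 200) {
  rate <- recording$rate
  if (window_ms < 1000 / rate) abort("window shorter than one sample period")
  v <- recording$data
  mu <- colMeans(v)
  sdv <- apply(v, 2, sd)
  volt_out <- sweep(abs(sweep(v, 2, mu)), 2, sd_thresh * sdv, `>`)
  grad <- abs(diff(v)) * rate / 1000      # microvolts per ms
  grad <- rbind(grad, grad[nrow(grad), ]) # boundary: forward difference
  grad_out <- grad > grad_thresh_uv_per_ms
  frac <- rowMeans(volt_out | grad_out)
  outlier <- frac >= frac_channels
  half <- round(window_ms / 2 / 1000 * rate)
  excluded <- rep(FALSE, nrow(v))
  for (i in which(outlier)) {
    excluded[max(1L, i - half):min(nrow(v), i + half)] <- TRUE
  }
  structure(list(bad_channels = character(0), excluded = excluded,
                 window_ms = window_ms, rate = rate),
            class = "artifact_mask")
}

#' An all-clear artifact mask
#' @param recording An `ecog_recording` (or an hfb signal) defining length.
#' @return An `artifact_mask` with nothing excluded.
#' @export
empty_mask <- function(recording) {
  n <- if (inherits(recording, "ecog_recording")) n_samples(recording)
       else nrow(recording$amplitude)
  structure(list(bad_channels = character(0), excluded = rep(FALSE, n),
                 window_ms = 0, rate = recording$rate),
            class = "artifact_mask")
}

#' Tidy an artifact mask into exclusion intervals
#'
#' @param x An `artifact_mask`.
#' @param ... Unused.
#' @return Tibble with `start_s`, `end_s` of each contiguous excluded window.
#' @method tidy artifact_mask
#' @export
tidy.artifact_mask <- function(x, ...) {
  r <- rle(x$excluded)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(start_s = (starts[keep] - 1) / x$rate, end_s = ends[keep] / x$rate)
}

#' @export
print.artifact_mask <- function(x, ...) {
  cat(sprintf("<artifact_mask> %.2f%% of samples excluded, %d bad channels\n",
              100 * mean(x$excluded), length(x$bad_channels)))
  invisible(x)
}
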