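# Multichannel raw-voltage container.

#' Construct an ECoG recording
#'
#' @param data Numeric matrix, samples x channels (microvolts).
#' @param rate Sampling rate, Hz.
#' @param channel_ids Unique channel identifiers (default: column names).
#' @param t0 Time of the first sample, seconds (default 0).
#' @return An `ecog_recording` object.
#' @export
new_recording <- function(data, rate, channel_ids = colnames(data), t0 = 0) {
  data <- as.matrix(data)
  if (is.null(channel_ids)) channel_ids <- sprintf("ch%02d", seq_len(ncol(data)))
  if (anyDuplicated(channel_ids)) abort("channel ids must be unique")
  if (length(channel_ids) != ncol(data))
    abort("channel_ids length must match columns")
  if (!is.finite(rate) || rate <= 0) abort("rate must be positive")
  if (!all(is.finite(data))) abort("recording contains non-finite values")
  colnames(data) <- channel_ids
  structure(list(data = data, rate = rate, channel_ids = channel_ids, t0 = t0),
            class = "ecog_recording")
}

#' @export
print.ecog_recording <- function(x, ...) {
  cat("<ecog_recording>", ncol(x$data), "channels x", nrow(x$data),
      sprintf("samples @ %g Hz (%.1f s)\n", x$rate, nrow(x$data) / x$rate))
  invisible(x)
}

# number of samples / duration helpers
n_samples <- function(rec) nrow(rec$data)
rec_times <- function(rec) rec$t0 + (seq_len(nrow(rec$data)) - 1) / rec$rate

# sample index of a time point: sample i covers [ (i-1)/rate, i/rate )
time_to_sample <- function(t, rate, t0 = 0) floor((t - t0) * rate) + 1L
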