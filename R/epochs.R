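# Viewing-stage epoching with pre-stimulus normalization.

#' Epoch the HFB signal around viewing trials
#'
#' Cuts -500..+1750 ms epochs around every stimulus onset and re-expresses
#' them as fractional change: each electrode's epochs in a run are divided by
#' a single scalar, the mean amplitude in the -400..-100 ms pre-stimulus
#' window averaged across all of that run's trials. Trials overlapping the
#' artifact mask are flagged (`clean = FALSE`) but kept.
#'
#' @param hfb An `hfb_signal` in state `"volts"`.
#' @param events Events tibble containing `stimulus` rows.
#' @param mask Optional `artifact_mask`.
#' @param window_s Epoch window, seconds (default `c(-0.5, 1.75)`, inclusive
#'   endpoints).
#' @param baseline_s Pre-stimulus baseline window (default `c(-0.4, -0.1)`).
#' @return An `hfb_epochs` object: `amplitude` array (time x trial x
#'   electrode) in state `"prestim_ratio"`, `times` (s relative to onset),
#'   `trials` tibble (`trial`, `run`, `item_id`, `category`, `onset`,
#'   `clean`), and `electrode_ids`.
#' @export
epoch_viewing <- function(hfb, events, mask = NULL,
                          window_s = c(-0.5, 1.75),
                          baseline_s = c(-0.4, -0.1)) {
  if (hfb$state != "volts") abort("epoch_viewing expects state 'volts'")
  stim <- events %>% filter(.data$event_type == "stimulus") %>%
    arrange(.data$onset)
  if (nrow(stim) == 0) abort("no viewing trials in events")
  rate <- hfb$rate
  n <- nrow(hfb$amplitude)
  rel_idx <- seq(round(window_s[1] * rate), round(window_s[2] * rate))
  times <- rel_idx / rate
  onset_idx <- time_to_sample(stim$onset, rate, hfb$t0)
  if (any(onset_idx + min(rel_idx) < 1) || any(onset_idx + max(rel_idx) > n))
    abort("epochs extend outside the recording")

  keep <- if (is.null(mask)) rep(TRUE, n) else !mask$excluded
  n_el <- ncol(hfb$amplitude)
  arr <- array(NA_real_, c(length(times), nrow(stim), n_el),
               dimnames = list(NULL, NULL, colnames(hfb$amplitude)))
  clean <- logical(nrow(stim))
  for (i in seq_len(nrow(stim))) {
    idx <- onset_idx[i] + rel_idx
    arr[, i, ] <- hfb$amplitude[idx, ]
    clean[i] <- all(keep[idx])
  }

  bsel <- times >= baseline_s[1] & times <= baseline_s[2]
  for (r in unique(stim$run)) {
    tr <- which(stim$run == r)
    for (j in seq_len(n_el)) {
      denom <- mean(arr[bsel, tr, j])  # one scalar per electrode per run
      arr[, tr, j] <- arr[, tr, j] / denom
    }
  }

  structure(
    list(amplitude = arr, times = times, rate = rate, state = "prestim_ratio",
         trials = tibble(trial = seq_len(nrow(stim)), run = stim$run,
                         item_id = stim$item_id, category = stim$category,
                         onset = stim$onset, clean = clean),
         electrode_ids = colnames(hfb$amplitude)),
    class = "hfb_epochs"
  )
}

#' @export
print.hfb_epochs <- function(x, ...) {
  cat("<hfb_epochs>", dim(x$amplitude)[2], "trials x",
      dim(x$amplitude)[1], "samples x", dim(x$amplitude)[3],
      sprintf("electrodes, state = %s\n", x$state))
  invisible(x)
}

# per-trial scalar means over a time window, one matrix trial x electrode
epoch_window_mean <- function(epochs, window_s) {
  sel <- epochs$times >= window_s[1] & epochs$times <= window_s[2]
  apply(epochs$amplitude[sel, , , drop = FALSE], c(2, 3), mean)
}
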