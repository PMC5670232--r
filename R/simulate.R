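# Synthetic ECoG synthesis.
#
# Signal model per channel:
#   x(t) = A * e(t) * g(t) * c(t) + b(t)
# where c(t) is a unit-RMS band-limited carrier (random-phase sinusoids
# spanning the HFB band), e(t) = exp(z(t)) is a log-normal envelope with z an
# AR(1) Gaussian process (sd `envelope_sigma`, autocorrelation time
# `envelope_tau_s`), g(t) collects the task-locked multiplicative gains
# (viewing responses, sustained recall baseline shifts, recall-locked
# transients, sporadic bursts), and b(t) is 1/f background noise. All dB
# quantities follow the amplitude-ratio convention dB = 10*log10(ratio), so a
# gain of s dB multiplies the amplitude by 10^(s/10).

# random-phase spectral synthesis: amplitude profile amp(f) over FFT bins.
# Synthesized at exactly length n (no truncation: cutting a longer periodic
# synthesis would smear leakage of the strong low-frequency components into
# an f^-2 floor that masks the intended spectral slope).
spectral_noise <- function(n, rate, amp_fun) {
  half <- n %/% 2 + 1L
  freqs <- (seq_len(half) - 1L) * rate / n
  amps <- amp_fun(freqs)
  amps[1] <- 0
  phases <- runif(half, 0, 2 * pi)
  spec <- complex(modulus = amps, argument = phases)
  spec[1] <- 0
  if (n %% 2 == 0) spec[half] <- Mod(spec[half])  # Nyquist bin must be real
  neg <- Conj(rev(spec[2:(half - 1L + (n %% 2))]))
  full <- c(spec, neg)
  x <- Re(fft(full, inverse = TRUE))
  x / sd(x)
}

# AR(1) Gaussian log-envelope, stationary, mean 0, sd sigma. Generated at a
# modest envelope rate (the amplitude envelope of band power is a slow
# signal) and interpolated to the signal rate: an AR(1) innovated at the
# full 500 Hz would carry a white modulation floor out to Nyquist, smearing
# carrier sidebands across the whole spectrum.
ar1_log_envelope <- function(n, rate, sigma, tau_s, env_rate = 50) {
  m <- ceiling(n / rate * env_rate) + 2L
  phi <- exp(-1 / (env_rate * tau_s))
  innov <- rnorm(m, 0, sigma * sqrt(1 - phi^2))
  z <- as.numeric(stats::filter(innov, phi, method = "recursive",
                                init = rnorm(1, 0, sigma)))
  approx(x = (seq_len(m) - 1) / env_rate, y = z,
         xout = (seq_len(n) - 1) / rate)$y
}

# raised-cosine step from 0 to 1 over [t0, t0 + rise]
rc_ramp <- function(t, t0, rise) {
  u <- (t - t0) / rise
  ifelse(u <= 0, 0, ifelse(u >= 1, 1, 0.5 - 0.5 * cos(pi * u)))
}

# transient recall-locked response: rises from -1.5 s, plateau, decays by +2 s
recall_transient_shape <- function(t_rel) {
  rc_ramp(t_rel, -1.5, 1) * (1 - rc_ramp(t_rel, 1, 1))
}

#' Simulate a synthetic ECoG dataset
#'
#' Synthesizes the multichannel raw recording implied by a task schedule and a
#' ground-truth electrode table. Each channel carries a log-normal
#' amplitude-modulated HFB-band carrier on top of 1/f background noise, with
#' task-locked multiplicative gains: per-item viewing responses (gamma-like
#' onset at the electrode's latency, sustained to stimulus offset), sustained
#' baseline shifts during recall blocks that target the electrode's preferred
#' category, signed recall-onset-locked transients, sporadic bursts when
#' configured, transient shift collapse before intrusions, and pre-prompt
#' shift decline with post-prompt recovery.
#'
#' @param schedule A [make_task_schedule()] result.
#' @param ground_truth A [ground_truth_electrodes()] table.
#' @param seed Integer seed; identical seeds give bit-identical recordings.
#' @param carrier_uv Mean carrier envelope amplitude, microvolts (default 4, a realistic high-gamma to LFP proportion).
#' @param noise_uv Background-noise RMS, microvolts (default 12; the 1/f shape
#'   concentrates it at low frequencies, leaving ~2% of carrier power inside
#'   the HFB band).
#' @return A `synthetic_dataset`: list with `recording` (an `ecog_recording`),
#'   `schedule`, `electrodes` (the electrode table) and `ground_truth`.
#' @export
simulate_recording <- function(schedule, ground_truth, seed = 1,
                               carrier_uv = 4, noise_uv = 12) {
  if (nrow(ground_truth) == 0) abort("empty ground truth")
  rate <- schedule$rate
  n <- round(schedule$duration_s * rate)
  tgrid <- (seq_len(n) - 1) / rate
  data <- matrix(0, n, nrow(ground_truth))
  colnames(data) <- ground_truth$electrode_id

  for (i in seq_len(nrow(ground_truth))) {
    g <- ground_truth[i, ]
    set.seed(derive_seed(seed, paste0("chan_", g$electrode_id)))
    carrier <- spectral_noise(n, rate, function(f) {
      as.numeric(f >= g$carrier_lo & f <= g$carrier_hi)
    })
    z <- ar1_log_envelope(n, rate, g$envelope_sigma, g$envelope_tau_s)
    gain_db <- task_gain_db(tgrid, schedule, g, rate)
    envelope <- exp(z - g$envelope_sigma^2 / 2) * db_amp(gain_db)
    noise <- spectral_noise(n, rate, function(f) {
      ifelse(f > 0, f^(-g$noise_exponent / 2), 0)
    })
    data[, i] <- carrier_uv * envelope * carrier + noise_uv * noise
  }

  rec <- new_recording(data, rate, ground_truth$electrode_id)
  structure(
    list(recording = rec, schedule = schedule,
         electrodes = electrode_table(ground_truth, seed = seed),
         ground_truth = ground_truth),
    class = "synthetic_dataset"
  )
}

# dB gain trace from all task-locked components of one electrode
task_gain_db <- function(tgrid, schedule, g, rate) {
  ev <- schedule$events
  gain <- numeric(length(tgrid))
  pref <- g$preferred_category

  # viewing responses: onset at latency, sustained to offset, 50-ms rise,
  # 100-ms decay after stimulus offset
  stim <- ev[ev$event_type == "stimulus", ]
  vg <- g$viewing_gain[[1]]
  if (nrow(stim) > 0 && !is.na(g$viewing_latency_s) && any(vg != 1)) {
    for (j in seq_len(nrow(stim))) {
      gdb <- amp_db(vg[[stim$item_id[j]]])
      if (gdb == 0) next
      t0 <- stim$onset[j] + g$viewing_latency_s
      t1 <- stim$onset[j] + stim$duration[j]
      i0 <- max(1L, floor(t0 * rate) + 1L)
      i1 <- min(length(tgrid), ceiling((t1 + 0.25) * rate) + 1L)
      idx <- i0:i1
      tr <- tgrid[idx]
      shape <- rc_ramp(tr, t0, 0.05) * (1 - rc_ramp(tr, t1, 0.1))
      gain[idx] <- gain[idx] + gdb * shape
    }
  }

  # sustained baseline shift during matching recall blocks (+ order effect)
  blocks <- recall_blocks(ev)
  shift_of <- c(face = g$shift_face_db, place = g$shift_place_db)
  if (any(shift_of != 0) || g$order_effect_db != 0) {
    for (j in seq_len(nrow(blocks))) {
      b <- blocks[j, ]
      idx <- which(tgrid >= b$start & tgrid < b$end)
      s <- shift_of[[b$target_category]]
      # order within run: is this the second-targeted block of its run?
      run_blocks <- blocks[blocks$run == b$run, ]
      second <- b$start > min(run_blocks$start)
      s <- s + if (second) g$order_effect_db else 0
      if (s == 0) next
      shift_tr <- rep(s, length(idx))
      tt <- tgrid[idx]

      if (isTRUE(g$intrusion_dip) && !is.na(pref) &&
          b$target_category == pref) {
        intr <- ev[ev$event_type == "recall" & ev$is_intrusion %in% TRUE &
                     ev$onset >= b$start & ev$onset < b$end, ]
        for (k in seq_len(nrow(intr))) {
          rel <- tt - intr$onset[k]
          dip <- rc_ramp(rel, -2, 1.5) * (1 - rc_ramp(rel, 1, 1))
          shift_tr <- shift_tr * (1 - dip)
        }
      }
      if (isTRUE(g$prompt_dip) && !is.na(pref) && b$target_category == pref) {
        pr <- ev[ev$event_type == "prompt" &
                   ev$onset >= b$start & ev$onset < b$end, ]
        for (k in seq_len(nrow(pr))) {
          rel <- tt - pr$onset[k]
          off <- pr$duration[k]
          dip <- rc_ramp(rel, -5, 2) * (1 - rc_ramp(rel, off, 1))
          shift_tr <- shift_tr * (1 - dip)
        }
      }
      gain[idx] <- gain[idx] + shift_tr
    }
  }

  # recall-onset-locked transients: +transient_db for preferred-category
  # recalls, -transient_db for non-preferred; ROI electrodes respond to every
  # recall with their own lag
  rec <- ev[ev$event_type == "recall", ]
  if (nrow(rec) > 0) {
    if (g$transient_db != 0 && !is.na(pref)) {
      for (j in seq_len(nrow(rec))) {
        sgn <- if (rec$category[j] == pref) 1 else -1
        idx <- which(tgrid >= rec$onset[j] - 2 & tgrid <= rec$onset[j] + 2.5)
        gain[idx] <- gain[idx] + sgn * g$transient_db *
          recall_transient_shape(tgrid[idx] - rec$onset[j])
      }
    }
    if (g$roi_transient_db != 0) {
      for (j in seq_len(nrow(rec))) {
        o <- rec$onset[j] + g$roi_lag_s
        idx <- which(tgrid >= o - 2 & tgrid <= o + 2.5)
        gain[idx] <- gain[idx] + g$roi_transient_db *
          recall_transient_shape(tgrid[idx] - o)
      }
    }
  }

  # sporadic bursts inside recall blocks
  if (g$burst_db != 0 && g$burst_occupancy > 0) {
    for (j in seq_len(nrow(blocks))) {
      b <- blocks[j, ]
      idx <- which(tgrid >= b$start & tgrid < b$end)
      gain[idx] <- gain[idx] + burst_train(length(idx), rate,
                                           g$burst_db, g$burst_occupancy,
                                           g$burst_window_s)
    }
  }
  gain
}

# burst train helper shared with the dynamics simulation: rectangular dB
# pulses totalling `occupancy` of the samples, smoothed with a unit-area
# Gaussian of total width window_s (sd = window_s / 6)
burst_train <- function(n, rate, burst_db, occupancy, window_s,
                        burst_len_s = 1) {
  len <- max(1L, round(burst_len_s * rate))
  n_bursts <- max(1L, round(occupancy * n / len))
  pulses <- numeric(n)
  taken <- integer(0)
  tries <- 0
  while (n_bursts > 0 && tries < 50 * n_bursts) {
    tries <- tries + 1
    s <- sample.int(n - len + 1L, 1)
    span <- s:(s + len - 1L)
    if (!any(span %in% taken)) {
      pulses[span] <- burst_db
      taken <- c(taken, span)
      n_bursts <- n_bursts - 1
    }
  }
  gauss_smooth(pulses, rate, window_s)
}

gauss_smooth <- function(x, rate, window_s) {
  sdv <- window_s / 6
  half <- round(3 * sdv * rate)
  k <- exp(-0.5 * ((-half:half) / (sdv * rate))^2)
  k <- k / sum(k)
  if (length(k) >= length(x)) abort("Gaussian kernel support exceeds trace")
  conv_same(k, x)
}

#' Simulate a rest-normalized synthetic HFB amplitude trace
#'
#' Generates the log-normal AR(1) amplitude envelope directly (skipping the
#' carrier synthesis and filter bank), normalized to its own geometric mean,
#' i.e. the `rest_ratio` state a fully processed electrode would be in. Used
#' by the burst/shift dynamics analyses and by parameter-recovery checks that
#' operate on the envelope itself.
#'
#' @param duration_s Trace duration in seconds.
#' @param rate Sampling rate (default 500 Hz).
#' @param sigma Log-amplitude standard deviation (default 0.4).
#' @param tau_s AR(1) autocorrelation time (default 1 s).
#' @param seed Integer seed.
#' @param state `"db"` (default) or `"ratio"`.
#' @return Numeric vector: the amplitude trace in the requested state.
#' @export
simulate_hfb_trace <- function(duration_s, rate = 500, sigma = 0.4,
                               tau_s = 1, seed = 1, state = c("db", "ratio")) {
  state <- match.arg(state)
  set.seed(derive_seed(seed, "hfb_trace"))
  n <- round(duration_s * rate)
  z <- ar1_log_envelope(n, rate, sigma, tau_s)
  if (state == "db") 10 / log(10) * z else exp(z)
}

#' Inject recall-locked transients into a dB trace
#'
#' Adds the recall-onset-locked transient waveform (raised-cosine rise from
#' -1.5 s, plateau, decay by +2 s, unit peak) scaled to `peak_db` around each
#' onset. Used for envelope-level parameter-recovery checks of the
#' event-locked analyses.
#'
#' @param trace_db Numeric dB trace.
#' @param onsets_s Onset times in seconds (trace starts at 0).
#' @param peak_db Peak amplitude of each transient, dB (signed).
#' @param rate Sampling rate (default 500 Hz).
#' @return The trace with transients added.
#' @export
inject_recall_transients <- function(trace_db, onsets_s, peak_db,
                                     rate = 500) {
  n <- length(trace_db)
  tgrid <- (seq_len(n) - 1) / rate
  for (o in onsets_s) {
    idx <- which(tgrid >= o - 2 & tgrid <= o + 2.5)
    trace_db[idx] <- trace_db[idx] +
      peak_db * recall_transient_shape(tgrid[idx] - o)
  }
  trace_db
}

#' Wrap an amplitude matrix as an HFB signal
#'
#' Lightweight constructor for analysis entry points that consume an
#' `hfb_signal`, used when traces are produced directly at the envelope level
#' (e.g. by [simulate_hfb_trace()]) rather than by the filter bank.
#'
#' @param amplitude Numeric matrix (samples x electrodes) or vector.
#' @param rate Sampling rate, Hz.
#' @param state One of `"volts"`, `"rest_ratio"`, `"db"`.
#' @param runs Optional run-interval tibble (see [run_intervals()]).
#' @return An `hfb_signal`.
#' @export
as_hfb_signal <- function(amplitude, rate = 500, state = "db", runs = NULL) {
  if (is.null(dim(amplitude))) amplitude <- matrix(amplitude, ncol = 1)
  if (is.null(colnames(amplitude)))
    colnames(amplitude) <- sprintf("E%02d", seq_len(ncol(amplitude)))
  new_hfb_signal(as.matrix(amplitude), rate, state, runs = runs)
}
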