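# Multitaper spectral estimation (Slepian tapers) for raw-LFP spectra
# (1-50 Hz) and ultra-slow HFB-fluctuation spectra (< ~2 Hz).

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw`, via the symmetric tridiagonal eigenproblem. For long
#' windows (n > 1024) the tapers are obtained by spline interpolation from a
#' length-801 solution followed by Gram-Schmidt re-orthonormalization, which
#' is accurate far beyond spectral-estimation needs. Tapers are unit-energy
#' and pairwise orthogonal; results are cached per (n, k, nw).
#'
#' @param n Window length in samples.
#' @param k Number of tapers (requires `k <= 2 * nw - 1`).
#' @param nw Time-bandwidth product (default `(k + 1) / 2`).
#' @return n x k matrix, one taper per column.
#' @export
dpss_tapers <- function(n, k, nw = (k + 1) / 2) {
  if (k > 2 * nw - 1 + 1e-9)
    abort("k exceeds the 2*NW - 1 concentration limit")
  key <- sprintf("dpss_%d_%d_%g", n, k, nw)
  cached <- .recallshift_cache[[key]]
  if (!is.null(cached)) return(cached)
  out <- if (n <= 1024) dpss_direct(n, k, nw) else dpss_interp(n, k, nw)
  .recallshift_cache[[key]] <- out
  out
}

# dense tridiagonal eigen-decomposition (exact)
dpss_direct <- function(n, k, nw) {
  w <- nw / n
  i <- seq_len(n) - 1
  d <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  e <- seq_len(n - 1) * (n - seq_len(n - 1)) / 2
  A <- diag(d)
  A[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- e
  A[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- e
  eg <- eigen(A, symmetric = TRUE)
  V <- eg$vectors[, seq_len(k), drop = FALSE]
  fix_taper_signs(V)
}

# long windows: interpolate from a shorter exact solution, re-orthonormalize
dpss_interp <- function(n, k, nw) {
  n0 <- 801L
  V0 <- dpss_direct(n0, k, nw)
  x0 <- seq(0, 1, length.out = n0)
  x1 <- seq(0, 1, length.out = n)
  V <- apply(V0, 2, function(v) spline(x0, v, xout = x1)$y)
  # Gram-Schmidt in taper order preserves each taper's identity
  for (j in seq_len(k)) {
    if (j > 1) {
      for (m in seq_len(j - 1)) {
        V[, j] <- V[, j] - sum(V[, j] * V[, m]) * V[, m]
      }
    }
    V[, j] <- V[, j] / sqrt(sum(V[, j]^2))
  }
  fix_taper_signs(V)
}

# convention: symmetric tapers have positive mean, antisymmetric ones a
# positive initial lobe
fix_taper_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    s <- if (j %% 2 == 1) sum(V[, j]) else sum(V[seq_len(nrow(V) %/% 2), j])
    if (s < 0) V[, j] <- -V[, j]
  }
  V
}

#' Multitaper half-bandwidth
#'
#' The spectral concentration half-bandwidth `W = NW / T` of a multitaper
#' configuration with segment length `T` seconds and `K` tapers at the
#' standard `NW = (K + 1) / 2`.
#'
#' @param T_s Segment length, seconds.
#' @param k Number of tapers.
#' @param nw Time-bandwidth product (default `(k + 1) / 2`).
#' @return Half-bandwidth in Hz.
#' @export
#' @examples
#' mt_half_bandwidth(25, 4)  # 0.1 Hz
mt_half_bandwidth <- function(T_s, k, nw = (k + 1) / 2) nw / T_s

#' Multitaper power spectral density
#'
#' Averages taper-windowed periodograms over K Slepian tapers and all
#' segments. Segments are demeaned and zero-padded to the next power of two
#' (or `pad` samples). One-sided density scaling, so the integral over
#' frequency recovers the signal variance.
#'
#' @param segments Numeric matrix (samples x segments) or a single vector.
#' @param rate Sampling rate, Hz.
#' @param k Number of tapers.
#' @param nw Time-bandwidth product (default `(k + 1) / 2`).
#' @param pad FFT length (default: next power of two at or above the segment
#'   length).
#' @return A `psd_estimate`: tibble `freq_hz`, `power`, with the taper and
#'   segment configuration in attributes.
#' @export
multitaper_psd <- function(segments, rate, k, nw = (k + 1) / 2, pad = NULL) {
  if (is.null(dim(segments))) segments <- matrix(segments, ncol = 1)
  n <- nrow(segments)
  if (is.null(pad)) pad <- stats::nextn(n, 2)
  if (pad < n) abort("pad must be at least the segment length")
  tapers <- dpss_tapers(n, k, nw)
  nfreq <- pad %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in seq_len(ncol(segments))) {
    x <- segments[, s] - mean(segments[, s])
    for (j in seq_len(k)) {
      X <- fft(c(x * tapers[, j], numeric(pad - n)))[seq_len(nfreq)]
      acc <- acc + Mod(X)^2
    }
  }
  pw <- acc / (k * ncol(segments)) / rate
  # one-sided: double everything except DC and Nyquist
  pw[2:(nfreq - 1L)] <- 2 * pw[2:(nfreq - 1L)]
  out <- tibble(freq_hz = seq(0, rate / 2, length.out = nfreq), power = pw)
  attr(out, "params") <- list(n = n, k = k, nw = nw, pad = pad, rate = rate,
                              n_segments = ncol(segments),
                              half_bandwidth_hz = nw / (n / rate))
  class(out) <- c("psd_estimate", class(out))
  out
}

# cut [start, end) into non-overlapping seg_s segments; returns start times
segment_starts <- function(start, end, seg_s) {
  s <- seq(start, end, by = seg_s)
  s[s + seg_s <= end + 1e-9]
}

# matrix of segments (samples x n_seg) from a single-channel trace,
# dropping segments that touch masked samples
cut_segments <- function(x, rate, starts, seg_s, keep = NULL, t0 = 0) {
  len <- round(seg_s * rate)
  cols <- list()
  for (st in starts) {
    i0 <- time_to_sample(st, rate, t0)
    idx <- i0:(i0 + len - 1L)
    if (idx[1] < 1 || idx[length(idx)] > length(x)) next
    if (!is.null(keep) && !all(keep[idx])) next
    cols[[length(cols) + 1L]] <- x[idx]
  }
  if (length(cols) == 0) return(NULL)
  do.call(cbind, cols)
}

#' Raw-LFP condition spectra (1-50 Hz)
#'
#' Multitaper spectra of the preprocessed raw signal per electrode and
#' condition: rest (5-s cuts of the rest periods), viewing (5-s cuts of the
#' continuous picture-viewing period), recall events (5-s segments centered
#' on recall onsets) and inter-recall intervals (IRI: 5-s non-overlapping
#' segments from each recall offset until 2 s before the next onset). Seven
#' tapers, zero-padding to 2^12. Gains are dB relative to rest, tested per
#' frequency with a signed-rank across electrodes and BH-FDR.
#'
#' @param recording A preprocessed `ecog_recording`.
#' @param events Events tibble.
#' @param mask Optional `artifact_mask`.
#' @param seg_s Segment length (default 5 s).
#' @param k Tapers (default 7).
#' @param pad FFT length (default 4096).
#' @param freq_range Analysis band (default `c(1, 50)` Hz).
#' @param electrode_ids Channels to analyse (default all).
#' @param alpha FDR level for the per-frequency tests (default 0.05).
#' @return A `condition_spectra` list: `psd` (tibble `electrode_id`,
#'   `condition`, `freq_hz`, `power`), `gain` (tibble `condition`,
#'   `freq_hz`, `mean_gain_db`, `p`, `q`) for each non-rest condition vs
#'   rest, and `recall_vs_iri` (same layout).
#' @export
lfp_condition_spectra <- function(recording, events, mask = NULL, seg_s = 5,
                                  k = 7, pad = 4096,
                                  freq_range = c(1, 50),
                                  electrode_ids = NULL, alpha = 0.05) {
  rate <- recording$rate
  keep <- if (is.null(mask)) NULL else !mask$excluded
  ids <- electrode_ids %||% recording$channel_ids
  runs <- run_intervals(events)
  blocks <- recall_blocks(events)
  recalls <- events %>% filter(.data$event_type == "recall") %>%
    arrange(.data$onset)
  stim <- events %>% filter(.data$event_type == "stimulus")

  rest_starts <- unlist(lapply(seq_len(nrow(runs)), function(r)
    segment_starts(runs$rest_start[r], runs$rest_end[r], seg_s)))
  view_starts <- unlist(lapply(unique(stim$run), function(r) {
    s <- stim %>% filter(.data$run == r)
    segment_starts(min(s$onset), max(s$onset + s$duration), seg_s)
  }))
  recall_starts <- recalls$onset - seg_s / 2
  iri_starts <- unlist(lapply(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    rr <- recalls %>% filter(.data$onset >= b$start, .data$onset < b$end)
    if (nrow(rr) == 0) return(numeric(0))
    unlist(lapply(seq_len(nrow(rr)), function(j) {
      lo <- rr$onset[j] + rr$duration[j]
      hi <- if (j < nrow(rr)) rr$onset[j + 1] - 2 else b$end
      if (hi - lo < seg_s) return(numeric(0))
      s <- seq(lo, hi, by = seg_s)
      s[s + seg_s <= hi + 1e-9]
    }))
  }))
  conds <- list(rest = rest_starts, viewing = view_starts,
                recall = recall_starts, iri = iri_starts)

  psd_rows <- list()
  for (id in ids) {
    x <- recording$data[, id]
    for (cn in names(conds)) {
      segs <- cut_segments(x, rate, conds[[cn]], seg_s, keep, recording$t0)
      if (is.null(segs)) abort(sprintf("no eligible segments for '%s'", cn))
      est <- multitaper_psd(segs, rate, k = k, pad = pad)
      sel <- est$freq_hz >= freq_range[1] & est$freq_hz <= freq_range[2]
      psd_rows[[length(psd_rows) + 1L]] <-
        tibble(electrode_id = id, condition = cn,
               freq_hz = est$freq_hz[sel], power = est$power[sel],
               n_segments = attr(est, "params")$n_segments)
    }
  }
  psd <- bind_rows(psd_rows)
  structure(
    list(psd = psd,
         gain = spectra_gain_tests(psd, ref = "rest", alpha = alpha),
         recall_vs_iri = spectra_gain_tests(
           filter(psd, .data$condition %in% c("recall", "iri")),
           ref = "iri", alpha = alpha)),
    class = "condition_spectra"
  )
}

# per-frequency rest-relative gains with signed-rank + BH-FDR
spectra_gain_tests <- function(psd, ref, alpha = 0.05) {
  wide <- psd %>%
    select("electrode_id", "condition", "freq_hz", "power") %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "power")
  conds <- setdiff(unique(psd$condition), ref)
  purrr::map_dfr(conds, function(cn) {
    d <- wide %>%
      mutate(gain_db = 10 * log10(.data[[cn]] / .data[[ref]]))
    per_freq <- d %>%
      group_by(.data$freq_hz) %>%
      summarise(mean_gain_db = mean(.data$gain_db),
                p = tryCatch(wilcoxon_signed_rank(.data$gain_db)$p,
                             error = function(e) NA_real_),
                .groups = "drop")
    ok <- !is.na(per_freq$p)
    per_freq$q <- NA_real_
    if (any(ok)) per_freq$q[ok] <- bh_fdr(per_freq$p[ok], alpha)$q
    per_freq$significant <- !is.na(per_freq$q) & per_freq$q <= alpha
    per_freq$condition <- cn
    per_freq$reference <- ref
    per_freq
  })
}

#' Ultra-slow HFB-fluctuation spectra
#'
#' Multitaper spectra of the rest-normalized HFB amplitude itself, revealing
#' modulation of the envelope at ultra-slow frequencies: 25-s demeaned
#' epochs, four tapers (0.1-Hz resolution), zero-padding to 2^14. Conditions
#' are rest, free recall (all recall blocks) and picture viewing. Epochs
#' overlapping the artifact mask are dropped whole. Gains vs rest are tested
#' as in [lfp_condition_spectra()]. An optional preferred/non-preferred
#' split of the recall blocks is returned when `profiles` is given.
#'
#' @param hfb An `hfb_signal` in state `"rest_ratio"`.
#' @param events Events tibble.
#' @param mask Optional `artifact_mask`.
#' @param epoch_s Epoch length (default 25 s).
#' @param k Tapers (default 4).
#' @param pad FFT length (default 16384).
#' @param freq_max Highest frequency reported (default 2 Hz).
#' @param electrode_ids Channels (default all).
#' @param profiles Optional `selectivity_profiles` for the preferred vs
#'   non-preferred recall contrast.
#' @param alpha FDR level (default 0.05).
#' @return A `condition_spectra` list (`psd`, `gain`, and when `profiles`
#'   is given `preference_gain`: preferred vs non-preferred recall).
#' @export
hfb_fluctuation_spectra <- function(hfb, events, mask = NULL, epoch_s = 25,
                                    k = 4, pad = 16384, freq_max = 2,
                                    electrode_ids = NULL, profiles = NULL,
                                    alpha = 0.05) {
  if (hfb$state != "rest_ratio")
    abort("hfb_fluctuation_spectra expects a rest_ratio signal")
  rate <- hfb$rate
  keep <- if (is.null(mask)) NULL else !mask$excluded
  ids <- electrode_ids %||% colnames(hfb$amplitude)
  runs <- hfb$runs %||% run_intervals(events)
  blocks <- recall_blocks(events)
  stim <- events %>% filter(.data$event_type == "stimulus")
  if (any(blocks$end - blocks$start < epoch_s))
    abort("recall block shorter than one epoch")

  rest_starts <- unlist(lapply(seq_len(nrow(runs)), function(r)
    segment_starts(runs$rest_start[r], runs$rest_end[r], epoch_s)))
  view_starts <- unlist(lapply(unique(stim$run), function(r) {
    s <- stim %>% filter(.data$run == r)
    segment_starts(min(s$onset), max(s$onset + s$duration), epoch_s)
  }))
  block_starts <- function(b) segment_starts(b$start, b$end, epoch_s)
  recall_starts <- unlist(lapply(seq_len(nrow(blocks)), function(i)
    block_starts(blocks[i, ])))
  conds <- list(rest = rest_starts, viewing = view_starts,
                recall = recall_starts)

  psd_of <- function(x, starts) {
    segs <- cut_segments(x, rate, starts, epoch_s, keep, hfb$t0)
    if (is.null(segs)) return(NULL)
    est <- multitaper_psd(segs, rate, k = k, pad = pad)
    est[est$freq_hz <= freq_max, ]
  }
  psd_rows <- list()
  for (id in ids) {
    x <- hfb$amplitude[, id]
    for (cn in names(conds)) {
      est <- psd_of(x, conds[[cn]])
      if (is.null(est)) abort(sprintf("no eligible epochs for '%s'", cn))
      psd_rows[[length(psd_rows) + 1L]] <-
        tibble(electrode_id = id, condition = cn,
               freq_hz = est$freq_hz, power = est$power)
    }
  }
  psd <- bind_rows(psd_rows)
  out <- list(psd = psd,
              gain = spectra_gain_tests(psd, ref = "rest", alpha = alpha))

  if (!is.null(profiles)) {
    pref <- preferred_category(profiles)
    sel_ids <- intersect(ids, names(pref)[!is.na(pref)])
    pr_rows <- list()
    for (id in sel_ids) {
      x <- hfb$amplitude[, id]
      for (side in c("preferred", "nonpreferred")) {
        want <- if (side == "preferred") pref[id]
                else setdiff(c("face", "place"), pref[id])
        starts <- unlist(lapply(which(blocks$target_category == want),
                                function(i) block_starts(blocks[i, ])))
        est <- psd_of(x, starts)
        if (is.null(est)) next
        pr_rows[[length(pr_rows) + 1L]] <-
          tibble(electrode_id = id, condition = side,
                 freq_hz = est$freq_hz, power = est$power)
      }
    }
    if (length(pr_rows) > 0) {
      out$preference_gain <- spectra_gain_tests(bind_rows(pr_rows),
                                                ref = "nonpreferred",
                                                alpha = alpha)
    }
  }
  class(out) <- "condition_spectra"
  out
}

#' @export
print.condition_spectra <- function(x, ...) {
  cat("<condition_spectra>",
      length(unique(x$psd$electrode_id)), "electrodes,",
      paste(unique(x$psd$condition), collapse = "/"), "\n")
  invisible(x)
}
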