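# Event-locked analyses: recall-onset, intrusion, and prompt time-locking
# with triangular smoothing, separation filters, per-event baselines, and
# cluster-based permutation correction.

#' Event-triggered HFB responses
#'
#' Smooths each rest-normalized electrode trace with a triangular window,
#' epochs it around the given onsets (default -5..+7 s), converts to dB, and
#' averages within electrode. Events whose onset follows the previous
#' retained onset by less than `min_separation_s` are dropped (onsets are
#' processed in sorted order).
#'
#' @param hfb An `hfb_signal` in state `"rest_ratio"`.
#' @param onsets Event-onset times, seconds.
#' @param window_s Epoch window (default `c(-5, 7)`).
#' @param smoothing_ms Triangular window width (default 1000; 0 disables).
#' @param min_separation_s Minimum onset-to-onset separation (default 5).
#' @param baseline_s Optional per-event baseline window: each event epoch is
#'   divided by its mean ratio over this window before the dB transform
#'   (e.g. `c(-5, -1)` for prompt-locked analyses; `NULL` keeps the rest
#'   normalization).
#' @param electrode_ids Electrodes to include (default all).
#' @return An `event_response` object: `times`, `mean` (time x electrode
#'   mean dB traces), `n_events`, `n_dropped`, `rate`.
#' @export
extract_event_triggered <- function(hfb, onsets, window_s = c(-5, 7),
                                    smoothing_ms = 1000,
                                    min_separation_s = 5,
                                    baseline_s = NULL,
                                    electrode_ids = NULL) {
  if (hfb$state != "rest_ratio")
    abort("extract_event_triggered expects a rest_ratio signal")
  onsets <- sort(onsets)
  kept <- keep_separated(onsets, min_separation_s)
  onsets_kept <- onsets[kept]
  if (length(onsets_kept) == 0) abort("no events survive the separation filter")

  amp <- hfb$amplitude
  if (!is.null(electrode_ids)) {
    amp <- amp[, electrode_ids, drop = FALSE]
  }
  rate <- hfb$rate
  if (smoothing_ms > 0) {
    amp <- apply(amp, 2, smooth_triangular, width_ms = smoothing_ms,
                 rate = rate)
  }
  rel_idx <- seq(round(window_s[1] * rate), round(window_s[2] * rate))
  times <- rel_idx / rate
  n <- nrow(amp)
  onset_idx <- time_to_sample(onsets_kept, rate, hfb$t0)
  usable <- onset_idx + min(rel_idx) >= 1 & onset_idx + max(rel_idx) <= n
  onset_idx <- onset_idx[usable]
  if (length(onset_idx) == 0) abort("no events with full window support")

  acc <- matrix(0, length(times), ncol(amp))
  for (oi in onset_idx) {
    ep <- amp[oi + rel_idx, , drop = FALSE]
    if (!is.null(baseline_s)) {
      bsel <- times >= baseline_s[1] & times <= baseline_s[2]
      ep <- sweep(ep, 2, colMeans(ep[bsel, , drop = FALSE]), `/`)
    }
    acc <- acc + amp_db(ep)
  }
  structure(
    list(times = times, mean = acc / length(onset_idx),
         electrode_ids = colnames(amp), n_events = length(onset_idx),
         n_dropped = sum(!kept) + sum(!usable), rate = rate,
         smoothing_ms = smoothing_ms, baseline_s = baseline_s),
    class = "event_response"
  )
}

# TRUE for onsets at least min_sep after the previously *retained* onset
keep_separated <- function(onsets, min_sep) {
  keep <- logical(length(onsets))
  last <- -Inf
  for (i in seq_along(onsets)) {
    if (onsets[i] - last >= min_sep) {
      keep[i] <- TRUE
      last <- onsets[i]
    }
  }
  keep
}

#' @export
print.event_response <- function(x, ...) {
  cat("<event_response>", length(x$electrode_ids), "electrodes,",
      x$n_events, "events (", x$n_dropped, "dropped ),",
      sprintf("%.1f..%.1f s\n", min(x$times), max(x$times)))
  invisible(x)
}

#' Tidy an event response into long format
#' @param x An `event_response`.
#' @param ... Unused.
#' @return Tibble `time_s`, `electrode_id`, `db`.
#' @method tidy event_response
#' @export
tidy.event_response <- function(x, ...) {
  tibble(time_s = rep(x$times, times = ncol(x$mean)),
         electrode_id = rep(x$electrode_ids, each = nrow(x$mean)),
         db = as.numeric(x$mean))
}

# ---------------------------------------------------------------------------
# cluster-based permutation test

#' Time-point-wise contrast with cluster-based permutation correction
#'
#' Runs a successive two-tailed t-test (paired across electrodes, or
#' two-sample when the condition sets differ) at every time point, forms
#' clusters as maximal runs of samples with p below `threshold_p`, scores
#' each cluster by its mass (sum of |t|), and corrects by comparing against
#' the Monte-Carlo null distribution of the maximum cluster mass obtained by
#' shuffling condition labels over electrodes.
#'
#' @param resp_a,resp_b `event_response` objects (or bare electrode x time
#'   matrices) for the two conditions.
#' @param paired Paired test across electrodes (default TRUE; requires equal
#'   electrode sets).
#' @param threshold_p Cluster-forming threshold (default 0.05).
#' @param n_perm Number of Monte-Carlo label permutations (default 10000).
#' @param seed Integer seed.
#' @return A `cluster_test` object: `times`, `t` trace, `df`, `clusters`
#'   tibble (`start_s`, `end_s`, `mass`, `p_corrected`), `threshold_p`,
#'   `n_perm`.
#' @export
contrast_timecourse <- function(resp_a, resp_b, paired = TRUE,
                                threshold_p = 0.05, n_perm = 10000,
                                seed = 1) {
  if (n_perm < 100) abort("need at least 100 permutations")
  times <- if (inherits(resp_a, "event_response")) resp_a$times else NULL
  A <- as_electrode_matrix(resp_a)
  B <- as_electrode_matrix(resp_b)
  if (paired && nrow(A) != nrow(B))
    abort("paired contrast requires matching electrode sets")
  if (min(nrow(A), nrow(B)) < 5) abort("need at least 5 electrodes")
  if (is.null(times)) times <- seq_len(ncol(A))
  set.seed(derive_seed(seed, "cluster_perm"))

  if (paired) {
    D <- A - B
    obs <- paired_t_trace(D)
    null_max <- numeric(n_perm)
    n <- nrow(D)
    block <- 500L
    done <- 0L
    while (done < n_perm) {
      nb <- min(block, n_perm - done)
      S <- matrix(sample(c(-1, 1), nb * n, replace = TRUE), nb, n)
      M <- S %*% D / n
      SS <- matrix(colSums(D^2), nb, ncol(D), byrow = TRUE)
      V <- (SS - n * M^2) / (n - 1)
      Tm <- M / sqrt(V / n)
      tc <- qt(1 - threshold_p / 2, n - 1)
      for (i in seq_len(nb)) {
        null_max[done + i] <- max_cluster_mass(Tm[i, ], tc)
      }
      done <- done + nb
    }
    df <- n - 1
    tcrit <- qt(1 - threshold_p / 2, df)
  } else {
    X <- rbind(A, B)
    lab <- rep(c(TRUE, FALSE), c(nrow(A), nrow(B)))
    obs <- two_sample_t_trace(X, lab)
    df <- nrow(X) - 2
    tcrit <- qt(1 - threshold_p / 2, df)
    null_max <- vapply(seq_len(n_perm), function(i) {
      max_cluster_mass(two_sample_t_trace(X, sample(lab)), tcrit)
    }, numeric(1))
  }

  clusters <- find_clusters(obs, tcrit, times)
  clusters$p_corrected <- vapply(clusters$mass, function(m)
    mean(null_max >= m), numeric(1))
  structure(
    list(times = times, t = obs, df = df, clusters = clusters,
         threshold_p = threshold_p, n_perm = n_perm, paired = paired,
         null_max = null_max),
    class = "cluster_test"
  )
}

as_electrode_matrix <- function(x) {
  if (inherits(x, "event_response")) t(x$mean) else as.matrix(x)
}

paired_t_trace <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  v <- (colSums(D^2) - n * m^2) / (n - 1)
  m / sqrt(pmax(v, .Machine$double.eps) / n)
}

two_sample_t_trace <- function(X, lab) {
  n1 <- sum(lab); n2 <- sum(!lab)
  m1 <- colMeans(X[lab, , drop = FALSE])
  m2 <- colMeans(X[!lab, , drop = FALSE])
  v1 <- (colSums(X[lab, , drop = FALSE]^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(X[!lab, , drop = FALSE]^2) - n2 * m2^2) / (n2 - 1)
  sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  (m1 - m2) / sqrt(pmax(sp, .Machine$double.eps) * (1 / n1 + 1 / n2))
}

find_clusters <- function(tt, tcrit, times) {
  sig <- abs(tt) > tcrit
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  tibble(
    start_s = times[starts[keep]],
    end_s = times[ends[keep]],
    mass = vapply(keep, function(k)
      sum(abs(tt[starts[k]:ends[k]])), numeric(1))
  )
}

max_cluster_mass <- function(tt, tcrit) {
  sig <- abs(tt) > tcrit
  if (!any(sig)) return(0)
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  max(vapply(keep, function(k) sum(abs(tt[starts[k]:ends[k]])), numeric(1)))
}

#' @export
print.cluster_test <- function(x, ...) {
  sig <- sum(x$clusters$p_corrected < 0.05)
  cat("<cluster_test>", nrow(x$clusters), "clusters (", sig,
      "with corrected p < 0.05 ),", x$n_perm, "permutations\n")
  invisible(x)
}

#' @method tidy cluster_test
#' @export
tidy.cluster_test <- function(x, ...) x$clusters

#' @method glance cluster_test
#' @export
glance.cluster_test <- function(x, ...) {
  tibble(n_clusters = nrow(x$clusters),
         min_p = if (nrow(x$clusters)) min(x$clusters$p_corrected) else NA_real_,
         threshold_p = x$threshold_p, n_perm = x$n_perm, paired = x$paired)
}

# ---------------------------------------------------------------------------
# higher-level event-locked analyses

#' Recall-onset contrast: preferred vs non-preferred category
#'
#' For every category-selective electrode, averages the event-triggered dB
#' response separately over recalls of its preferred and its non-preferred
#' category (5-s separation filter applied within each condition), then runs
#' the paired cluster-corrected contrast across electrodes.
#'
#' @param hfb An `hfb_signal` in state `"rest_ratio"`.
#' @param events Events tibble.
#' @param profiles A `selectivity_profiles` tibble.
#' @param n_perm Permutations (default 10000).
#' @param seed Integer seed.
#' @param ... Passed to [extract_event_triggered()].
#' @return List with `preferred`/`nonpreferred` (electrode x time matrices),
#'   `times` and `test` (a `cluster_test`).
#' @export
recall_onset_contrast <- function(hfb, events, profiles, n_perm = 10000,
                                  seed = 1, ...) {
  pref <- preferred_category(profiles)
  sel_ids <- names(pref)[!is.na(pref)]
  if (length(sel_ids) < 5) abort("need at least 5 category-selective electrodes")
  recalls <- events %>% filter(.data$event_type == "recall")
  build <- function(want_pref) {
    rows <- lapply(sel_ids, function(id) {
      cat_want <- if (want_pref) pref[id]
                  else setdiff(c("face", "place"), pref[id])
      on <- recalls$onset[recalls$category == cat_want]
      er <- extract_event_triggered(hfb, on, electrode_ids = id, ...)
      list(trace = er$mean[, 1], times = er$times)
    })
    list(mat = do.call(rbind, lapply(rows, `[[`, "trace")),
         times = rows[[1]]$times)
  }
  a <- build(TRUE)
  b <- build(FALSE)
  rownames(a$mat) <- rownames(b$mat) <- sel_ids
  test <- contrast_timecourse(
    structure(list(times = a$times, mean = t(a$mat)), class = "event_response"),
    structure(list(times = b$times, mean = t(b$mat)), class = "event_response"),
    paired = TRUE, n_perm = n_perm, seed = seed
  )
  list(preferred = a$mat, nonpreferred = b$mat, times = a$times, test = test)
}

#' Intrusion-locked contrast
#'
#' Time-locks category-selective electrodes to extra-category intrusion
#' onsets, split by whether the block then targeted the electrode's
#' preferred category, and contrasts the two conditions with a two-sample
#' cluster-corrected test (the event sets differ, so pairing is not
#' meaningful).
#'
#' @inheritParams recall_onset_contrast
#' @return List with `preferred_targeted`/`nonpreferred_targeted` matrices,
#'   `times`, `test`.
#' @export
intrusion_timecourse <- function(hfb, events, profiles, n_perm = 10000,
                                 seed = 1, ...) {
  pref <- preferred_category(profiles)
  sel_ids <- names(pref)[!is.na(pref)]
  intr <- events %>% filter(.data$event_type == "recall",
                            .data$is_intrusion %in% TRUE)
  if (nrow(intr) == 0) abort("no intrusions in a condition")
  build <- function(want_pref_targeted) {
    mats <- lapply(sel_ids, function(id) {
      tgt <- if (want_pref_targeted) pref[id]
             else setdiff(c("face", "place"), pref[id])
      on <- intr$onset[intr$target_category == tgt]
      if (length(on) == 0) return(NULL)
      er <- extract_event_triggered(hfb, on, electrode_ids = id, ...)
      list(trace = er$mean[, 1], times = er$times, id = id)
    })
    mats <- mats[!vapply(mats, is.null, logical(1))]
    if (length(mats) == 0) abort("no intrusions in a condition")
    m <- do.call(rbind, lapply(mats, `[[`, "trace"))
    rownames(m) <- vapply(mats, `[[`, character(1), "id")
    list(mat = m, times = mats[[1]]$times)
  }
  a <- build(TRUE)
  b <- build(FALSE)
  test <- contrast_timecourse(a$mat, b$mat, paired = FALSE,
                              n_perm = n_perm, seed = seed)
  test$times <- a$times
  test$clusters$start_s <- a$times[test$clusters$start_s]
  test$clusters$end_s <- a$times[test$clusters$end_s]
  list(preferred_targeted = a$mat, nonpreferred_targeted = b$mat,
       times = a$times, test = test)
}

#' Prompt-locked contrast
#'
#' Time-locks to experimenter prompts, normalizing each electrode's response
#' by its own pre-prompt baseline (-5..-1 s). Only prompts separated from
#' the next recall onset by at least `min_gap_to_next_recall_s` are used.
#' Conditions: the prompted category is / is not the electrode's preferred
#' category (two-sample test).
#'
#' @inheritParams recall_onset_contrast
#' @param min_gap_to_next_recall_s Required gap to the next recall (default 7).
#' @return List with `preferred`/`nonpreferred` matrices, `times`, `test`,
#'   `n_eligible`.
#' @export
prompt_timecourse <- function(hfb, events, profiles,
                              min_gap_to_next_recall_s = 7,
                              n_perm = 10000, seed = 1, ...) {
  pref <- preferred_category(profiles)
  sel_ids <- names(pref)[!is.na(pref)]
  prompts <- events %>% filter(.data$event_type == "prompt")
  recalls <- events %>% filter(.data$event_type == "recall")
  if (nrow(prompts) == 0) abort("no eligible prompts")
  eligible <- vapply(seq_len(nrow(prompts)), function(i) {
    nxt <- recalls$onset[recalls$onset > prompts$onset[i]]
    length(nxt) == 0 || min(nxt) - prompts$onset[i] >= min_gap_to_next_recall_s
  }, logical(1))
  prompts <- prompts[eligible, ]
  if (nrow(prompts) == 0) abort("no eligible prompts")
  build <- function(want_pref) {
    mats <- lapply(sel_ids, function(id) {
      sel <- if (want_pref) prompts$target_category == pref[id]
             else prompts$target_category != pref[id]
      on <- prompts$onset[sel]
      if (length(on) == 0) return(NULL)
      er <- extract_event_triggered(hfb, on, electrode_ids = id,
                                    baseline_s = c(-5, -1),
                                    min_separation_s = 0, ...)
      list(trace = er$mean[, 1], times = er$times, id = id)
    })
    mats <- mats[!vapply(mats, is.null, logical(1))]
    if (length(mats) == 0) abort("no eligible prompts")
    m <- do.call(rbind, lapply(mats, `[[`, "trace"))
    rownames(m) <- vapply(mats, `[[`, character(1), "id")
    list(mat = m, times = mats[[1]]$times)
  }
  a <- build(TRUE)
  b <- build(FALSE)
  test <- contrast_timecourse(a$mat, b$mat, paired = FALSE,
                              n_perm = n_perm, seed = seed)
  test$times <- a$times
  test$clusters$start_s <- a$times[test$clusters$start_s]
  test$clusters$end_s <- a$times[test$clusters$end_s]
  list(preferred = a$mat, nonpreferred = b$mat, times = a$times,
       test = test, n_eligible = nrow(prompts))
}

#' Region-of-interest recall-locked responses
#'
#' Event-triggered responses of anatomically defined electrode groups,
#' normalized per event by a pre-recall baseline (-5..-3 s). Returns the ROI
#' mean traces, a per-electrode two-bin summary (baseline -5..-3 s vs
#' recall-onset transient -1..+1 s) for the mixed-model contract, and a
#' paired cluster-corrected test of the ROI trace against zero.
#'
#' @param hfb An `hfb_signal` in state `"rest_ratio"`.
#' @param onsets Recall-onset times.
#' @param roi_groups Named list of electrode-id vectors, one per ROI.
#' @param baseline_window,transient_window Bin windows (defaults
#'   `c(-5, -3)`, `c(-1, 1)`).
#' @param n_perm Permutations for the against-baseline test (default 2000).
#' @param seed Integer seed.
#' @param ... Passed to [extract_event_triggered()].
#' @return List per ROI: `trace` (mean dB), `times`, `bins` tibble
#'   (`electrode_id`, `baseline_db`, `transient_db`), `test`.
#' @export
roi_event_response <- function(hfb, onsets, roi_groups,
                               baseline_window = c(-5, -3),
                               transient_window = c(-1, 1),
                               n_perm = 2000, seed = 1, ...) {
  if (any(lengths(roi_groups) == 0)) abort("empty ROI")
  purrr::imap(roi_groups, function(ids, roi) {
    er <- extract_event_triggered(hfb, onsets, electrode_ids = ids,
                                  baseline_s = baseline_window, ...)
    bsel <- er$times >= baseline_window[1] & er$times <= baseline_window[2]
    tsel <- er$times >= transient_window[1] & er$times <= transient_window[2]
    bins <- tibble(
      electrode_id = er$electrode_ids,
      baseline_db = colMeans(er$mean[bsel, , drop = FALSE]),
      transient_db = colMeans(er$mean[tsel, , drop = FALSE])
    )
    test <- if (length(ids) >= 5) {
      contrast_timecourse(t(er$mean), matrix(0, ncol(er$mean), nrow(er$mean)),
                          paired = TRUE, n_perm = n_perm, seed = seed)
    } else NULL
    if (!is.null(test)) {
      test$times <- er$times
      test$clusters$start_s <- er$times[test$clusters$start_s]
      test$clusters$end_s <- er$times[test$clusters$end_s]
    }
    list(trace = rowMeans(er$mean), times = er$times, bins = bins,
         test = test, n_events = er$n_events)
  })
}

#' ROI membership by MNI distance
#'
#' @param electrodes Electrode table with `name`, `x`, `y`, `z`.
#' @param centers Named list of MNI coordinate rows (each a matrix or vector
#'   of xyz; several rows for bilateral ROIs). Default: the six prefrontal /
#'   parietal retrieval-control ROIs.
#' @param radius_mm Capture radius (default 15).
#' @return Named list of electrode-id vectors (empty ROIs dropped).
#' @export
roi_membership <- function(electrodes, centers = default_roi_centers(),
                           radius_mm = 15) {
  out <- purrr::map(centers, function(ctr) {
    ctr <- matrix(ctr, ncol = 3, byrow = is.null(dim(ctr)))
    hit <- vapply(seq_len(nrow(electrodes)), function(i) {
      any(sqrt(colSums((t(ctr) - c(electrodes$x[i], electrodes$y[i],
                                   electrodes$z[i]))^2)) <= radius_mm)
    }, logical(1))
    electrodes$name[hit]
  })
  out[lengths(out) > 0]
}

#' Default prefrontal and parietal ROI centers (MNI mm)
#' @return Named list of coordinate matrices.
#' @export
default_roi_centers <- function() {
  list(
    aVLPFC = c(-48, 33, -9),
    mid_VLPFC_L = c(-51, 18, 6),
    mid_VLPFC_R = c(54, 15, 15),
    DLPFC_R = c(37, 33, 33),
    DPC = rbind(c(-36, -57, 36), c(35, -54, 38)),
    VPC = rbind(c(-44, -60, 23), c(56, -64, 20))
  )
}
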