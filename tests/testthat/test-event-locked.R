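# Event-locked analyses: separation filter, triggered averaging, cluster
# permutation statistics, intrusion/prompt/ROI paths.

test_that("the 5-s separation filter keeps the documented events", {
  expect_equal(recallshift:::keep_separated(c(0, 10, 20), 5),
               c(TRUE, TRUE, TRUE))
  expect_equal(recallshift:::keep_separated(c(0, 3, 10), 5),
               c(TRUE, FALSE, TRUE))
  # order dependence only on the onset sort: second of a close pair drops
  expect_equal(recallshift:::keep_separated(c(0, 3, 6), 5),
               c(TRUE, FALSE, TRUE))
})

test_that("a constant trace yields a flat event-triggered response", {
  h <- as_hfb_signal(rep(2, 300 * 500), 500, "rest_ratio")
  er <- extract_event_triggered(h, onsets = c(50, 100, 150))
  expect_equal(er$n_events, 3)
  expect_true(all(abs(er$mean - to_db(2)) < 1e-9))
  expect_error(extract_event_triggered(h, numeric(0)), "survive|support")
})

test_that("injected transients are recovered at their amplitude and time", {
  rate <- 500
  onsets <- seq(20, 380, length.out = 25)
  mats <- sapply(1:12, function(e) {
    tr <- simulate_hfb_trace(400, seed = 100 + e)
    db_amp(inject_recall_transients(tr, onsets, 0.17))
  })
  h <- as_hfb_signal(mats, rate, "rest_ratio")
  er <- extract_event_triggered(h, onsets)
  grand <- rowMeans(er$mean)
  base <- mean(grand[er$times < -3])
  expect_lt(abs((max(grand) - base) - 0.17), 0.05)
  expect_lt(abs(er$times[which.max(grand)]), 1.6)
})

test_that("cluster permutation: observed mass is sign-symmetric and null-calibrated", {
  set.seed(20)
  A <- matrix(rnorm(8 * 300), 8)
  B <- matrix(rnorm(8 * 300), 8)
  ct1 <- contrast_timecourse(A, B, paired = TRUE, n_perm = 200, seed = 1)
  # flipping every electrode label flips the difference sign; two-sided
  # cluster masses are unchanged
  ct2 <- contrast_timecourse(B, A, paired = TRUE, n_perm = 200, seed = 1)
  expect_equal(ct1$clusters$mass, ct2$clusters$mass)
  expect_equal(abs(ct1$t), abs(ct2$t))
  expect_error(contrast_timecourse(A, B, n_perm = 50), "100")
  expect_error(contrast_timecourse(A[1:3, ], B[1:3, ], n_perm = 200),
               "at least 5")
})

test_that("a strong differential transient produces an early significant cluster", {
  rate <- 100
  onsets <- seq(20, 580, by = 14)
  build <- function(peak) {
    mats <- sapply(1:10, function(e) {
      tr <- simulate_hfb_trace(600, rate = rate, seed = 400 + e + peak * 1000)
      db_amp(inject_recall_transients(tr, onsets, peak, rate = rate))
    })
    as_hfb_signal(mats, rate, "rest_ratio")
  }
  era <- extract_event_triggered(build(1.2), onsets)
  erb <- extract_event_triggered(build(0), onsets)
  ct <- contrast_timecourse(era, erb, paired = TRUE, n_perm = 500, seed = 2)
  sig <- ct$clusters[ct$clusters$p_corrected < 0.05, ]
  expect_gte(nrow(sig), 1)
  # earliest significant cluster begins near the -1.5 s transient onset
  expect_lt(abs(min(sig$start_s) - (-1.5)), 0.5)
})

test_that("intrusion analysis contrasts preferred- vs non-preferred-targeted blocks", {
  s <- small_session()
  ev <- s$sched$events
  if (sum(ev$event_type == "recall" & ev$is_intrusion %in% TRUE) == 0) {
    # the fixture seed draws no intrusions: error path must fire
    expect_error(intrusion_timecourse(s$hfb_ratio, ev, s$profiles,
                                      n_perm = 200), "intrusions")
  } else {
    succeed()
  }
  # constructed intrusion set at the envelope level
  rate <- 100
  n_el <- 12
  blocks <- tibble::tibble(
    onset = c(0, 300), duration = 300, event_type = "recall_block",
    item_id = NA_character_, category = NA_character_,
    target_category = c("face", "place"), is_intrusion = NA, run = 1L)
  intr <- tibble::tibble(
    onset = c(seq(40, 260, by = 30), seq(340, 560, by = 30)),
    duration = 3, event_type = "recall",
    item_id = "x",
    category = rep(c("place", "face"), each = 8),
    target_category = rep(c("face", "place"), each = 8),
    is_intrusion = TRUE, run = 1L)
  ev2 <- dplyr::bind_rows(blocks, intr)
  mats <- sapply(1:n_el, function(e) {
    tr <- simulate_hfb_trace(600, rate = rate, seed = 500 + e)
    # shift during preferred-targeted block collapses before each intrusion
    shift <- rep(0, length(tr))
    tg <- (seq_along(tr) - 1) / rate
    shift[tg < 300] <- 0.8
    for (o in intr$onset[intr$target_category == "face"]) {
      dipw <- tg >= o - 2 & tg <= o + 1
      shift[dipw] <- 0
    }
    db_amp(tr + shift)
  })
  h <- as_hfb_signal(mats, rate, "rest_ratio")
  prof <- structure(tibble::tibble(
    electrode_id = colnames(h$amplitude), responsive = TRUE,
    group = "face_selective", csi = NA_real_),
    class = c("selectivity_profiles", "tbl_df", "tbl", "data.frame"))
  res <- intrusion_timecourse(h, ev2, prof, n_perm = 300, seed = 3,
                              min_separation_s = 5)
  # preferred-targeted condition is higher well before the intrusion,
  # collapses to parity around onset
  tsel <- res$times < -4
  diff_pre <- mean(res$preferred_targeted[, tsel]) -
    mean(res$nonpreferred_targeted[, tsel])
  t0 <- abs(res$times) <= 0.5
  diff_at <- mean(res$preferred_targeted[, t0]) -
    mean(res$nonpreferred_targeted[, t0])
  expect_gt(diff_pre, 0.4)
  expect_lt(diff_at, 0.25)
})

test_that("prompt analysis excludes prompts too close to the next recall", {
  rate <- 100
  n_el <- 10
  blocks <- tibble::tibble(
    onset = c(0, 300), duration = 300, event_type = "recall_block",
    item_id = NA_character_, category = NA_character_,
    target_category = c("face", "place"), is_intrusion = NA, run = 1L)
  prompts <- tibble::tibble(
    onset = c(50, 120, 350, 420), duration = 2, event_type = "prompt",
    item_id = NA_character_, category = NA_character_,
    target_category = c("face", "face", "place", "place"),
    is_intrusion = NA, run = 1L)
  recalls <- tibble::tibble(
    onset = c(124, 200, 500), duration = 3, event_type = "recall",
    item_id = "x", category = c("face", "face", "place"),
    target_category = c("face", "face", "place"),
    is_intrusion = FALSE, run = 1L)
  ev <- dplyr::bind_rows(blocks, prompts, recalls)
  mats <- sapply(1:n_el, function(e)
    db_amp(simulate_hfb_trace(600, rate = rate, seed = 600 + e)))
  h <- as_hfb_signal(mats, rate, "rest_ratio")
  prof <- structure(tibble::tibble(
    electrode_id = colnames(h$amplitude), responsive = TRUE,
    group = "face_selective", csi = NA_real_),
    class = c("selectivity_profiles", "tbl_df", "tbl", "data.frame"))
  res <- prompt_timecourse(h, ev, prof, n_perm = 200, seed = 4)
  # the prompt at 120 s is 4 s before a recall: excluded; 3 remain
  expect_equal(res$n_eligible, 3)
  # per-event baseline normalization re-centers the pre-prompt window
  bsel <- res$times >= -5 & res$times <= -1
  expect_lt(abs(mean(res$preferred[, bsel])), 0.25)
})

test_that("post-prompt recovery appears only for preferred prompts", {
  rate <- 100
  n_el <- 10
  blocks <- tibble::tibble(
    onset = c(0, 300), duration = 300, event_type = "recall_block",
    item_id = NA_character_, category = NA_character_,
    target_category = c("face", "place"), is_intrusion = NA, run = 1L)
  prompts <- tibble::tibble(
    onset = c(60, 120, 180, 240, 360, 420, 480, 540), duration = 2,
    event_type = "prompt",
    item_id = NA_character_, category = NA_character_,
    target_category = rep(c("face", "place"), each = 4),
    is_intrusion = NA, run = 1L)
  ev <- dplyr::bind_rows(blocks, prompts)
  mats <- sapply(1:n_el, function(e) {
    tr <- simulate_hfb_trace(600, rate = rate, seed = 700 + e)
    tg <- (seq_along(tr) - 1) / rate
    add <- rep(0, length(tr))
    for (o in prompts$onset[prompts$target_category == "face"]) {
      add[tg >= o + 2 & tg <= o + 6] <- 1.5   # recovery after prompt offset
    }
    db_amp(tr + add)
  })
  h <- as_hfb_signal(mats, rate, "rest_ratio")
  prof <- structure(tibble::tibble(
    electrode_id = colnames(h$amplitude), responsive = TRUE,
    group = "face_selective", csi = NA_real_),
    class = c("selectivity_profiles", "tbl_df", "tbl", "data.frame"))
  res <- prompt_timecourse(h, ev, prof, n_perm = 300, seed = 5)
  sig <- res$test$clusters[res$test$clusters$p_corrected < 0.05, ]
  expect_gte(nrow(sig), 1)
  expect_gt(min(sig$start_s), 0)   # post-offset, not pre-prompt
})

test_that("ROI responses are baseline-normalized and lag is measurable", {
  rate <- 100
  onsets <- seq(30, 570, by = 18)
  lagged <- sapply(1:6, function(e) {
    tr <- simulate_hfb_trace(600, rate = rate, seed = 800 + e)
    db_amp(inject_recall_transients(tr, onsets + 0.6, 0.8, rate = rate))
  })
  visual <- sapply(1:6, function(e) {
    tr <- simulate_hfb_trace(600, rate = rate, seed = 900 + e)
    db_amp(inject_recall_transients(tr, onsets, 0.8, rate = rate))
  })
  h <- as_hfb_signal(cbind(lagged, visual), rate, "rest_ratio")
  colnames(h$amplitude) <- c(paste0("F", 1:6), paste0("V", 1:6))
  rois <- list(frontal = paste0("F", 1:6), visual = paste0("V", 1:6))
  res <- roi_event_response(h, onsets, rois, n_perm = 200, seed = 6)
  # per-event baseline normalization pins the baseline window near 0 dB
  # (exactly 1.0 in ratio terms; the dB average carries a small Jensen term)
  for (roi in res) {
    bsel <- roi$times >= -5 & roi$times <= -3
    expect_lt(abs(mean(roi$trace[bsel])), 0.15)
  }
  hc <- as_hfb_signal(matrix(3, 600 * rate, 4), rate, "rest_ratio")
  resc <- roi_event_response(hc, onsets, list(r = colnames(hc$amplitude)))
  expect_lt(max(abs(resc$r$trace)), 1e-9)
  # response lag via the centroid of the positive response
  centroid <- function(roi) {
    v <- pmax(roi$trace, 0)
    sum(roi$times * v) / sum(v)
  }
  expect_gte(centroid(res$frontal) - centroid(res$visual), 0.5 - 0.2)
  # two-bin summary distinguishes transient from baseline
  expect_gt(mean(res$frontal$bins$transient_db -
                   res$frontal$bins$baseline_db), 0.3)
  expect_error(roi_event_response(h, onsets, list(empty = character(0))),
               "empty ROI")
})
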