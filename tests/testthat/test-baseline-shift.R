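# Baseline-shift quantification: medians, stages, exclusion control, CSI
# correlation, recall order.

# events table with two runs x two 150-s blocks and optional recall events
toy_blocks <- function(recalls_per_block = 0, block_s = 150, seed = 1) {
  set.seed(seed)
  rows <- list()
  t <- 0
  for (r in 1:2) {
    order <- if (r == 1) c("face", "place") else c("place", "face")
    for (tc in order) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        onset = t, duration = block_s, event_type = "recall_block",
        item_id = NA_character_, category = NA_character_,
        target_category = tc, is_intrusion = NA, run = r)
      if (recalls_per_block > 0) {
        on <- sort(runif(recalls_per_block, t + 5, t + block_s - 10))
        on <- on[c(TRUE, diff(on) > 6)]
        rows[[length(rows) + 1]] <- tibble::tibble(
          onset = on, duration = 3, event_type = "recall",
          item_id = "x", category = tc, target_category = tc,
          is_intrusion = FALSE, run = r)
      }
      t <- t + block_s
    }
  }
  dplyr::bind_rows(rows)
}

toy_profiles <- function(groups) {
  structure(tibble::tibble(
    electrode_id = names(groups), responsive = TRUE, group = unname(groups),
    csi = NA_real_
  ), class = c("selectivity_profiles", "tbl_df", "tbl", "data.frame"))
}

shifted_cohort <- function(events, shifts_face, shifts_place, seed = 1,
                           rate = 500) {
  dur <- max(events$onset + events$duration)
  blocks <- recall_blocks(events)
  mats <- sapply(seq_along(shifts_face), function(e) {
    tr <- simulate_hfb_trace(dur, rate = rate, seed = seed * 997 + e)
    for (i in seq_len(nrow(blocks))) {
      idx <- seq(floor(blocks$start[i] * rate) + 1,
                 min(length(tr), floor(blocks$end[i] * rate)))
      s <- if (blocks$target_category[i] == "face") shifts_face[e]
           else shifts_place[e]
      tr[idx] <- tr[idx] + s
    }
    tr
  })
  as_hfb_signal(mats, rate, "db")
}

test_that("injected category shifts are recovered by the block medians", {
  ev <- toy_blocks()
  n <- 12
  h <- shifted_cohort(ev, shifts_face = rep(0.5, n), shifts_place = rep(0, n),
                      seed = 3)
  med <- median_recall_amplitude(h, ev)
  prof <- toy_profiles(setNames(rep("face_selective", n),
                                colnames(h$amplitude)))
  sel <- shift_selectivity(med, prof)
  expect_lt(abs(mean(sel$selectivity_db) - 0.5), 0.1)
  expect_equal(sel$selectivity_db, sel$median_face_db - sel$median_place_db)
})

test_that("null cohort shows ~0 selectivity", {
  ev <- toy_blocks()
  n <- 20
  h <- shifted_cohort(ev, rep(0, n), rep(0, n), seed = 4)
  med <- median_recall_amplitude(h, ev)
  prof <- toy_profiles(setNames(rep("face_selective", n),
                                colnames(h$amplitude)))
  sel <- shift_selectivity(med, prof)
  expect_equal(mean(sel$selectivity_db), 0, tolerance = 0.1)
})

test_that("a sustained shift survives the recall-exclusion control", {
  ev <- toy_blocks(recalls_per_block = 5, seed = 5)
  n <- 12
  h <- shifted_cohort(ev, rep(0.5, n), rep(0, n), seed = 5)
  prof <- toy_profiles(setNames(rep("face_selective", n),
                                colnames(h$amplitude)))
  sel_all <- shift_selectivity(median_recall_amplitude(h, ev), prof)
  sel_ex <- shift_selectivity(
    median_recall_amplitude(h, ev, exclude_recalls = TRUE), prof)
  expect_lt(abs(mean(sel_ex$selectivity_db) - mean(sel_all$selectivity_db)),
            0.05)
})

test_that("transient-only injection vanishes under recall exclusion", {
  ev <- toy_blocks(recalls_per_block = 8, seed = 6)
  rate <- 500
  n <- 16
  recalls <- dplyr::filter(ev, event_type == "recall")
  mats <- sapply(seq_len(n), function(e) {
    tr <- simulate_hfb_trace(600, rate = rate, sigma = 0.2, seed = 600 + e)
    # transients only at face-block recall onsets, no sustained shift
    on <- recalls$onset[recalls$target_category == "face"]
    inject_recall_transients(tr, on, peak_db = 1)
  })
  h <- as_hfb_signal(mats, rate, "db")
  prof <- toy_profiles(setNames(rep("face_selective", n),
                                colnames(h$amplitude)))
  sel_all <- shift_selectivity(median_recall_amplitude(h, ev), prof)
  sel_ex <- shift_selectivity(
    median_recall_amplitude(h, ev, exclude_recalls = TRUE), prof)
  expect_gt(mean(sel_all$selectivity_db), 0.05)
  expect_lt(abs(mean(sel_ex$selectivity_db)), 0.05)
})

test_that("stage gains are flat for a constant shift, front-loaded otherwise", {
  ev <- toy_blocks()
  rate <- 500
  n <- 16
  blocks <- recall_blocks(ev)
  build <- function(early_only) {
    mats <- sapply(seq_len(n), function(e) {
      tr <- simulate_hfb_trace(600, rate = rate, seed = 700 + e)
      for (i in which(blocks$target_category == "face")) {
        hi <- if (early_only) blocks$start[i] + 50 else blocks$end[i]
        idx <- seq(floor(blocks$start[i] * rate) + 1, floor(hi * rate))
        tr[idx] <- tr[idx] + 0.5
      }
      tr
    })
    as_hfb_signal(mats, rate, "db")
  }
  prof <- toy_profiles(setNames(rep("face_selective", n), sprintf("E%02d", 1:n)))
  sg_const <- stage_gain(build(FALSE), ev, prof)
  means <- tapply(sg_const$gain_db, sg_const$stage, mean)
  expect_lt(max(means) - min(means), 0.25)
  expect_true(all(means > 0.3))
  sg_early <- stage_gain(build(TRUE), ev, prof)
  m2 <- tapply(sg_early$gain_db, sg_early$stage, mean)
  expect_gt(m2[["early"]], 0.3)
  expect_lt(abs(m2[["middle"]]), 0.2)
  expect_lt(abs(m2[["late"]]), 0.2)
})

test_that("CSI correlates with recall selectivity when constructed to", {
  ev <- toy_blocks()
  n <- 30
  set.seed(9)
  csi_true <- runif(n, -1, 1)
  h <- shifted_cohort(ev, shifts_face = 0.6 * pmax(csi_true, 0),
                      shifts_place = 0.6 * pmax(-csi_true, 0), seed = 9)
  med <- median_recall_amplitude(h, ev)
  prof <- toy_profiles(setNames(
    ifelse(csi_true > 0, "face_selective", "place_selective"),
    colnames(h$amplitude)))
  prof$csi <- csi_true
  sel <- shift_selectivity(med, prof)
  ct <- csi_shift_correlation(prof, sel)
  expect_gte(ct$estimate, 0.8)
  expect_lt(ct$p, 0.001)
  # insufficient n
  expect_error(csi_shift_correlation(prof[1:2, ], sel[1:2, ]), "at least 5")
})

test_that("uncorrelated shifts give small rho and calibrated p", {
  ev <- toy_blocks()
  n <- 20
  ps <- vapply(1:20, function(r) {
    set.seed(1000 + r)
    csi_true <- runif(n, -1, 1)
    h <- shifted_cohort(ev, rep(0, n), rep(0, n), seed = 2000 + r)
    med <- median_recall_amplitude(h, ev)
    prof <- toy_profiles(setNames(
      ifelse(csi_true > 0, "face_selective", "place_selective"),
      colnames(h$amplitude)))
    prof$csi <- csi_true
    csi_shift_correlation(prof, shift_selectivity(med, prof))$p
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.7)  # mostly non-significant under the null
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("recall-order effect is recovered and destroyed by shuffling", {
  ev <- toy_blocks()
  rate <- 50                       # order analysis is rate-agnostic
  n <- 60
  blocks <- recall_blocks(ev)
  # low-noise envelopes: the 0.04 dB effect needs tight block medians
  mats <- sapply(seq_len(n), function(e) {
    tr <- simulate_hfb_trace(600, rate = rate, sigma = 0.15, tau_s = 0.3,
                             seed = 800 + e, state = "ratio")
    for (r in 1:2) {
      rb <- blocks[blocks$run == r, ]
      rb <- rb[order(rb$start), ]
      idx <- seq(floor(rb$start[2] * rate) + 1, floor(rb$end[2] * rate))
      tr[idx] <- tr[idx] * 10^(0.04 / 10)
    }
    tr
  })
  h <- as_hfb_signal(mats, rate, "rest_ratio")
  prof <- toy_profiles(setNames(rep(c("face_selective", "place_selective"),
                                    n / 2), colnames(h$amplitude)))
  tab <- recall_order_analysis(h, ev, prof)
  est <- mean(tab$median_db[tab$order == "second"]) -
    mean(tab$median_db[tab$order == "first"])
  expect_lt(abs(est - 0.04), 0.02)
  # shuffled order labels destroy the effect
  set.seed(10)
  tab2 <- tab
  tab2$order <- sample(tab2$order)
  est2 <- mean(tab2$median_db[tab2$order == "second"]) -
    mean(tab2$median_db[tab2$order == "first"])
  expect_lt(abs(est2), abs(est))
})
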