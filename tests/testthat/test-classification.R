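# Electrode classification: responsiveness, latency, selectivity, CSI,
# grouping, item ranking.

# build a compact epochs object directly: trials x electrodes with known
# per-trial response/baseline structure
toy_epochs <- function(n_trials = 56, gains, latency_s = 0.12, noise = 0.08,
                       seed = 1, rate = 500, categories = NULL) {
  set.seed(seed)
  times <- seq(-0.5, 1.75, by = 1 / rate)
  n_el <- length(gains)
  if (is.null(categories))
    categories <- rep(c("face", "place"), length.out = n_trials)
  items <- paste0("i", rep(seq_len(14), length.out = n_trials))
  arr <- array(NA_real_, c(length(times), n_trials, n_el),
               dimnames = list(NULL, NULL, names(gains)))
  for (j in seq_len(n_el)) {
    for (tr in seq_len(n_trials)) {
      g <- if (is.list(gains)) {
        gg <- gains[[j]]
        if (length(gg) == 2) gg[[categories[tr]]] else gg
      } else gains[j]
      shape <- ifelse(times >= latency_s, 1, 0) * (g - 1) + 1
      arr[, tr, j] <- shape * exp(rnorm(length(times), 0, noise))
    }
  }
  structure(
    list(amplitude = arr, times = times, rate = rate,
         state = "prestim_ratio",
         trials = tibble::tibble(trial = seq_len(n_trials), run = 1L,
                                 item_id = items, category = categories,
                                 onset = seq_len(n_trials) * 3,
                                 clean = TRUE),
         electrode_ids = names(gains)),
    class = "hfb_epochs")
}

test_that("responsiveness test flags driven electrodes, spares null ones", {
  ep <- toy_epochs(gains = c(driven = 3, null = 1), seed = 2)
  res <- test_responsiveness(ep)
  expect_true(res$responsive[res$electrode_id == "driven"])
  expect_false(res$responsive[res$electrode_id == "null"])
  # identical response and baseline -> p = 1 behaviour, not flagged
  flat <- toy_epochs(gains = c(f = 1), noise = 0, seed = 3)
  resf <- test_responsiveness(flat)
  expect_false(resf$responsive)
  expect_equal(resf$p, 1)
})

test_that("null electrodes are false-flagged at about the FDR level", {
  # 100 null electrodes over several repetitions: BH at 0.01 should flag
  # about 1% of truly-null electrodes at most (in expectation, fewer)
  flags <- unlist(lapply(1:10, function(r) {
    ep <- toy_epochs(gains = setNames(rep(1, 100), paste0("e", 1:100)),
                     n_trials = 20, seed = 100 + r)
    test_responsiveness(ep)$responsive
  }))
  expect_lt(mean(flags), 0.02)
})

test_that("response latency finds the onset and honours the 50-ms rule", {
  ep <- toy_epochs(gains = c(e = 3), latency_s = 0.12, noise = 0.05, seed = 4)
  lat <- response_latency(ep, "e")
  expect_equal(lat, 120, tolerance = 10)
  # null electrode: no sustained run
  epn <- toy_epochs(gains = c(e = 1), seed = 5)
  expect_true(is.na(response_latency(epn, "e")))
  # a 40-ms blip of deterministic signal is below the minimum duration
  ep2 <- toy_epochs(gains = c(e = 1), noise = 0.05, seed = 6)
  blip <- ep2$times >= 0.2 & ep2$times < 0.24
  ep2$amplitude[blip, , 1] <- ep2$amplitude[blip, , 1] * 3
  expect_true(is.na(response_latency(ep2, "e")))
})

test_that("category selectivity respects direction, FDR and V1/V2 exclusion", {
  ep <- toy_epochs(gains = list(f = list(face = 2, place = 1),
                                p = list(face = 1, place = 2),
                                n = 1.5,
                                v = list(face = 2, place = 1)),
                   seed = 7)
  anat <- c(f = "higher_order", p = "higher_order", n = "higher_order",
            v = "V1")
  sel <- test_category_selectivity(ep, c("f", "p", "n", "v"), anat)
  expect_equal(sel$label[sel$electrode_id == "f"], "face_selective")
  expect_equal(sel$label[sel$electrode_id == "p"], "place_selective")
  expect_true(is.na(sel$label[sel$electrode_id == "n"]))
  # selective profile but V1 label: excluded from face/place groups
  expect_true(is.na(sel$label[sel$electrode_id == "v"]))
})

test_that("equal gains are rarely declared selective", {
  hits <- vapply(1:20, function(r) {
    ep <- toy_epochs(gains = list(a = 1.5, b = 1.5, c = 1.5, d = 1.5),
                     seed = 200 + r)
    any(test_category_selectivity(ep, c("a", "b", "c", "d"),
                                  c(a = "higher_order", b = "higher_order",
                                    c = "higher_order",
                                    d = "higher_order"))$selective)
  }, logical(1))
  expect_lt(mean(hits), 0.05 + 1e-9)
})

test_that("CSI follows its closed form, bounds, and symmetries", {
  expect_equal(compute_csi(0.8, 0), 1)
  expect_equal(compute_csi(0.5, 0.5), 0)
  expect_equal(compute_csi(0.3, 0.6), -1 / 3)
  expect_error(compute_csi(0, 0), "undefined")
  expect_error(compute_csi(-0.1, 0.5), "non-negative")
  # grid: antisymmetry, scale invariance, bounds
  grid <- expand.grid(f = seq(0, 1, 0.2), p = seq(0, 1, 0.2))
  grid <- grid[grid$f + grid$p > 0, ]
  v <- compute_csi(grid$f, grid$p)
  expect_true(all(v >= -1 & v <= 1))
  expect_equal(compute_csi(grid$p, grid$f), -v)
  expect_equal(compute_csi(3 * grid$f, 3 * grid$p), v)
})

test_that("group assignment applies the latency and anatomy rules", {
  profiles <- tibble::tibble(
    electrode_id = c("a", "b", "c", "d", "e"),
    responsive = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    latency_ms = c(150, 220, 140, 150, 100),
    label = c(NA, NA, "face_selective", NA, NA)
  )
  anat <- c(a = "V1", b = "V1", c = "higher_order", d = "intermediate",
            e = "V2")
  out <- assign_groups(profiles, anat)
  expect_equal(out$group, c("V1", "other", "face_selective", "intermediate",
                            NA))
  expect_error(assign_groups(profiles, anat[-1]), "anatomical")
  # every responsive electrode gets exactly one group
  expect_true(all(!is.na(out$group[out$responsive])))
})

test_that("item ranking orders by viewing response with deterministic ties", {
  set.seed(8)
  n_items <- 28
  gains <- setNames(seq(1.1, 3.8, length.out = n_items),
                    paste0("i", sprintf("%02d", 1:n_items)))
  times <- seq(-0.5, 1.75, by = 1 / 100)
  n_trials <- n_items * 2
  items <- rep(names(gains), 2)
  arr <- array(NA_real_, c(length(times), n_trials, 1),
               dimnames = list(NULL, NULL, "e"))
  for (tr in seq_len(n_trials)) {
    shape <- ifelse(times >= 0.1, gains[[items[tr]]], 1)
    arr[, tr, 1] <- shape * exp(rnorm(length(times), 0, 0.01))
  }
  ep <- structure(
    list(amplitude = arr, times = times, rate = 100, state = "prestim_ratio",
         trials = tibble::tibble(trial = seq_len(n_trials), run = 1L,
                                 item_id = items,
                                 category = rep(c("face", "place"),
                                                each = n_items),
                                 onset = seq_len(n_trials), clean = TRUE),
         electrode_ids = "e"),
    class = "hfb_epochs")
  rk <- rank_items(ep, "e", k = 10)
  expect_equal(rk$ranking$item_id[1], names(which.max(gains)))
  expect_equal(rk$top, rev(names(gains))[1:10])
  expect_setequal(rk$bottom, names(gains)[1:10])
  expect_equal(length(intersect(rk$top, rk$bottom)), 0)
  expect_equal(length(setdiff(rk$ranking$item_id,
                              c(rk$top, rk$bottom))), 8)
  expect_error(rank_items(ep, "e", k = 20), "exceeds")
  # all-equal gains: tie-break by item id
  arr2 <- arr; arr2[] <- 1
  ep2 <- ep; ep2$amplitude <- arr2
  rk2 <- rank_items(ep2, "e", k = 10)
  expect_equal(rk2$ranking$item_id, sort(names(gains)))
})

test_that("full classification recovers the generator's groups", {
  s <- small_session()
  got <- s$profiles$group
  names(got) <- s$profiles$electrode_id
  truth <- setNames(s$gt$group, s$gt$electrode_id)
  # every category-selective ground-truth electrode is recovered
  sel_ids <- names(truth)[truth %in% c("face_selective", "place_selective")]
  expect_equal(got[sel_ids], truth[sel_ids])
  # V1/V2 recovered with their short latencies
  early <- names(truth)[truth %in% c("V1", "V2")]
  expect_equal(got[early], truth[early])
  # CSI sign matches preferred category
  pref <- preferred_category(s$profiles)
  csi <- setNames(s$profiles$csi, s$profiles$electrode_id)
  expect_true(all(csi[names(pref)[pref %in% "face"]] > 0))
  expect_true(all(csi[names(pref)[pref %in% "place"]] < 0))
})
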