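# Electrode classification: visual responsiveness, response latency,
# category selectivity, the category-selectivity index (CSI), group
# assignment, and item ranking.

#' Test visual responsiveness of every electrode
#'
#' Pairs, per trial, the mean normalized response in the 100-500 ms
#' post-stimulus window against the mean in the -400..-100 ms pre-stimulus
#' baseline, and runs a two-tailed paired t-test per electrode. The p-values
#' of all electrodes (pooled across patients when several epoch sets are
#' supplied) are corrected together by Benjamini-Hochberg FDR.
#'
#' @param epochs An `hfb_epochs` object, or a list of them (one per patient).
#' @param alpha FDR level (default 0.01).
#' @param response_s,baseline_s Averaging windows (defaults 0.1-0.5 and
#'   -0.4..-0.1 s).
#' @return Tibble with `electrode_id`, `t`, `p`, `q`, `responsive`.
#' @export
test_responsiveness <- function(epochs, alpha = 0.01,
                                response_s = c(0.1, 0.5),
                                baseline_s = c(-0.4, -0.1)) {
  sets <- if (inherits(epochs, "hfb_epochs")) list(epochs) else epochs
  res <- purrr::map_dfr(sets, function(ep) {
    resp <- epoch_window_mean(ep, response_s)
    base <- epoch_window_mean(ep, baseline_s)
    if (nrow(resp) < 10) abort("need at least 10 trials per electrode")
    purrr::map_dfr(seq_len(ncol(resp)), function(j) {
      d <- resp[, j] - base[, j]
      if (sd(d) == 0) {
        tibble(electrode_id = ep$electrode_ids[j], t = 0, p = 1)
      } else {
        tt <- t.test(resp[, j], base[, j], paired = TRUE)
        tibble(electrode_id = ep$electrode_ids[j],
               t = unname(tt$statistic), p = tt$p.value)
      }
    })
  })
  fdr <- bh_fdr(res$p, alpha = alpha)
  res$q <- fdr$q
  res$responsive <- fdr$reject
  res
}

#' Estimate the visual response latency of an electrode
#'
#' Compares, at every post-stimulus sample, the amplitude across trials to
#' each trial's pre-stimulus baseline mean (paired t-test, the same pairing
#' as the responsiveness test). The latency is the first time point at which
#' p < `alpha` holds continuously for at least `min_duration_ms`.
#'
#' @param epochs An `hfb_epochs` object.
#' @param electrode_id Electrode to analyse.
#' @param alpha Per-sample threshold (default 0.05).
#' @param min_duration_ms Minimum run of significance (default 50 ms).
#' @param baseline_s Baseline window (default -0.4..-0.1 s).
#' @return Latency in ms, or `NA_real_` when no sustained run exists.
#' @export
response_latency <- function(epochs, electrode_id, alpha = 0.05,
                             min_duration_ms = 50,
                             baseline_s = c(-0.4, -0.1)) {
  j <- match(electrode_id, epochs$electrode_ids)
  if (is.na(j)) abort("unknown electrode")
  bsel <- epochs$times >= baseline_s[1] & epochs$times <= baseline_s[2]
  base <- colMeans(epochs$amplitude[bsel, , j, drop = FALSE][, , 1])
  post <- which(epochs$times >= 0)
  amp <- epochs$amplitude[post, , j]           # time x trial
  d <- sweep(amp, 2, base)                      # per-trial paired differences
  nt <- ncol(d)
  m <- rowMeans(d)
  s <- sqrt(pmax(rowSums((d - m)^2) / (nt - 1), 0))
  tstat <- m / (s / sqrt(nt))
  p <- 2 * pt(abs(tstat), df = nt - 1, lower.tail = FALSE)
  sig <- p < alpha
  need <- max(1L, round(min_duration_ms / 1000 * epochs$rate))
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= need)
  if (length(ok) == 0) return(NA_real_)
  epochs$times[post[starts[ok[1]]]] * 1000
}

#' Test category selectivity (faces vs places)
#'
#' Averages the normalized response over 100-500 ms per trial, transforms to
#' dB, and compares face against place trials with a two-tailed two-sample
#' t-test per electrode; p-values are BH-FDR corrected across the tested
#' (responsive) electrodes. Electrodes anatomically inside V1/V2 are excluded
#' from face/place labels.
#'
#' @param epochs An `hfb_epochs` object.
#' @param electrode_ids Electrodes to test (typically the responsive ones).
#' @param anatomical Named character vector mapping electrode id to
#'   anatomical label (`V1`, `V2`, ...).
#' @param alpha FDR level (default 0.01).
#' @param var_equal Classic equal-variance t (default TRUE); set FALSE for
#'   Welch.
#' @return Tibble with `electrode_id`, `t`, `p`, `q`, `selective`, `label`
#'   (`face_selective` / `place_selective` / `NA`).
#' @export
test_category_selectivity <- function(epochs, electrode_ids, anatomical,
                                      alpha = 0.01, var_equal = TRUE) {
  resp <- epoch_window_mean(epochs, c(0.1, 0.5))
  cats <- epochs$trials$category
  if (length(unique(cats)) < 2) abort("both categories must be present")
  res <- purrr::map_dfr(electrode_ids, function(id) {
    j <- match(id, epochs$electrode_ids)
    rdb <- to_db(resp[, j])
    tt <- t.test(rdb[cats == "face"], rdb[cats == "place"],
                 var.equal = var_equal)
    tibble(electrode_id = id, t = unname(tt$statistic), p = tt$p.value)
  })
  fdr <- bh_fdr(res$p, alpha = alpha)
  res$q <- fdr$q
  in_v1v2 <- anatomical[res$electrode_id] %in% c("V1", "V2")
  res$selective <- fdr$reject & !in_v1v2
  res$label <- dplyr::case_when(
    res$selective & res$t > 0 ~ "face_selective",
    res$selective & res$t < 0 ~ "place_selective",
    TRUE ~ NA_character_
  )
  res
}

#' Category-selectivity index
#'
#' `CSI = (R_faces - R_places) / (R_faces + R_places)`, where the two means
#' are the stimulus responses per category averaged over 100-500 ms
#' post-stimulus and normalized by the electrode's maximal stimulus response.
#' CSI ranges from -1 (pure place preference) to +1 (pure face preference).
#'
#' @param r_faces,r_places Non-negative normalized mean responses.
#' @return The index, in `[-1, 1]`.
#' @export
#' @examples
#' compute_csi(0.8, 0)    # 1
#' compute_csi(0.3, 0.6)  # -1/3
compute_csi <- function(r_faces, r_places) {
  if (any(r_faces < 0) || any(r_places < 0))
    abort("mean responses must be non-negative")
  s <- r_faces + r_places
  if (any(s == 0)) abort("CSI undefined when both mean responses are zero")
  (r_faces - r_places) / s
}

# per-electrode CSI from epochs: item-level means, max-normalized
csi_from_epochs <- function(epochs, electrode_id) {
  resp <- epoch_window_mean(epochs, c(0.1, 0.5))
  j <- match(electrode_id, epochs$electrode_ids)
  per_item <- tapply(resp[, j], epochs$trials$item_id, mean)
  norm <- max(per_item)  # maximal single-item stimulus response
  cats <- epochs$trials$category[match(names(per_item),
                                       epochs$trials$item_id)]
  r_f <- mean(per_item[cats == "face"]) / norm
  r_p <- mean(per_item[cats == "place"]) / norm
  compute_csi(max(r_f, 0), max(r_p, 0))
}

#' Assign the five electrode groups
#'
#' V1/V2: anatomical V1/V2 label AND response latency at most 180 ms.
#' Face-/place-selective: significant category selectivity outside V1/V2.
#' Intermediate: responsive, anatomically intermediate retinotopic, not
#' category selective. Everything else responsive: `other`. Non-responsive
#' electrodes get `NA`.
#'
#' @param profiles Tibble with `electrode_id`, `responsive`, `latency_ms`,
#'   `label` (from [test_category_selectivity()]).
#' @param anatomical Named character vector of anatomical labels.
#' @param max_latency_ms Early-visual latency criterion (default 180).
#' @return The profiles tibble with a `group` column added.
#' @export
assign_groups <- function(profiles, anatomical, max_latency_ms = 180) {
  if (any(!profiles$electrode_id %in% names(anatomical)))
    abort("missing anatomical label")
  anat <- anatomical[profiles$electrode_id]
  profiles$group <- dplyr::case_when(
    !profiles$responsive ~ NA_character_,
    anat %in% c("V1", "V2") & !is.na(profiles$latency_ms) &
      profiles$latency_ms <= max_latency_ms ~ unname(anat),
    !is.na(profiles$label) ~ profiles$label,
    anat == "intermediate" ~ "intermediate",
    TRUE ~ "other"
  )
  profiles
}

#' Rank items by viewing response
#'
#' Items are ordered by their mean viewing response (100-500 ms window, dB),
#' pooled over runs; ties break deterministically by item id. The top-k
#' "preferred" and bottom-k "non-preferred" sets exclude the borderline
#' middle.
#'
#' @param epochs An `hfb_epochs` object.
#' @param electrode_id Electrode to rank for.
#' @param k Set size (default 10).
#' @return List with `ranking` (tibble `item_id`, `mean_db`, ordered best
#'   first), `top` and `bottom` (character vectors of k item ids).
#' @export
rank_items <- function(epochs, electrode_id, k = 10) {
  resp <- epoch_window_mean(epochs, c(0.1, 0.5))
  j <- match(electrode_id, epochs$electrode_ids)
  per_item <- tapply(to_db(resp[, j]), epochs$trials$item_id, mean)
  if (2 * k > length(per_item)) abort("k exceeds half the item count")
  ord <- order(-per_item, names(per_item))
  ranking <- tibble(item_id = names(per_item)[ord],
                    mean_db = unname(per_item[ord]))
  list(ranking = ranking,
       top = ranking$item_id[seq_len(k)],
       bottom = rev(ranking$item_id)[seq_len(k)])
}

#' Full electrode classification
#'
#' Convenience wrapper running responsiveness, latency, selectivity, CSI,
#' grouping and item ranking over one epochs object.
#'
#' @param epochs An `hfb_epochs` object.
#' @param electrodes Electrode table (`name`, `group` anatomical label).
#' @param alpha_responsive,alpha_selective FDR levels (defaults 0.01).
#' @param k Preferred/non-preferred set size (default 10; reduced to fit when
#'   fewer items are available).
#' @return A `selectivity_profiles` tibble: `electrode_id`, `responsive`,
#'   `q`, `latency_ms`, `csi`, `category_q`, `group`, plus list-columns
#'   `top_items`, `bottom_items`.
#' @export
classify_electrodes <- function(epochs, electrodes,
                                alpha_responsive = 0.01,
                                alpha_selective = 0.01, k = 10) {
  anatomical <- setNames(electrodes$group, electrodes$name)
  rsp <- test_responsiveness(epochs, alpha = alpha_responsive)
  rsp$latency_ms <- NA_real_
  for (i in which(rsp$responsive)) {
    rsp$latency_ms[i] <- response_latency(epochs, rsp$electrode_id[i])
  }
  resp_ids <- rsp$electrode_id[rsp$responsive]
  if (length(resp_ids) > 0) {
    sel <- test_category_selectivity(epochs, resp_ids, anatomical,
                                     alpha = alpha_selective)
    rsp <- left_join(rsp, select(sel, "electrode_id", category_q = "q",
                                 "label"), by = "electrode_id")
  } else {
    rsp$category_q <- NA_real_
    rsp$label <- NA_character_
  }
  rsp <- assign_groups(rsp, anatomical)
  k_use <- min(k, floor(length(unique(epochs$trials$item_id)) / 2))
  rsp$csi <- NA_real_
  rsp$top_items <- vector("list", nrow(rsp))
  rsp$bottom_items <- vector("list", nrow(rsp))
  for (i in which(rsp$responsive)) {
    id <- rsp$electrode_id[i]
    rsp$csi[i] <- csi_from_epochs(epochs, id)
    rk <- rank_items(epochs, id, k = k_use)
    rsp$top_items[[i]] <- rk$top
    rsp$bottom_items[[i]] <- rk$bottom
  }
  class(rsp) <- c("selectivity_profiles", class(rsp))
  rsp
}

#' Preferred category of each profiled electrode
#'
#' @param profiles A `selectivity_profiles` tibble.
#' @return Named character vector (`face` / `place` / `NA`) keyed by
#'   electrode id.
#' @export
preferred_category <- function(profiles) {
  setNames(dplyr::case_when(
    profiles$group == "face_selective" ~ "face",
    profiles$group == "place_selective" ~ "place",
    TRUE ~ NA_character_
  ), profiles$electrode_id)
}
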