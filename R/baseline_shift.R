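# Sustained baseline-shift quantification during free recall.
#
# The central quantity is the median rest-normalized HFB amplitude (dB) over
# each 150-s recall block, per electrode and recalled category, averaged
# across runs. "Selectivity" is the median during recall of the electrode's
# preferred category minus the median during recall of the non-preferred one.

#' Median recall-block amplitude per electrode and category
#'
#' Computes, for every electrode, the median dB amplitude over the samples of
#' each recall block (artifact-masked samples excluded), then averages the
#' per-block medians across runs within recalled category. With
#' `exclude_recalls = TRUE` the samples from 2 s before the onset until the
#' offset of every individual recall event are additionally removed -- the
#' control that separates a sustained shift from accumulated transients.
#'
#' @param hfb An `hfb_signal` in state `"db"` (rest-normalized).
#' @param events Events tibble (provides recall blocks and recall events).
#' @param mask Optional `artifact_mask`.
#' @param exclude_recalls Remove recall-event windows (default FALSE).
#' @param pre_onset_s Seconds before each recall onset to drop when excluding
#'   (default 2).
#' @return Tibble with `electrode_id`, `category`, `median_db` (one row per
#'   electrode x recalled category).
#' @export
median_recall_amplitude <- function(hfb, events, mask = NULL,
                                    exclude_recalls = FALSE,
                                    pre_onset_s = 2) {
  if (hfb$state != "db") abort("median_recall_amplitude expects a dB signal")
  blocks <- recall_blocks(events)
  recalls <- events %>% filter(.data$event_type == "recall")
  n <- nrow(hfb$amplitude)
  keep_all <- if (is.null(mask)) rep(TRUE, n) else !mask$excluded

  per_block <- purrr::map_dfr(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    idx <- sample_range(b$start, b$end, hfb$rate, n)
    keep <- keep_all[idx]
    if (exclude_recalls && nrow(recalls) > 0) {
      tt <- hfb$t0 + (idx - 1) / hfb$rate
      inside <- rep(FALSE, length(idx))
      rr <- recalls %>% filter(.data$onset >= b$start, .data$onset < b$end)
      for (k in seq_len(nrow(rr))) {
        inside <- inside | (tt >= rr$onset[k] - pre_onset_s &
                              tt < rr$onset[k] + rr$duration[k])
      }
      keep <- keep & !inside
    }
    if (!any(keep)) abort("recall block empty after exclusions")
    med <- apply(hfb$amplitude[idx[keep], , drop = FALSE], 2, median)
    tibble(electrode_id = colnames(hfb$amplitude),
           run = b$run, category = b$target_category, median_db = unname(med))
  })
  per_block %>%
    group_by(.data$electrode_id, .data$category) %>%
    summarise(median_db = mean(.data$median_db), .groups = "drop")
}

#' Baseline-shift selectivity per category-selective electrode
#'
#' Preferred-minus-non-preferred median recall amplitude, plus the signed
#' (face minus place) difference used for the CSI correlation.
#'
#' @param medians Output of [median_recall_amplitude()].
#' @param profiles A `selectivity_profiles` tibble (provides the preferred
#'   category per electrode).
#' @return Tibble with `electrode_id`, `group`, `median_face_db`,
#'   `median_place_db`, `selectivity_db` (preferred - non-preferred) and
#'   `signed_db` (face - place).
#' @export
shift_selectivity <- function(medians, profiles) {
  pref <- preferred_category(profiles)
  wide <- medians %>%
    tidyr::pivot_wider(names_from = "category", values_from = "median_db",
                       names_prefix = "median_") %>%
    rename(median_face_db = "median_face", median_place_db = "median_place")
  wide$group <- profiles$group[match(wide$electrode_id,
                                     profiles$electrode_id)]
  wide$signed_db <- wide$median_face_db - wide$median_place_db
  p <- unname(pref[wide$electrode_id])
  wide$selectivity_db <- ifelse(is.na(p), NA_real_,
                                ifelse(p == "face", wide$signed_db,
                                       -wide$signed_db))
  wide %>% select("electrode_id", "group", "median_face_db",
                  "median_place_db", "signed_db", "selectivity_db")
}

#' Early/middle/late stage gains
#'
#' Splits each 150-s recall block into 0-50, 50-100 and 100-150 s stages and
#' computes the preferred-minus-non-preferred median amplitude per stage
#' (averaged across runs).
#'
#' @param hfb An `hfb_signal` in state `"db"`.
#' @param events Events tibble.
#' @param profiles A `selectivity_profiles` tibble.
#' @param mask Optional `artifact_mask`.
#' @param stage_s Stage length in seconds (default 50).
#' @return Tibble with `electrode_id`, `stage` (`early`/`middle`/`late`),
#'   `gain_db`.
#' @export
stage_gain <- function(hfb, events, profiles, mask = NULL, stage_s = 50) {
  if (hfb$state != "db") abort("stage_gain expects a dB signal")
  blocks <- recall_blocks(events)
  if (any(blocks$end - blocks$start < 3 * stage_s - 1e-9))
    abort("recall blocks shorter than three stages")
  n <- nrow(hfb$amplitude)
  keep_all <- if (is.null(mask)) rep(TRUE, n) else !mask$excluded
  stage_names <- c("early", "middle", "late")

  per <- purrr::map_dfr(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    purrr::map_dfr(seq_along(stage_names), function(s) {
      idx <- sample_range(b$start + (s - 1) * stage_s,
                          b$start + s * stage_s, hfb$rate, n)
      idx <- idx[keep_all[idx]]
      med <- apply(hfb$amplitude[idx, , drop = FALSE], 2, median)
      tibble(electrode_id = colnames(hfb$amplitude), run = b$run,
             category = b$target_category, stage = stage_names[s],
             median_db = unname(med))
    })
  })
  pref <- preferred_category(profiles)
  per <- per %>%
    group_by(.data$electrode_id, .data$category, .data$stage) %>%
    summarise(median_db = mean(.data$median_db), .groups = "drop")
  wide <- tidyr::pivot_wider(per, names_from = "category",
                             values_from = "median_db")
  p <- pref[wide$electrode_id]
  wide$gain_db <- ifelse(p == "face", wide$face - wide$place,
                         wide$place - wide$face)
  wide %>% filter(!is.na(.data$gain_db)) %>%
    mutate(stage = factor(.data$stage, levels = stage_names)) %>%
    select("electrode_id", "stage", "gain_db")
}

#' Correlate viewing-stage CSI with recall-stage selectivity
#'
#' Spearman rank correlation between each electrode's category-selectivity
#' index during viewing and its signed (face minus place) baseline-shift
#' during recall. A positive correlation means category preference is
#' preserved from perception to recall.
#'
#' @param profiles A `selectivity_profiles` tibble with `csi`.
#' @param selectivity Output of [shift_selectivity()] (uses `signed_db`).
#' @param electrode_ids Electrodes to include (default: all with both values).
#' @return A `recall_htest` (Spearman rho, p).
#' @export
csi_shift_correlation <- function(profiles, selectivity,
                                  electrode_ids = NULL) {
  merged <- dplyr::inner_join(
    select(profiles, "electrode_id", "csi"),
    select(selectivity, "electrode_id", "signed_db"),
    by = "electrode_id"
  ) %>% filter(complete.cases(.data$csi, .data$signed_db))
  if (!is.null(electrode_ids))
    merged <- filter(merged, .data$electrode_id %in% electrode_ids)
  if (nrow(merged) < 5) abort("need at least 5 electrodes")
  spearman_cor(merged$csi, merged$signed_db)
}

#' Recall-order analysis inputs
#'
#' Re-normalizes each electrode's recall-session amplitude by that run's mean
#' amplitude across the entire free-recall session (both blocks), then
#' computes the median dB per electrode x recalled category x recall order
#' (whether the category was targeted first or second within the run).
#' The result feeds [mixed_anova()] with factors electrode group, recalled
#' category and recall order.
#'
#' @param hfb An `hfb_signal` in state `"rest_ratio"`.
#' @param events Events tibble.
#' @param profiles A `selectivity_profiles` tibble.
#' @param mask Optional `artifact_mask`.
#' @return Tibble with `electrode_id`, `group`, `run`, `category`,
#'   `order` (`first`/`second`), `preferred` and `median_db`.
#' @export
recall_order_analysis <- function(hfb, events, profiles, mask = NULL) {
  if (hfb$state != "rest_ratio")
    abort("recall_order_analysis expects a rest_ratio signal")
  blocks <- recall_blocks(events)
  if (length(unique(blocks$run)) < 2) abort("need two runs")
  n <- nrow(hfb$amplitude)
  keep_all <- if (is.null(mask)) rep(TRUE, n) else !mask$excluded
  pref <- preferred_category(profiles)

  purrr::map_dfr(unique(blocks$run), function(r) {
    rb <- blocks %>% filter(.data$run == r) %>% arrange(.data$start)
    sess_idx <- unlist(lapply(seq_len(nrow(rb)), function(i)
      sample_range(rb$start[i], rb$end[i], hfb$rate, n)))
    sess_idx <- sess_idx[keep_all[sess_idx]]
    sess_mean <- colMeans(hfb$amplitude[sess_idx, , drop = FALSE])
    purrr::map_dfr(seq_len(nrow(rb)), function(i) {
      idx <- sample_range(rb$start[i], rb$end[i], hfb$rate, n)
      idx <- idx[keep_all[idx]]
      norm <- sweep(hfb$amplitude[idx, , drop = FALSE], 2, sess_mean, `/`)
      med <- apply(norm, 2, median)
      ids <- colnames(hfb$amplitude)
      tibble(
        electrode_id = ids,
        group = profiles$group[match(ids, profiles$electrode_id)],
        run = r, category = rb$target_category[i],
        order = if (i == 1) "first" else "second",
        preferred = ifelse(is.na(pref[ids]), NA,
                           pref[ids] == rb$target_category[i]),
        median_db = amp_db(unname(med))
      )
    })
  })
}
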