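# Ground-truth electrode parameters for the synthetic cohort.
#
# Every downstream stage is validated by parameter recovery, so each synthetic
# electrode carries the generative parameters the analyses should recover:
# per-item viewing gains, a per-category sustained baseline shift during
# matching recall blocks, a signed recall-onset-locked transient, optional
# sporadic-burst injections, and the log-envelope statistics.

#' Default ground-truth electrode cohort
#'
#' Builds the parameter table for one synthetic "patient": early visual
#' electrodes (V1/V2, short latency, strong but category-agnostic viewing
#' responses), intermediate visual electrodes, category-selective high-order
#' electrodes (face/place) carrying the sustained recall baseline shift and
#' the recall-locked transient, non-visual "other" electrodes, and frontal /
#' parietal ROI electrodes whose recall-locked response lags the visual one.
#'
#' @param n_face,n_place Number of face-/place-selective electrodes (default
#'   6 each, so the selective cohort supports the dynamics classification).
#' @param n_v1,n_v2,n_intermediate,n_other,n_frontal,n_parietal Counts of the
#'   remaining groups (defaults 2 each).
#' @param items Tibble with `item_id`, `category` (one row per picture across
#'   all runs); usually taken from a [make_task_schedule()] events table.
#' @param shift_db Sustained baseline shift (dB, amplitude) applied to
#'   category-selective electrodes during recall blocks targeting their
#'   preferred category (default 0.5, the size seen in strongly selective
#'   electrodes).
#' @param transient_db Peak dB of the recall-onset-locked transient (default
#'   0.17, the observed peak differential amplitude); applied positively for
#'   preferred-category recalls and negatively for non-preferred ones.
#' @param envelope_sigma Standard deviation of the AR(1) log-amplitude
#'   envelope (default 0.4, i.e. about 1.7 dB).
#' @param envelope_tau_s Autocorrelation time of the log-envelope (default 1 s).
#' @param noise_exponent Spectral slope of the 1/f background (PSD slope
#'   `-noise_exponent`; default 2.5).
#' @param pref_gain,nonpref_gain Viewing amplitude gains for preferred /
#'   non-preferred category items at selective electrodes (defaults 2.5, 1.2).
#' @param roi_lag_s Extra response latency of frontal ROI electrodes relative
#'   to the visual recall transient (default 0.6 s).
#' @param intrusion_dip,prompt_dip Emulate the transient collapse of the
#'   baseline shift before intrusion errors and before prompts (defaults TRUE).
#' @param order_effect_db Extra amplitude (dB) added to recall blocks targeted
#'   second within a run (default 0; the recall-order analysis recovers it).
#' @param seed Seed controlling per-item gain jitter.
#' @return Tibble, one row per electrode, with list-column `viewing_gain`
#'   (named per-item amplitude gains) plus all generative parameters; carries
#'   class `ground_truth`.
#' @export
ground_truth_electrodes <- function(n_face = 6, n_place = 6, n_v1 = 2,
                                    n_v2 = 2, n_intermediate = 2, n_other = 2,
                                    n_frontal = 2, n_parietal = 2,
                                    items,
                                    shift_db = 0.5,
                                    transient_db = 0.17,
                                    envelope_sigma = 0.4,
                                    envelope_tau_s = 1,
                                    noise_exponent = 2.5,
                                    pref_gain = 2.5,
                                    nonpref_gain = 1.2,
                                    roi_lag_s = 0.6,
                                    intrusion_dip = TRUE,
                                    prompt_dip = TRUE,
                                    order_effect_db = 0,
                                    seed = 1) {
  set.seed(derive_seed(seed, "ground_truth"))
  groups <- c(rep("V1", n_v1), rep("V2", n_v2),
              rep("intermediate", n_intermediate),
              rep("face_selective", n_face), rep("place_selective", n_place),
              rep("other", n_other),
              rep("roi_frontal", n_frontal), rep("roi_parietal", n_parietal))
  n <- length(groups)
  ids <- sprintf("E%02d", seq_len(n))

  pref <- dplyr::case_when(
    groups == "face_selective" ~ "face",
    groups == "place_selective" ~ "place",
    TRUE ~ NA_character_
  )
  latency <- dplyr::case_when(
    groups %in% c("V1", "V2") ~ 0.10,
    groups == "intermediate" ~ 0.12,
    groups %in% c("face_selective", "place_selective") ~ 0.15,
    TRUE ~ NA_real_
  )

  gains <- lapply(seq_len(n), function(i) {
    g <- switch(
      groups[i],
      V1 = ,
      V2 = ,
      intermediate = runif(nrow(items), 1.8, 2.6),
      face_selective = ifelse(items$category == "face",
                              pref_gain * runif(nrow(items), 0.85, 1.15),
                              nonpref_gain * runif(nrow(items), 0.85, 1.15)),
      place_selective = ifelse(items$category == "place",
                               pref_gain * runif(nrow(items), 0.85, 1.15),
                               nonpref_gain * runif(nrow(items), 0.85, 1.15)),
      rep(1, nrow(items))  # other / ROI electrodes: no viewing response
    )
    setNames(g, items$item_id)
  })

  tt <- tibble(
    electrode_id = ids,
    group = groups,
    preferred_category = pref,
    viewing_gain = gains,
    viewing_latency_s = latency,
    shift_face_db = ifelse(groups == "face_selective", shift_db, 0),
    shift_place_db = ifelse(groups == "place_selective", shift_db, 0),
    transient_db = dplyr::case_when(
      groups %in% c("face_selective", "place_selective") ~ transient_db,
      TRUE ~ 0
    ),
    roi_transient_db = ifelse(groups %in% c("roi_frontal", "roi_parietal"),
                              0.5, 0),
    roi_lag_s = dplyr::case_when(
      groups == "roi_frontal" ~ roi_lag_s,
      groups == "roi_parietal" ~ -1.0,
      TRUE ~ 0
    ),
    burst_db = 0, burst_occupancy = 0, burst_window_s = 3,
    envelope_sigma = envelope_sigma,
    envelope_tau_s = envelope_tau_s,
    carrier_lo = 60, carrier_hi = 160,
    noise_exponent = noise_exponent,
    intrusion_dip = intrusion_dip,
    prompt_dip = prompt_dip,
    order_effect_db = order_effect_db
  )
  validate_ground_truth(tt)
  class(tt) <- c("ground_truth", class(tt))
  tt
}

#' Validate a ground-truth table
#'
#' @param gt Ground-truth tibble.
#' @return The table, invisibly; aborts on violation.
#' @export
validate_ground_truth <- function(gt) {
  if (nrow(gt) == 0) abort("empty ground truth")
  if (anyDuplicated(gt$electrode_id)) abort("electrode ids must be unique")
  if (any(unlist(gt$viewing_gain) < 0)) abort("viewing_gain must be >= 0")
  if (any(gt$burst_occupancy < 0 | gt$burst_occupancy > 1))
    abort("burst occupancy must lie in [0, 1]")
  if (any(gt$envelope_sigma <= 0)) abort("envelope_sigma must be positive")
  invisible(gt)
}

#' Electrode table (labels, MNI coordinates, anatomical group)
#'
#' Assigns plausible MNI coordinates per anatomical group so that downstream
#' stages that key on the electrode table (anatomical labels, ROI capture by
#' MNI distance) are exercised. Coordinates are jittered around canonical
#' sites, with frontal/parietal electrodes placed at the prefrontal and
#' parietal ROI centers used by the ROI analysis.
#'
#' @param ground_truth Ground-truth tibble.
#' @param seed Seed for coordinate jitter.
#' @return Tibble with `name`, `x`, `y`, `z` (MNI mm), `group` (anatomical
#'   label: V1, V2, intermediate, higher_order, frontal, parietal, other).
#' @export
electrode_table <- function(ground_truth, seed = 1) {
  set.seed(derive_seed(seed, "electrode_table"))
  anat <- dplyr::case_when(
    ground_truth$group %in% c("V1", "V2", "intermediate", "other") ~
      ground_truth$group,
    ground_truth$group %in% c("face_selective", "place_selective") ~
      "higher_order",
    ground_truth$group == "roi_frontal" ~ "frontal",
    ground_truth$group == "roi_parietal" ~ "parietal"
  )
  base <- list(
    V1 = c(10, -95, 0), V2 = c(15, -95, 8), intermediate = c(30, -85, -5),
    higher_order = c(38, -55, -18), other = c(55, -20, -10),
    frontal = c(-48, 33, -9), parietal = c(-36, -57, 36)
  )
  xyz <- t(vapply(anat, function(a) base[[a]] + stats::rnorm(3, 0, 3),
                  numeric(3)))
  tibble(
    name = ground_truth$electrode_id,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    group = anat
  )
}
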