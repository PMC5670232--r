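# End-to-end pipeline: simulate (or load) -> preprocess -> HFB -> classify ->
# baseline-shift, dynamics, event-locked and spectral analyses, with a
# machine-readable summary.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis with its default. The config plus
#' the seed fully determine a run.
#'
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param input_dir Optional directory of an existing dataset (from
#'   [write_dataset()]); when `NULL` a synthetic cohort is simulated.
#' @param out_dir Optional output directory; when given, intermediates and
#'   the summary are written there.
#' @param schedule_args,ground_truth_args Overrides passed to
#'   [make_task_schedule()] / [ground_truth_electrodes()].
#' @param line_hz Line frequency (60).
#' @param sd_thresh,grad_thresh,frac_channels,window_ms Artifact-detection
#'   parameters (5, 30, 0.10, 200).
#' @param alpha_responsive,alpha_selective FDR levels for classification
#'   (0.01, 0.01).
#' @param n_perm Cluster-permutation iterations (default 2000 for runtime;
#'   raise to 10000 for final inference).
#' @param analyses Character vector of optional stages to run; any of
#'   `"event_locked"`, `"intrusion"`, `"prompt"`, `"spectra"`, `"dynamics"`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, input_dir = NULL, out_dir = NULL,
                            schedule_args = list(),
                            ground_truth_args = list(),
                            line_hz = 60, sd_thresh = 5, grad_thresh = 30,
                            frac_channels = 0.10, window_ms = 200,
                            alpha_responsive = 0.01, alpha_selective = 0.01,
                            n_perm = 2000,
                            analyses = c("event_locked", "intrusion",
                                         "prompt", "spectra", "dynamics")) {
  structure(
    list(seed = seed, input_dir = input_dir, out_dir = out_dir,
         schedule_args = schedule_args,
         ground_truth_args = ground_truth_args,
         line_hz = line_hz, sd_thresh = sd_thresh, grad_thresh = grad_thresh,
         frac_channels = frac_channels, window_ms = window_ms,
         alpha_responsive = alpha_responsive,
         alpha_selective = alpha_selective,
         n_perm = n_perm, analyses = analyses),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order on a synthetic (or loaded) dataset and
#' returns a results bundle; identical config and seed give identical
#' results. Event-locked stages are skipped with a logged reason when their
#' events are absent.
#'
#' @param config A [pipeline_config()].
#' @return A `recall_pipeline` list: `dataset`, `mask`, `bad_channels`,
#'   `hfb_db`, `profiles`, `shift` (medians, selectivity, stages, excluded
#'   variant, CSI correlation, recall-order table), `dynamics`,
#'   `event_locked`, `intrusion`, `prompt`, `spectra`, `log`, `summary`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  log <- character(0)
  t_start <- Sys.time()
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(sprintf("[%6.1fs] %s",
                    as.numeric(difftime(Sys.time(), t_start, units = "secs")),
                    msg))
  }

  # --- stage 1: data -------------------------------------------------------
  if (is.null(config$input_dir)) {
    sched <- do.call(make_task_schedule,
                     c(list(seed = config$seed), config$schedule_args))
    items <- sched$events %>%
      filter(.data$event_type == "stimulus") %>%
      dplyr::distinct(.data$item_id, .data$category)
    gt <- do.call(ground_truth_electrodes,
                  c(list(items = items, seed = config$seed),
                    config$ground_truth_args))
    ds <- simulate_recording(sched, gt, seed = config$seed)
    events <- sched$events
    note("simulated %d channels, %.0f s", ncol(ds$recording$data),
         sched$duration_s)
  } else {
    loaded <- read_dataset(config$input_dir)
    ds <- list(recording = loaded$recording,
               electrodes = loaded$electrodes,
               ground_truth = loaded$ground_truth)
    events <- loaded$events
    note("loaded dataset from %s", config$input_dir)
  }
  rec <- ds$recording

  # --- stage 2: preprocessing ---------------------------------------------
  rec <- notch_line_noise(rec, line_hz = config$line_hz)
  bad <- detect_bad_channels(rec)
  rec <- common_average_reference(rec, exclude_ids = bad)
  mask <- detect_transient_artifacts(rec, sd_thresh = config$sd_thresh,
                                     grad_thresh_uv_per_ms = config$grad_thresh,
                                     frac_channels = config$frac_channels,
                                     window_ms = config$window_ms)
  mask$bad_channels <- bad
  note("preprocessing: %d bad channels, %.2f%% samples masked",
       length(bad), 100 * mean(mask$excluded))

  # --- stage 3: HFB --------------------------------------------------------
  hfb <- hfb_amplitude(rec, mask = mask)
  runs <- run_intervals(events)
  hfb_ratio <- normalize_to_rest(hfb, runs, mask = mask)
  hfb_db <- to_db(hfb_ratio)
  note("HFB extracted for %d electrodes", ncol(hfb$amplitude))

  # --- stage 4: classification --------------------------------------------
  epochs <- epoch_viewing(hfb, events, mask = mask)
  profiles <- classify_electrodes(epochs, ds$electrodes,
                                  alpha_responsive = config$alpha_responsive,
                                  alpha_selective = config$alpha_selective)
  note("classification: %d responsive, %d face-selective, %d place-selective",
       sum(profiles$responsive),
       sum(profiles$group %in% "face_selective"),
       sum(profiles$group %in% "place_selective"))

  # --- stage 5: baseline shift --------------------------------------------
  med <- median_recall_amplitude(hfb_db, events, mask = mask)
  med_ex <- median_recall_amplitude(hfb_db, events, mask = mask,
                                    exclude_recalls = TRUE)
  sel <- shift_selectivity(med, profiles)
  sel_ex <- shift_selectivity(med_ex, profiles)
  stages <- tryCatch(stage_gain(hfb_db, events, profiles, mask = mask),
                     error = function(e) {
                       note("stage gains skipped: %s", conditionMessage(e))
                       NULL
                     })
  csi_cor <- tryCatch(csi_shift_correlation(profiles, sel),
                      error = function(e) {
                        note("CSI correlation skipped: %s", conditionMessage(e))
                        NULL
                      })
  order_tab <- tryCatch(
    recall_order_analysis(hfb_ratio, events, profiles, mask = mask),
    error = function(e) NULL
  )
  shift <- list(medians = med, selectivity = sel,
                medians_excluded = med_ex, selectivity_excluded = sel_ex,
                stages = stages, csi_correlation = csi_cor,
                recall_order = order_tab)

  results <- list(dataset = ds, events = events, mask = mask,
                  bad_channels = bad, hfb_db = hfb_db, profiles = profiles,
                  shift = shift)

  pref <- preferred_category(profiles)
  has_sel <- sum(!is.na(pref)) >= 5

  # --- stage 6: dynamics ---------------------------------------------------
  if ("dynamics" %in% config$analyses) {
    if (sum(!is.na(pref)) >= 2) {
      gains <- recall_percentile_gains(hfb_db, events, profiles, mask = mask)
      results$dynamics <- if (nrow(gains) >= 10) classify_dynamics(gains)
                          else list(label = "indeterminate",
                                    mean_gain = colMeans(gains))
      results$percentile_gains <- gains
      note("dynamics: %s", results$dynamics$label)
    } else {
      note("dynamics skipped: fewer than 2 selective electrodes")
    }
  }

  # --- stage 7: event-locked ----------------------------------------------
  n_recalls <- sum(events$event_type == "recall")
  if ("event_locked" %in% config$analyses) {
    if (has_sel && n_recalls >= 10) {
      results$event_locked <- recall_onset_contrast(
        hfb_ratio, events, profiles, n_perm = config$n_perm,
        seed = derive_seed(config$seed, "evlock"))
      note("event-locked recall contrast: %d clusters",
           nrow(results$event_locked$test$clusters))
    } else {
      note("event-locked stage skipped: insufficient recalls or electrodes")
    }
  }
  if ("intrusion" %in% config$analyses) {
    res <- tryCatch(
      intrusion_timecourse(hfb_ratio, events, profiles,
                           n_perm = config$n_perm,
                           seed = derive_seed(config$seed, "intr")),
      error = function(e) {
        note("intrusion stage skipped: %s", conditionMessage(e))
        NULL
      })
    results$intrusion <- res
  }
  if ("prompt" %in% config$analyses) {
    res <- tryCatch(
      prompt_timecourse(hfb_ratio, events, profiles,
                        n_perm = config$n_perm,
                        seed = derive_seed(config$seed, "prompt")),
      error = function(e) {
        note("prompt stage skipped: %s", conditionMessage(e))
        NULL
      })
    results$prompt <- res
  }

  # --- stage 8: spectra ----------------------------------------------------
  if ("spectra" %in% config$analyses) {
    results$spectra <- tryCatch({
      sp <- list(
        lfp = lfp_condition_spectra(rec, events, mask = mask),
        hfb = hfb_fluctuation_spectra(hfb_ratio, events, mask = mask,
                                      profiles = profiles)
      )
      note("spectra computed")
      sp
    }, error = function(e) {
      note("spectra skipped: %s", conditionMessage(e))
      NULL
    })
  }

  results$log <- log
  results$summary <- pipeline_summary(results)
  class(results) <- "recall_pipeline"

  if (!is.null(config$out_dir)) write_pipeline(results, config$out_dir)
  results
}

# machine-readable summary of the headline numbers
pipeline_summary <- function(res) {
  sel <- res$shift$selectivity %>% filter(!is.na(.data$selectivity_db))
  sel_ex <- res$shift$selectivity_excluded %>%
    filter(!is.na(.data$selectivity_db))
  out <- list(
    n_electrodes = nrow(res$profiles),
    n_responsive = sum(res$profiles$responsive),
    groups = as.list(table(res$profiles$group)),
    mean_selectivity_db = mean(sel$selectivity_db),
    mean_selectivity_excluded_db = mean(sel_ex$selectivity_db),
    masked_fraction = mean(res$mask$excluded),
    n_bad_channels = length(res$bad_channels)
  )
  if (!is.null(res$shift$csi_correlation)) {
    out$csi_shift_rho <- res$shift$csi_correlation$estimate
    out$csi_shift_p <- res$shift$csi_correlation$p
  }
  if (!is.null(res$dynamics)) {
    out$dynamics_label <- res$dynamics$label
    out$dynamics_kw_p <- res$dynamics$kw_p
  }
  if (!is.null(res$event_locked)) {
    cl <- res$event_locked$test$clusters
    out$recall_clusters <- nrow(cl)
    if (nrow(cl) > 0) out$earliest_cluster_s <- min(cl$start_s)
  }
  out
}

#' Write the pipeline results bundle to disk
#'
#' @param results A `recall_pipeline`.
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_pipeline <- function(results, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- character(0)
  w <- function(x, f) {
    path <- file.path(out_dir, f)
    readr::write_tsv(x, path, progress = FALSE)
    p <<- c(p, path)
  }
  prof <- results$profiles %>%
    mutate(top_items = purrr::map_chr(.data$top_items, function(v)
             paste(v %||% character(0), collapse = ",")),
           bottom_items = purrr::map_chr(.data$bottom_items, function(v)
             paste(v %||% character(0), collapse = ",")))
  w(prof, "profiles.tsv")
  w(results$shift$selectivity, "baseline_shift.tsv")
  w(results$shift$selectivity_excluded, "baseline_shift_excluded.tsv")
  if (!is.null(results$shift$stages))
    w(results$shift$stages, "stage_gains.tsv")
  w(tidy(results$mask), "artifact_mask.tsv")
  jsonlite::write_json(results$summary,
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  writeLines(results$log, file.path(out_dir, "pipeline_log.txt"))
  invisible(c(p, file.path(out_dir, c("summary.json", "pipeline_log.txt"))))
}

#' @export
print.recall_pipeline <- function(x, ...) {
  cat("<recall_pipeline>\n")
  for (l in x$log) cat(" -", l, "\n")
  invisible(x)
}
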