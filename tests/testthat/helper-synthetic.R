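# Shared fixtures: a compact synthetic session built once per test run.
# Reduced task (4 items/category, 60-s rest, 10-s distraction) keeps the
# raw-signal chain fast while preserving every structural feature the
# analyses rely on: two runs, counter-balanced 150-s recall blocks, recall
# events with intrusions, prompts, and the five electrode groups.

small_schedule <- function(seed = 11, ...) {
  make_task_schedule(n_items_per_category = 4, rest_s = 60,
                     distraction_s = 10, seed = seed, ...)
}

small_ground_truth <- function(sched, seed = 11, ...) {
  items <- dplyr::distinct(
    dplyr::filter(sched$events, event_type == "stimulus"),
    item_id, category
  )
  ground_truth_electrodes(n_face = 2, n_place = 2, n_v1 = 1, n_v2 = 1,
                          n_intermediate = 1, n_other = 1,
                          n_frontal = 0, n_parietal = 0,
                          items = items, seed = seed, ...)
}

# memoised full small session: recording -> preprocessed -> hfb states
small_session <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    sched <- small_schedule()
    gt <- small_ground_truth(sched)
    ds <- simulate_recording(sched, gt, seed = 11)
    mask <- detect_transient_artifacts(ds$recording)
    rec <- common_average_reference(notch_line_noise(ds$recording),
                                    detect_bad_channels(ds$recording))
    hfb <- hfb_amplitude(rec, mask = mask)
    runs <- run_intervals(sched$events)
    hfb_ratio <- normalize_to_rest(hfb, runs, mask = mask)
    epochs <- epoch_viewing(hfb, sched$events, mask = mask)
    profiles <- classify_electrodes(epochs, ds$electrodes)
    cache <<- list(sched = sched, gt = gt, ds = ds, mask = mask, rec = rec,
                   hfb = hfb, runs = runs, hfb_ratio = hfb_ratio,
                   hfb_db = to_db(hfb_ratio), epochs = epochs,
                   profiles = profiles)
    cache
  }
})

# multi-electrode envelope-level cohort in a given state
envelope_cohort <- function(n_electrodes, duration_s, seed, sigma = 0.4,
                            state = "db") {
  sapply(seq_len(n_electrodes), function(e)
    simulate_hfb_trace(duration_s, sigma = sigma, seed = seed * 1000 + e,
                       state = state))
}
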