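# Task schedule: the categorized free-recall protocol the analyses assume.
#
# Each run: 200 s eyes-closed rest; 14 pictures (7 famous faces, 7 landmarks)
# shown 4 times each, 1500 ms on / 750 ms inter-stimulus interval, pseudorandom
# cycles with no immediate repeats; 40 s backward-counting distraction; then
# two 150-s free-recall blocks, one per category. The recalled-category order
# is counter-balanced across runs (faces first in run 1, places first in
# run 2). Each run uses a fresh picture set.

#' Build a synthetic free-recall task schedule
#'
#' Generates the full event timeline of the categorized free-recall task:
#' rest, viewing trials, distraction, recall blocks, overt recall events
#' (with extra-category intrusions), and experimenter prompts. Recall onsets
#' are drawn from an inhomogeneous Poisson process whose rate decays
#' exponentially across the block (halving every `recall_halflife_s`
#' seconds), so early recall stages contain more events than later ones.
#'
#' @param n_runs Number of runs (default 2).
#' @param n_items_per_category Pictures per category per run (default 7, so 14
#'   pictures per run).
#' @param n_repetitions Presentations of each picture (default 4).
#' @param rate Sampling rate in Hz used to align all times (default 500).
#' @param rest_s Rest duration at the start of each run, seconds (default 200).
#' @param stim_s,isi_s Stimulus duration and inter-stimulus interval, seconds
#'   (defaults 1.5 and 0.75).
#' @param distraction_s Distraction-task duration, seconds (default 40).
#' @param block_s Duration of each free-recall block, seconds (default 150).
#' @param intrusion_rate Probability that a recall event comes from the
#'   non-designated category; must lie in `[0, 1)` (default 0.115, the rate
#'   observed behaviourally).
#' @param recall_rate0 Initial recall-event rate at block start, events/s
#'   (default 0.08, giving roughly 6--7 events per 150-s block).
#' @param recall_halflife_s Halving time of the recall rate (default 75 s).
#' @param recall_dur_range Range of recall-event durations, seconds, drawn
#'   uniformly (default `c(2, 6)`).
#' @param min_gap_s Minimum gap between consecutive recall onsets (default 1).
#' @param prompts_per_block Experimenter prompts per recall block (default 1);
#'   prompts are placed in quiet gaps late in the block.
#' @param seed Integer seed; identical seeds give identical schedules.
#' @return A `task_schedule` object: a list with `rate`, `n_runs`, `runs`
#'   (per-run interval bookkeeping) and `events`, a tibble in the canonical
#'   events-table layout (`onset`, `duration`, `event_type`, `item_id`,
#'   `category`, `target_category`, `is_intrusion`, `run`). Onsets are in
#'   seconds from recording start and strictly increasing within each event
#'   type and run.
#' @export
#' @examples
#' sched <- make_task_schedule(seed = 1)
#' dplyr::count(sched$events, event_type)
make_task_schedule <- function(n_runs = 2,
                               n_items_per_category = 7,
                               n_repetitions = 4,
                               rate = 500,
                               rest_s = 200,
                               stim_s = 1.5,
                               isi_s = 0.75,
                               distraction_s = 40,
                               block_s = 150,
                               intrusion_rate = 0.115,
                               recall_rate0 = 0.08,
                               recall_halflife_s = 75,
                               recall_dur_range = c(2, 6),
                               min_gap_s = 1,
                               prompts_per_block = 1,
                               seed = 1) {
  if (n_items_per_category < 1) abort("need at least one item per category")
  if (intrusion_rate < 0 || intrusion_rate >= 1)
    abort("intrusion_rate must lie in [0, 1)")
  if (any(c(rest_s, stim_s, isi_s, block_s, rate, recall_rate0,
            recall_halflife_s) <= 0))
    abort("durations and rates must be positive")

  set.seed(derive_seed(seed, "schedule"))
  n_items <- 2L * n_items_per_category
  trial_s <- stim_s + isi_s
  rows <- list()
  runs <- list()
  t0 <- 0

  for (r in seq_len(n_runs)) {
    # each run has its own picture set
    items <- tibble(
      item_id = sprintf("r%d_i%02d", r, seq_len(n_items)),
      category = rep(c("face", "place"), each = n_items_per_category)
    )
    rows[[length(rows) + 1L]] <- tibble(
      onset = t0, duration = rest_s, event_type = "rest",
      item_id = NA_character_, category = NA_character_,
      target_category = NA_character_, is_intrusion = NA, run = r
    )
    rest_iv <- c(t0, t0 + rest_s)
    t <- t0 + rest_s

    # pseudorandom presentation cycles: every cycle shows all items once,
    # shuffled, with no picture repeated back-to-back across cycle joins
    order_idx <- integer(0)
    for (cyc in seq_len(n_repetitions)) {
      repeat {
        perm <- sample.int(n_items)
        if (length(order_idx) == 0 || perm[1] != tail(order_idx, 1)) break
      }
      order_idx <- c(order_idx, perm)
    }
    onsets <- t + (seq_along(order_idx) - 1) * trial_s
    rows[[length(rows) + 1L]] <- tibble(
      onset = onsets, duration = stim_s, event_type = "stimulus",
      item_id = items$item_id[order_idx],
      category = items$category[order_idx],
      target_category = NA_character_, is_intrusion = NA, run = r
    )
    view_iv <- c(t, t + length(order_idx) * trial_s)
    t <- view_iv[2]

    rows[[length(rows) + 1L]] <- tibble(
      onset = t, duration = distraction_s, event_type = "distraction",
      item_id = NA_character_, category = NA_character_,
      target_category = NA_character_, is_intrusion = NA, run = r
    )
    t <- t + distraction_s

    # counter-balanced block order: faces first on odd runs
    block_order <- if (r %% 2 == 1) c("face", "place") else c("place", "face")
    block_ivs <- list()
    for (b in seq_along(block_order)) {
      target <- block_order[b]
      rows[[length(rows) + 1L]] <- tibble(
        onset = t, duration = block_s, event_type = "recall_block",
        item_id = NA_character_, category = NA_character_,
        target_category = target, is_intrusion = NA, run = r
      )
      block_ivs[[target]] <- c(t, t + block_s)

      ev <- draw_recall_events(
        block_start = t, block_s = block_s, items = items, target = target,
        intrusion_rate = intrusion_rate, rate0 = recall_rate0,
        halflife_s = recall_halflife_s, dur_range = recall_dur_range,
        min_gap_s = min_gap_s
      )
      ev$run <- r
      rows[[length(rows) + 1L]] <- ev

      if (prompts_per_block > 0) {
        pr <- draw_prompts(ev, block_start = t, block_s = block_s,
                           target = target, n_prompts = prompts_per_block)
        if (nrow(pr) > 0) {
          pr$run <- r
          rows[[length(rows) + 1L]] <- pr
        }
      }
      t <- t + block_s
    }
    runs[[r]] <- list(run = r, start = t0, end = t,
                      rest = rest_iv, viewing = view_iv,
                      blocks = block_ivs)
    t0 <- t
  }

  events <- dplyr::bind_rows(rows) %>% arrange(.data$onset, .data$event_type)
  out <- structure(
    list(rate = rate, n_runs = n_runs, runs = runs, events = events,
         duration_s = t0),
    class = "task_schedule"
  )
  validate_task_schedule(out)
  out
}

# decaying-rate point process of overt recall events within one block
draw_recall_events <- function(block_start, block_s, items, target,
                               intrusion_rate, rate0, halflife_s,
                               dur_range, min_gap_s) {
  lambda <- function(t) rate0 * 2^(-t / halflife_s)
  # thinning of a homogeneous process at rate0
  t <- 0
  onsets <- numeric(0)
  while (TRUE) {
    t <- t + rexp(1, rate0)
    if (t >= block_s - 1) break
    if (runif(1) <= lambda(t) / rate0 &&
        (length(onsets) == 0 || t - tail(onsets, 1) >= min_gap_s)) {
      onsets <- c(onsets, t)
    }
  }
  n <- length(onsets)
  if (n == 0) {
    return(tibble(onset = numeric(0), duration = numeric(0),
                  event_type = character(0), item_id = character(0),
                  category = character(0), target_category = character(0),
                  is_intrusion = logical(0)))
  }
  durs <- runif(n, dur_range[1], dur_range[2])
  durs <- pmin(durs, block_s - onsets - 0.5)  # stay inside the block
  intr <- runif(n) < intrusion_rate
  cat_of <- ifelse(intr, setdiff(c("face", "place"), target), target)
  item <- vapply(cat_of, function(cc) {
    sample(items$item_id[items$category == cc], 1)
  }, character(1))
  tibble(
    onset = block_start + onsets, duration = durs, event_type = "recall",
    item_id = unname(item), category = unname(cat_of),
    target_category = target, is_intrusion = intr
  )
}

# prompts go into the longest recall-free gaps of the block
draw_prompts <- function(recalls, block_start, block_s, target, n_prompts) {
  bounds <- sort(c(block_start,
                   recalls$onset, recalls$onset + recalls$duration,
                   block_start + block_s))
  gaps <- tibble(start = head(bounds, -1), end = tail(bounds, -1)) %>%
    mutate(len = .data$end - .data$start) %>%
    filter(.data$len > 12) %>%   # need room: 2-s prompt + 7-s gap to next recall
    arrange(dplyr::desc(.data$len))
  n <- min(n_prompts, nrow(gaps))
  if (n == 0) {
    return(tibble(onset = numeric(0), duration = numeric(0),
                  event_type = character(0), item_id = character(0),
                  category = character(0), target_category = character(0),
                  is_intrusion = logical(0)))
  }
  g <- gaps[seq_len(n), ]
  tibble(
    onset = g$start + 1, duration = 2, event_type = "prompt",
    item_id = NA_character_, category = NA_character_,
    target_category = target, is_intrusion = NA
  )
}

#' Validate a task schedule
#'
#' Checks the structural invariants of the task timeline: strictly increasing
#' onsets per event type and run, recall events and prompts contained in
#' exactly one recall block of their run, intrusion flags consistent with the
#' block's target category, and the expected viewing-trial count and spacing.
#'
#' @param schedule A `task_schedule`.
#' @return The schedule, invisibly; aborts on violation.
#' @export
validate_task_schedule <- function(schedule) {
  ev <- schedule$events
  by_type <- split(ev, interaction(ev$event_type, ev$run, drop = TRUE))
  for (g in by_type) {
    if (is.unsorted(g$onset, strictly = TRUE))
      abort("onsets must be strictly increasing within each event list")
  }
  blocks <- filter(ev, .data$event_type == "recall_block")
  for (kind in c("recall", "prompt")) {
    sub <- filter(ev, .data$event_type == kind)
    if (nrow(sub) == 0) next
    hits <- vapply(seq_len(nrow(sub)), function(i) {
      sum(sub$onset[i] >= blocks$onset &
            sub$onset[i] + sub$duration[i] <= blocks$onset + blocks$duration &
            sub$run[i] == blocks$run)
    }, integer(1))
    if (any(hits != 1L))
      abort(sprintf("every %s must lie inside exactly one recall block", kind))
  }
  rec <- filter(ev, .data$event_type == "recall")
  if (nrow(rec) > 0 &&
      !all(rec$is_intrusion == (rec$category != rec$target_category)))
    abort("is_intrusion must mark exactly the extra-category recalls")
  stim <- filter(ev, .data$event_type == "stimulus")
  for (r in unique(stim$run)) {
    s <- filter(stim, .data$run == r)
    tab <- table(s$item_id)
    reps <- unique(as.integer(tab))
    if (length(reps) != 1L)
      abort("each item must be presented the same number of times per run")
    d <- diff(s$onset)
    if (max(abs(d - d[1])) > 1e-9)
      abort("viewing trials must be evenly spaced")
  }
  invisible(schedule)
}

#' @export
print.task_schedule <- function(x, ...) {
  cat("<task_schedule>", x$n_runs, "runs,",
      nrow(filter(x$events, .data$event_type == "stimulus")), "viewing trials,",
      nrow(filter(x$events, .data$event_type == "recall")), "recall events,",
      sprintf("%.0f s total\n", x$duration_s))
  invisible(x)
}

# interval accessors used by downstream stages ------------------------------

#' Recall-block intervals of a schedule or events table
#'
#' @param events Events tibble (or a `task_schedule`).
#' @return Tibble with `run`, `target_category`, `start`, `end` (seconds).
#' @export
recall_blocks <- function(events) {
  if (inherits(events, "task_schedule")) events <- events$events
  events %>%
    filter(.data$event_type == "recall_block") %>%
    mutate(start = .data$onset, end = .data$onset + .data$duration) %>%
    select("run", "target_category", "start", "end")
}

#' Run intervals (start/end and rest period) from an events table
#'
#' Rest rows delimit runs: each run spans from its rest onset to the start of
#' the next run's rest (or the end of the last event).
#'
#' @param events Events tibble (or a `task_schedule`).
#' @return Tibble with `run`, `start`, `end`, `rest_start`, `rest_end`.
#' @export
run_intervals <- function(events) {
  if (inherits(events, "task_schedule")) events <- events$events
  rests <- events %>%
    filter(.data$event_type == "rest") %>% arrange(.data$onset)
  ends <- c(rests$onset[-1], max(events$onset + events$duration))
  tibble(run = rests$run, start = rests$onset, end = ends,
         rest_start = rests$onset, rest_end = rests$onset + rests$duration)
}
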