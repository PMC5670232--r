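# Plain-text dataset persistence: TSV recording matrix with a JSON sidecar,
# BIDS-like events and electrodes TSVs, and the ground-truth JSON.

#' Write a synthetic dataset to a directory
#'
#' Emits `recording.tsv` (samples x channels, microvolts, `digits` decimal
#' places), `recording.json` (rate, channel ids, units), `events.tsv`,
#' `electrodes.tsv` and `ground_truth.json`. Reading back with
#' [read_dataset()] round-trips the events table exactly and the signal to
#' within the quantization implied by `digits`.
#'
#' @param dataset A `synthetic_dataset` from [simulate_recording()].
#' @param out_dir Output directory (created if missing).
#' @param digits Decimal places kept in the recording TSV (default 3, i.e.
#'   1 nV quantization step ~ 5e-4 microvolts max error).
#' @return Named character vector of the file paths written.
#' @export
write_dataset <- function(dataset, out_dir, digits = 3) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort("cannot create output directory")
  }
  rec <- dataset$recording
  paths <- c(
    recording = file.path(out_dir, "recording.tsv"),
    sidecar = file.path(out_dir, "recording.json"),
    events = file.path(out_dir, "events.tsv"),
    electrodes = file.path(out_dir, "electrodes.tsv"),
    ground_truth = file.path(out_dir, "ground_truth.json")
  )
  mat <- round(rec$data, digits)
  readr::write_tsv(as_tibble(mat), paths[["recording"]], progress = FALSE)
  jsonlite::write_json(
    list(rate_hz = rec$rate, channel_ids = rec$channel_ids,
         units = "uV", t0_s = rec$t0, digits = digits),
    paths[["sidecar"]], auto_unbox = TRUE, digits = NA
  )
  readr::write_tsv(dataset$schedule$events, paths[["events"]],
                   progress = FALSE)
  readr::write_tsv(dataset$electrodes, paths[["electrodes"]],
                   progress = FALSE)
  gt <- dataset$ground_truth
  gt_json <- lapply(seq_len(nrow(gt)), function(i) {
    row <- as.list(gt[i, ])
    row$viewing_gain <- as.list(gt$viewing_gain[[i]])
    row
  })
  jsonlite::write_json(gt_json, paths[["ground_truth"]],
                       auto_unbox = TRUE, digits = NA)
  paths
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing the files.
#' @return A list with `recording`, `events`, `electrodes`, `ground_truth`
#'   (ground truth present only when its JSON exists).
#' @export
read_dataset <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "recording.json"),
                              simplifyVector = TRUE)
  mat <- as.matrix(readr::read_tsv(file.path(dir, "recording.tsv"),
                                   show_col_types = FALSE, progress = FALSE))
  rec <- new_recording(mat, side$rate_hz, side$channel_ids,
                       side$t0_s %||% 0)
  events <- readr::read_tsv(
    file.path(dir, "events.tsv"), progress = FALSE,
    col_types = readr::cols(
      onset = "d", duration = "d", event_type = "c", item_id = "c",
      category = "c", target_category = "c", is_intrusion = "l", run = "i"
    )
  )
  electrodes <- readr::read_tsv(file.path(dir, "electrodes.tsv"),
                                show_col_types = FALSE, progress = FALSE)
  out <- list(recording = rec, events = events, electrodes = electrodes)
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) {
    raw <- jsonlite::read_json(gt_path, simplifyVector = FALSE)
    num_cols <- c("viewing_latency_s", "shift_face_db", "shift_place_db",
                  "transient_db", "roi_transient_db", "roi_lag_s",
                  "burst_db", "burst_occupancy", "burst_window_s",
                  "envelope_sigma", "envelope_tau_s", "carrier_lo",
                  "carrier_hi", "noise_exponent", "order_effect_db")
    lgl_cols <- c("intrusion_dip", "prompt_dip")
    gt <- purrr::map_dfr(raw, function(row) {
      vg <- unlist(row$viewing_gain)
      row$viewing_gain <- NULL
      row <- purrr::imap(row, function(v, nm) {
        if (is.null(v) || (is.character(v) && v == "NA")) v <- NA
        if (nm %in% num_cols) as.numeric(v)
        else if (nm %in% lgl_cols) as.logical(v)
        else as.character(v)
      })
      as_tibble(row) %>% mutate(viewing_gain = list(vg))
    })
    validate_ground_truth(gt)
    out$ground_truth <- gt
  }
  out
}
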