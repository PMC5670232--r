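# ggplot2 visualizations for the main result types.

#' @importFrom ggplot2 aes autoplot ggplot geom_line geom_col geom_rect
#'   geom_hline geom_point geom_histogram labs theme_minimal facet_wrap
NULL

#' Plot a percentile-gain profile
#'
#' @param object A `percentile_gain` tibble.
#' @param ... Unused.
#' @return A ggplot: per-decile amplitude gain.
#' @export
autoplot.percentile_gain <- function(object, ...) {
  ggplot(object, aes(x = factor(.data$bin), y = .data$gain_db)) +
    geom_col(fill = "grey35") +
    geom_hline(yintercept = 0, linetype = 2) +
    labs(x = "amplitude percentile bin (1 = lowest decile)",
         y = "gain (dB)") +
    theme_minimal()
}

#' Plot a cluster-corrected contrast time course
#'
#' @param object A `cluster_test`.
#' @param alpha Corrected threshold used for shading (default 0.05).
#' @param ... Unused.
#' @return A ggplot: t trace with significant clusters shaded.
#' @export
autoplot.cluster_test <- function(object, alpha = 0.05, ...) {
  df <- tibble(time_s = object$times, t = object$t)
  cl <- object$clusters %>% filter(.data$p_corrected < alpha)
  p <- ggplot(df, aes(x = .data$time_s, y = .data$t)) +
    geom_hline(yintercept = 0, colour = "grey70") +
    geom_line() +
    labs(x = "time (s)", y = "t value") +
    theme_minimal()
  if (nrow(cl) > 0) {
    p <- p + geom_rect(data = cl,
                       aes(xmin = .data$start_s, xmax = .data$end_s),
                       ymin = -Inf, ymax = Inf, alpha = 0.2,
                       fill = "gold", inherit.aes = FALSE)
  }
  p
}

#' Plot event-triggered mean responses
#'
#' @param object An `event_response`.
#' @param ... Unused.
#' @return A ggplot: per-electrode traces plus the grand average.
#' @export
autoplot.event_response <- function(object, ...) {
  df <- tidy(object)
  grand <- df %>% group_by(.data$time_s) %>%
    summarise(db = mean(.data$db), .groups = "drop")
  ggplot(df, aes(x = .data$time_s, y = .data$db,
                 group = .data$electrode_id)) +
    geom_line(alpha = 0.25) +
    geom_line(data = grand, aes(group = NULL), linewidth = 1,
              colour = "firebrick") +
    geom_hline(yintercept = 0, linetype = 2) +
    labs(x = "time from event onset (s)", y = "HFB amplitude (dB)") +
    theme_minimal()
}

#' Plot condition spectra gains
#'
#' @param object A `condition_spectra`.
#' @param ... Unused.
#' @return A ggplot: mean gain vs reference per condition, significant
#'   frequencies marked.
#' @export
autoplot.condition_spectra <- function(object, ...) {
  g <- object$gain
  ggplot(g, aes(x = .data$freq_hz, y = .data$mean_gain_db)) +
    geom_hline(yintercept = 0, colour = "grey70") +
    geom_line() +
    geom_point(data = filter(g, .data$significant), colour = "gold") +
    facet_wrap(~condition) +
    labs(x = "frequency (Hz)", y = "gain vs reference (dB)") +
    theme_minimal()
}

#' Histogram of baseline-shift selectivity across electrodes
#'
#' @param selectivity Output of [shift_selectivity()].
#' @param binwidth Histogram bin width in dB (default 0.05).
#' @return A ggplot.
#' @export
plot_shift_selectivity <- function(selectivity, binwidth = 0.05) {
  df <- selectivity %>% filter(!is.na(.data$selectivity_db))
  ggplot(df, aes(x = .data$selectivity_db)) +
    geom_histogram(binwidth = binwidth, fill = "grey35", colour = "white") +
    geom_hline(yintercept = 0) +
    labs(x = "preferred - non-preferred median amplitude (dB)",
         y = "electrodes") +
    theme_minimal()
}
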