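#' @import ggplot2
NULL

#' Plot the analog trajectories of one trial
#'
#' Step plot of both response keys' analog values over the trial, with the
#' full-press threshold and the starts-pressed guard window marked. Partial
#' errors are visible as sub-threshold excursions of the incorrect key.
#'
#' @param events Change-event tibble.
#' @param participant,trial Which trial to draw.
#' @param full_press_threshold,onset_guard_ms Reference lines.
#' @return A ggplot object.
#' @export
plot_trial_trajectories <- function(events, participant, trial,
                                    full_press_threshold = 0.95,
                                    onset_guard_ms = 5) {
  d <- events |>
    dplyr::filter(.data$participant_id == participant,
                  .data$trial_index == trial)
  if (nrow(d) == 0) abort("no events for the requested trial.")
  d <- d |>
    group_by(.data$key_id) |>
    group_modify(~ tibble::add_row(.x, time_ms = 0, value = 0, .before = 1)) |>
    ungroup()
  ggplot(d, aes(x = .data$time_ms, y = .data$value, colour = .data$key_id)) +
    geom_step(linewidth = 0.6) +
    geom_hline(yintercept = full_press_threshold, linetype = "dashed") +
    geom_vline(xintercept = onset_guard_ms, linetype = "dotted") +
    labs(x = "time from stimulus onset (ms)", y = "analog key value",
         colour = "key",
         title = sprintf("%s, trial %s", participant, trial)) +
    ylim(0, 1) +
    theme_minimal()
}

#' Participant-level means by item type
#'
#' Companion figure to the standard group analyses: per item type, the
#' distribution over participants of mean RT and of the partial-press
#' proportion.
#'
#' @param summaries Summary tibble from [summarize_participants()].
#' @return A ggplot object (faceted over the two dependent variables).
#' @export
plot_participant_summaries <- function(summaries) {
  assert_columns(summaries, c("participant_id", "item_type", "mean_rt_ms",
                              "prop_partial"), "`summaries`")
  long <- summaries |>
    tidyr::pivot_longer(c("mean_rt_ms", "prop_partial"),
                        names_to = "measure", values_to = "value") |>
    mutate(measure = dplyr::recode(.data$measure,
                                   mean_rt_ms = "mean RT (ms)",
                                   prop_partial = "partial-press proportion"))
  ggplot(long, aes(x = .data$item_type, y = .data$value)) +
    geom_boxplot(outlier.shape = NA, width = 0.5) +
    geom_jitter(width = 0.12, alpha = 0.5, size = 1) +
    facet_wrap(~measure, scales = "free_y") +
    labs(x = "item type", y = NULL) +
    theme_minimal()
}

#' @rdname exgauss_mle
#' @param object An `exgauss_fit`.
#' @param ... Unused.
#' @method autoplot exgauss_fit
#' @export
autoplot.exgauss_fit <- function(object, ...) {
  est <- object$estimates$estimate
  d <- tibble(rt = object$data)
  grid <- tibble(rt = seq(min(d$rt), max(d$rt), length.out = 300))
  if (object$converged) {
    grid$density <- dexgauss(grid$rt, est[1], est[2], est[3])
  }
  p <- ggplot(d, aes(x = .data$rt)) +
    geom_histogram(aes(y = after_stat(.data$density)), bins = 40,
                   fill = "grey80", colour = "grey50") +
    labs(x = "RT (ms)", y = "density",
         title = "ex-Gaussian maximum-likelihood fit") +
    theme_minimal()
  if (object$converged) {
    p <- p + geom_line(data = grid, aes(y = .data$density), linewidth = 0.8)
  }
  p
}

#' @rdname jzs_mixed_anova_bf
#' @param object A `bf_result`.
#' @param ... Unused.
#' @method autoplot bf_result
#' @export
autoplot.bf_result <- function(object, ...) {
  d <- tidy(object) |>
    mutate(comparison = paste(.data$model_a, "vs", .data$model_b))
  ggplot(d, aes(x = .data$comparison, y = .data$log_bf)) +
    geom_col(width = 0.5, fill = "grey40") +
    geom_hline(yintercept = 0) +
    geom_errorbar(aes(ymin = .data$log_bf - 2 * .data$error,
                      ymax = .data$log_bf + 2 * .data$error), width = 0.15) +
    labs(x = NULL, y = "log Bayes factor") +
    theme_minimal()
}
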