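#' Extract the overt response from one trial's trajectories
#'
#' The response time is the earliest time at or before the deadline at which
#' either response key's analog value exceeds the full-press threshold
#' (strictly greater than 0.95 by default); the responding key is the one
#' that crosses first. If neither key crosses by the deadline the trial is a
#' no-response trial. Should both keys first cross at the same millisecond,
#' the key with the larger analog value at that sample is taken as pressed;
#' an exact tie is deterministic but unresolvable and the trial is marked an
#' error.
#'
#' @param trial A one-row trial (list or tibble row) with `correct_key`,
#'   `deadline_ms` and `trajectories`, a named list of two
#'   [key_trajectory()] objects (as built by [as_trajectories()]).
#' @param full_press_threshold Analog value above which a key counts as
#'   fully pressed; must lie in (0, 1).
#' @return A one-row tibble: `rt_ms`, `pressed_key` (`NA` for no-response),
#'   `is_error`, `exclusion_reason` (`"no_response"` or `"none"`; upstream
#'   reasons are assigned by [apply_exclusions()]).
#' @export
extract_response <- function(trial, full_press_threshold = 0.95) {
  assert_scalar_number(full_press_threshold, "full_press_threshold")
  if (full_press_threshold <= 0 || full_press_threshold >= 1) {
    abort("`full_press_threshold` must lie strictly within (0, 1).")
  }
  trajs <- trial_field(trial, "trajectories")
  correct_key <- trial_field(trial, "correct_key")
  deadline <- trial_field(trial, "deadline_ms")
  if (length(trajs) != 2L) abort("a trial must carry exactly two response-key trajectories.")

  crossing <- vapply(trajs, function(tr) {
    hit <- tr$time_ms <= deadline & tr$value > full_press_threshold
    if (any(hit)) min(tr$time_ms[hit]) else Inf
  }, numeric(1))
  rt <- min(crossing)
  if (!is.finite(rt)) {
    return(tibble(rt_ms = NA_real_, pressed_key = NA_character_,
                  is_error = FALSE, exclusion_reason = "no_response"))
  }
  winners <- names(crossing)[crossing == rt]
  tie_error <- FALSE
  if (length(winners) > 1) {
    vals <- vapply(trajs[winners], function(tr) value_at(tr, rt), numeric(1))
    if (vals[1] == vals[2]) {
      tie_error <- TRUE
      winners <- sort(winners)[1]
    } else {
      winners <- winners[which.max(vals)]
    }
  }
  tibble(
    rt_ms = rt,
    pressed_key = winners,
    is_error = tie_error || winners != correct_key,
    exclusion_reason = "none"
  )
}

trial_field <- function(trial, field) {
  x <- trial[[field]]
  if (is.list(x) && !inherits(x, "key_trajectory") && field == "trajectories" &&
      length(x) == 1L && is.list(x[[1]]) && !inherits(x[[1]], "key_trajectory")) {
    x <- x[[1]] # list-column row
  }
  x
}

#' Detect a partial error on a responded trial
#'
#' A partial error (partial button press) is recorded when both response
#' keys show analog values greater than 0 at some time strictly before the
#' response threshold is crossed. The two keys need not be depressed
#' simultaneously: since the responding key is necessarily nonzero on its
#' way to the threshold, the criterion is in practice that the *other* key
#' moved before the response.
#'
#' @inheritParams extract_response
#' @param outcome The one-row outcome from [extract_response()]; must have a
#'   response (`rt_ms` present).
#' @return `TRUE` if both keys were nonzero before `rt_ms`, else `FALSE`.
#' @export
detect_partial_error <- function(trial, outcome) {
  rt <- outcome$rt_ms
  if (is.na(rt)) {
    abort("detect_partial_error() requires a responded trial (rt_ms present).")
  }
  trajs <- trial_field(trial, "trajectories")
  moved <- vapply(trajs, function(tr) {
    any(tr$time_ms < rt & tr$value > 0)
  }, logical(1))
  all(moved)
}

#' Flag trials that start with a partially pressed key
#'
#' Trials with an analog value greater than 0 on either response key within
#' the first `window_ms` (default 5 ms) of the trial are treated as
#' accidental carry-over presses and excluded.
#'
#' @inheritParams extract_response
#' @param window_ms Guard window length in ms.
#' @return `TRUE` if any response key is nonzero anywhere in
#'   \[0, `window_ms`\].
#' @export
flag_starts_pressed <- function(trial, window_ms = 5) {
  assert_scalar_number(window_ms, "window_ms", lower = 0)
  trajs <- trial_field(trial, "trajectories")
  any(vapply(trajs, function(tr) {
    any(tr$time_ms <= window_ms & tr$value > 0)
  }, logical(1)))
}

#' Exclusion policy for a task
#'
#' Mirrors the standard trial-exclusion rules: responses faster than
#' 200 ms or slower than the task deadline (1500 ms CIT, 2500 ms Sternberg)
#' are dropped, as are error trials and trials starting with a pressed key;
#' for the CIT's probe-vs-irrelevant analyses target trials are excluded as
#' well. Bounds are strict (`< min`, `> max`).
#'
#' @param task `"CIT"` or `"STERNBERG"`.
#' @param rt_min_ms,rt_max_ms RT bounds in ms.
#' @param exclude_targets Drop target trials (`TRUE` for the CIT).
#' @param exclude_errors Drop error trials.
#' @return A list of class `exclusion_policy`.
#' @export
exclusion_policy <- function(task = c("CIT", "STERNBERG"),
                             rt_min_ms = 200,
                             rt_max_ms = if (task[1] == "CIT") 1500 else 2500,
                             exclude_targets = task[1] == "CIT",
                             exclude_errors = TRUE) {
  task <- match.arg(task)
  if (rt_min_ms <= 0 || rt_max_ms <= 0 || rt_max_ms <= rt_min_ms) {
    abort("exclusion policy RT bounds must be positive with max > min.")
  }
  structure(list(task = task, rt_min_ms = rt_min_ms, rt_max_ms = rt_max_ms,
                 exclude_targets = exclude_targets,
                 exclude_errors = exclude_errors),
            class = "exclusion_policy")
}

exclusion_reasons <- c("starts_pressed", "no_response", "too_fast",
                       "too_slow", "error", "target_trial", "none")

#' Assign exclusion reasons to processed trials
#'
#' Each trial receives exactly one `exclusion_reason`, assigned in fixed
#' priority order: `starts_pressed`, `no_response`, `too_fast`, `too_slow`,
#' `error`, `target_trial`, `none`. Retained trials are those with reason
#' `"none"`.
#'
#' @param outcomes Outcome tibble from [process_trials()] (needs `rt_ms`,
#'   `is_error`, `starts_pressed`, `item_type`).
#' @param policy An [exclusion_policy()].
#' @return The outcomes with `exclusion_reason` and `excluded` columns set;
#'   attribute `exclusion_counts` holds the per-reason tally and
#'   `exclusion_fraction` the overall excluded proportion.
#' @export
apply_exclusions <- function(outcomes, policy) {
  stopifnot(inherits(policy, "exclusion_policy"))
  assert_columns(outcomes, c("rt_ms", "is_error", "starts_pressed", "item_type"),
                 "`outcomes`")
  reason <- dplyr::case_when(
    outcomes$starts_pressed ~ "starts_pressed",
    is.na(outcomes$rt_ms) ~ "no_response",
    outcomes$rt_ms < policy$rt_min_ms ~ "too_fast",
    outcomes$rt_ms > policy$rt_max_ms ~ "too_slow",
    policy$exclude_errors & outcomes$is_error ~ "error",
    policy$exclude_targets & outcomes$item_type == "target" ~ "target_trial",
    TRUE ~ "none"
  )
  outcomes$exclusion_reason <- factor(reason, levels = exclusion_reasons)
  outcomes$excluded <- reason != "none"
  counts <- table(outcomes$exclusion_reason)
  attr(outcomes, "exclusion_counts") <- counts
  attr(outcomes, "exclusion_fraction") <- mean(outcomes$excluded)
  outcomes
}

#' Process an event log into trial outcomes
#'
#' Vectorised end-to-end pass over a change-event table: per trial it
#' extracts the response (first threshold crossing within the deadline),
#' detects partial errors on responded trials, flags starts-pressed trials,
#' and applies the task's exclusion policy. Equivalent to running
#' [extract_response()], [detect_partial_error()] and
#' [flag_starts_pressed()] trial by trial on reconstructed trajectories.
#'
#' @param events Change-event tibble ([read_event_log()] format).
#' @param trials Trial metadata tibble (one row per trial).
#' @param keys Character vector of the two response keys.
#' @param full_press_threshold Full-press threshold (analog value, strict).
#' @param onset_guard_ms Starts-pressed guard window in ms.
#' @param policy Exclusion policy; defaults to the task's standard policy
#'   (taken from the first trial's `task`).
#' @return A tibble with one row per trial: metadata plus `rt_ms`,
#'   `pressed_key`, `is_error`, `is_partial_error`, `starts_pressed`,
#'   `exclusion_reason`, `excluded`.
#' @export
process_trials <- function(events, trials, keys = c("e", "i"),
                           full_press_threshold = 0.95,
                           onset_guard_ms = 5,
                           policy = NULL) {
  stopifnot(length(keys) == 2L)
  if (full_press_threshold <= 0 || full_press_threshold >= 1) {
    abort("`full_press_threshold` must lie strictly within (0, 1).")
  }
  assert_columns(trials, c("participant_id", "trial_index", "item_type",
                           "correct_key", "deadline_ms"), "`trials`")
  assert_columns(events, event_log_cols, "`events`")
  if (is.null(policy)) {
    task <- if ("task" %in% names(trials) && nrow(trials) > 0) {
      trials$task[1]
    } else {
      "CIT"
    }
    policy <- exclusion_policy(task)
  }

  ev <- events |>
    dplyr::semi_join(trials, by = c("participant_id", "trial_index")) |>
    dplyr::filter(.data$key_id %in% keys) |>
    dplyr::left_join(trials |> select("participant_id", "trial_index",
                                      "deadline_ms"),
                     by = c("participant_id", "trial_index"))

  # first threshold crossing per trial x key, within the deadline (filter
  # first so the grouped step only touches supra-threshold events)
  crossing <- ev |>
    dplyr::filter(.data$value > full_press_threshold,
                  .data$time_ms <= .data$deadline_ms) |>
    group_by(.data$participant_id, .data$trial_index, .data$key_id) |>
    dplyr::slice_min(.data$time_ms, n = 1, with_ties = FALSE) |>
    ungroup()

  resp <- crossing |>
    group_by(.data$participant_id, .data$trial_index) |>
    mutate(rt_ms = suppressWarnings(min(.data$time_ms))) |>
    dplyr::filter(.data$time_ms == .data$rt_ms) |>
    arrange(dplyr::desc(.data$value), .data$key_id, .by_group = TRUE) |>
    summarise(
      rt_ms = .data$rt_ms[1],
      # simultaneous crossing: larger analog value wins; exact tie is an
      # unresolvable error (deterministically assigned the sorted-first key)
      tie_error = dplyr::n() > 1 && .data$value[1] == .data$value[2],
      pressed_key = if (tie_error) NA_character_ else .data$key_id[1],
      .groups = "drop"
    )

  early <- ev |>
    dplyr::filter(.data$time_ms <= onset_guard_ms, .data$value > 0) |>
    dplyr::distinct(.data$participant_id, .data$trial_index) |>
    mutate(starts_pressed = TRUE)
  resp <- resp |>
    dplyr::full_join(early, by = c("participant_id", "trial_index")) |>
    mutate(starts_pressed = dplyr::coalesce(.data$starts_pressed, FALSE))

  # keys nonzero strictly before the crossing (computed on the event table)
  moved <- ev |>
    dplyr::left_join(resp |> select("participant_id", "trial_index", "rt_ms"),
                     by = c("participant_id", "trial_index")) |>
    dplyr::filter(!is.na(.data$rt_ms), .data$time_ms < .data$rt_ms,
                  .data$value > 0) |>
    dplyr::distinct(.data$participant_id, .data$trial_index, .data$key_id) |>
    count(.data$participant_id, .data$trial_index, name = "keys_moved")

  out <- trials |>
    dplyr::left_join(resp, by = c("participant_id", "trial_index")) |>
    dplyr::left_join(moved, by = c("participant_id", "trial_index")) |>
    mutate(
      starts_pressed = dplyr::coalesce(.data$starts_pressed, FALSE),
      tie_error = dplyr::coalesce(.data$tie_error, FALSE),
      pressed_key = ifelse(.data$tie_error,
                           pmin(keys[1], keys[2]), .data$pressed_key),
      is_error = !is.na(.data$rt_ms) &
        (.data$tie_error | .data$pressed_key != .data$correct_key),
      is_partial_error = !is.na(.data$rt_ms) & !.data$starts_pressed &
        dplyr::coalesce(.data$keys_moved, 0L) == 2L
    ) |>
    select(-"keys_moved", -"tie_error")
  apply_exclusions(out, policy)
}

#' Summarise retained trials per participant and item type
#'
#' Computes, for each participant x item type cell, the number of retained
#' (valid) trials, mean and SD of RT, the proportion of retained trials with
#' a partial error, and the error proportion among response-valid trials
#' (responded, within RT bounds, not starts-pressed) -- the quantity
#' performance screening uses. Cells with no retained trials are reported
#' with `NA` means, never 0.
#'
#' @param outcomes Outcome tibble from [process_trials()] /
#'   [apply_exclusions()].
#' @return A tibble keyed by `participant_id` (and `condition` if present)
#'   x `item_type` with `n_valid`, `mean_rt_ms`, `sd_rt_ms`, `prop_partial`,
#'   `prop_error`.
#' @export
summarize_participants <- function(outcomes) {
  assert_columns(outcomes, c("participant_id", "item_type", "rt_ms",
                             "is_error", "is_partial_error",
                             "exclusion_reason"), "`outcomes`")
  keys <- intersect(c("participant_id", "condition", "item_type"),
                    names(outcomes))
  outcomes |>
    group_by(dplyr::across(dplyr::all_of(keys))) |>
    summarise(
      n_valid = sum(.data$exclusion_reason == "none"),
      mean_rt_ms = if (n_valid > 0) {
        mean(.data$rt_ms[.data$exclusion_reason == "none"])
      } else {
        NA_real_
      },
      sd_rt_ms = if (n_valid > 1) {
        stats::sd(.data$rt_ms[.data$exclusion_reason == "none"])
      } else {
        NA_real_
      },
      prop_partial = if (n_valid > 0) {
        mean(.data$is_partial_error[.data$exclusion_reason == "none"])
      } else {
        NA_real_
      },
      prop_error = {
        ok <- .data$exclusion_reason %in% c("none", "error", "target_trial")
        if (any(ok)) mean(.data$is_error[ok]) else NA_real_
      },
      .groups = "drop"
    )
}

#' @rdname summarize_participants
#' @param retained Outcomes of a single participant.
#' @export
summarize_participant <- function(retained) {
  if (length(unique(retained$participant_id)) > 1) {
    abort("summarize_participant() expects trials of a single participant.")
  }
  summarize_participants(retained)
}

#' Participant-level performance filter
#'
#' Drops a participant whose accuracy is below the threshold (strictly less
#' than 60% by default) in at least one item category; accuracy exactly at
#' the threshold keeps the participant.
#'
#' @param accuracies Named numeric vector or data frame
#'   (`item_type`/`category`, `accuracy`) of per-category accuracies in
#'   \[0, 1\].
#' @param threshold Minimum acceptable accuracy.
#' @param required_categories Categories that must be present; missing ones
#'   raise a validation error. Defaults to the supplied names.
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
participant_performance_filter <- function(accuracies, threshold = 0.60,
                                           required_categories = NULL) {
  if (is.data.frame(accuracies)) {
    nm <- intersect(c("item_type", "category"), names(accuracies))[1]
    acc <- stats::setNames(accuracies$accuracy, accuracies[[nm]])
  } else {
    acc <- accuracies
  }
  if (!is.null(required_categories)) {
    missing <- setdiff(required_categories, names(acc))
    if (length(missing) > 0) {
      abort(sprintf("missing accuracy for category: %s.",
                    paste(missing, collapse = ", ")))
    }
    acc <- acc[required_categories]
  }
  if (any(is.na(acc) | acc < 0 | acc > 1)) {
    abort("accuracies must lie in [0, 1] with no missing values.")
  }
  all(acc >= threshold)
}
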