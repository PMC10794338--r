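#' Analog key trajectories from change-only event logs
#'
#' Analog keyboards report each key's depression as a value in \[0, 1\] at
#' 1000 Hz, but to keep files small only *changes* are logged: one event per
#' (timestamp, key, new value). A [key_trajectory()] reconstructs the
#' continuous signal by zero-order hold: the analog value is 0 before the
#' first event and holds each event's value until the next event
#' (right-continuous step interpolation).
#'
#' @param time_ms Numeric vector of event times in milliseconds from stimulus
#'   onset; must be non-negative and strictly increasing.
#' @param value Numeric vector of analog values in \[0, 1\], one per event.
#'   Consecutive events must differ (change-only recording).
#' @param key_id Single string naming the key (e.g. `"e"`).
#' @param duration_ms Trial duration in ms; events must not exceed it.
#' @return An object of class `key_trajectory`: a list with fields `key_id`,
#'   `time_ms`, `value`, `duration_ms`.
#' @examples
#' tr <- key_trajectory(c(100, 140), c(0.4, 1), "e", 1500)
#' value_at(tr, c(50, 100, 120, 1500))
#' @seealso [value_at()], [densify()], [sparsify()]
#' @export
key_trajectory <- function(time_ms, value, key_id, duration_ms) {
  stopifnot(length(time_ms) == length(value), is.character(key_id),
            length(key_id) == 1L)
  assert_scalar_number(duration_ms, "duration_ms", lower = 0)
  if (length(time_ms) > 0) {
    if (any(time_ms < 0)) abort("event times must be non-negative.")
    if (any(time_ms > duration_ms)) {
      abort("event times must not exceed `duration_ms`.")
    }
    if (any(diff(time_ms) <= 0)) {
      abort("event times within a key must be strictly increasing.")
    }
    if (any(value < 0 | value > 1)) {
      abort("analog values must lie in [0, 1].")
    }
    if (length(value) > 1 && any(diff(value) == 0)) {
      abort("consecutive events of one key must have different values (change-only log).")
    }
  }
  structure(
    list(key_id = key_id, time_ms = as.numeric(time_ms),
         value = as.numeric(value), duration_ms = as.numeric(duration_ms)),
    class = "key_trajectory"
  )
}

#' @export
print.key_trajectory <- function(x, ...) {
  cat(sprintf("<key_trajectory '%s': %d change events over %.0f ms>\n",
              x$key_id, length(x$time_ms), x$duration_ms))
  invisible(x)
}

#' Analog value of a trajectory at given times
#'
#' Evaluates the zero-order-hold reconstruction: the value of the most recent
#' event at or before `t`, or 0 if no event has occurred yet.
#'
#' @param traj A [key_trajectory()].
#' @param t Numeric vector of query times in ms; each must lie in
#'   \[0, `duration_ms`\].
#' @return Numeric vector of analog values in \[0, 1\].
#' @export
value_at <- function(traj, t) {
  stopifnot(inherits(traj, "key_trajectory"))
  if (any(t < 0 | t > traj$duration_ms)) {
    abort("query time outside [0, duration_ms].")
  }
  if (length(traj$time_ms) == 0) return(rep(0, length(t)))
  idx <- findInterval(t, traj$time_ms) # 0 => before first event
  c(0, traj$value)[idx + 1L]
}

#' Sample a trajectory onto a regular grid
#'
#' Inverse of the change-only sparsification: samples the reconstructed
#' signal at `t = 0, 1/rate, 2/rate, ...` up to the trial duration, mimicking
#' the keyboard's raw 1000 Hz polling.
#'
#' @inheritParams value_at
#' @param rate_hz Sampling rate in Hz (default 1000, the hardware poll rate).
#' @return A tibble with columns `time_ms`, `value`.
#' @export
densify <- function(traj, rate_hz = 1000) {
  assert_scalar_number(rate_hz, "rate_hz")
  if (rate_hz <= 0) abort("`rate_hz` must be positive.")
  step <- 1000 / rate_hz
  t <- seq(0, traj$duration_ms, by = step)
  tibble(time_ms = t, value = value_at(traj, t))
}

#' Compress a sampled trajectory back to change events
#'
#' Keeps only samples where the value differs from the previous retained
#' value, dropping an initial run of zeros (an unpressed key logs nothing).
#' For trajectories whose events lie on the sampling grid,
#' `sparsify(densify(x))` reproduces `x` exactly.
#'
#' @param samples A data frame with columns `time_ms`, `value` (as produced
#'   by [densify()]), in increasing time order.
#' @inheritParams key_trajectory
#' @return A [key_trajectory()].
#' @export
sparsify <- function(samples, key_id, duration_ms) {
  assert_columns(samples, c("time_ms", "value"), "`samples`")
  v <- samples$value
  keep <- v != dplyr::lag(v, default = 0)
  key_trajectory(samples$time_ms[keep], v[keep], key_id, duration_ms)
}

# CSV column types shared by readers/writers.
event_log_cols <- c("participant_id", "trial_index", "key_id", "time_ms", "value")
trial_meta_cols <- c("participant_id", "trial_index", "task", "condition",
                     "block", "item", "item_type", "correct_key",
                     "deadline_ms", "rsi_ms")

#' Read a change-event analog key log
#'
#' The on-disk format is a long UTF-8 CSV with a mandatory header and one row
#' per change event: `participant_id, trial_index, key_id, time_ms, value`.
#' Times are trial-relative (stimulus onset = 0). The reader validates the
#' change-only invariants and reports offending data rows by file line
#' number (header = line 1).
#'
#' @param path Path to the event-log CSV.
#' @param dialect Log dialect; only `"long_csv"` is currently defined.
#' @return A tibble of events (columns as above), in file order, with class
#'   `pp_events`.
#' @export
read_event_log <- function(path, dialect = "long_csv") {
  dialect <- match.arg(dialect, "long_csv")
  if (!file.exists(path)) abort(sprintf("event log not found: %s", path))
  raw <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      trial_index = readr::col_integer(),
      key_id = readr::col_character(),
      time_ms = readr::col_double(),
      value = readr::col_double()
    ),
    progress = FALSE
  )) # parse problems are re-raised below with file line numbers
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    # problems() rows count file lines (header = line 1)
    abort(sprintf("malformed event log row at line %d of %s: expected %s",
                  probs$row[1], path, probs$expected[1]))
  }
  assert_columns(raw, event_log_cols, sprintf("event log %s", path))
  validate_events(raw, file = path)
}

#' Validate an in-memory event table
#'
#' Checks the change-only log invariants: values in \[0, 1\], non-negative
#' strictly increasing times within each participant x trial x key, and no
#' consecutive duplicate values. Errors name the first offending data line
#' (counting a header as line 1, matching [read_event_log()] files).
#'
#' @param events A data frame of change events.
#' @param file Optional file name used in error messages.
#' @return The validated events as a `pp_events` tibble.
#' @export
validate_events <- function(events, file = NULL) {
  assert_columns(events, event_log_cols, "`events`")
  events <- as_tibble(events)
  where <- if (is.null(file)) "" else sprintf(" of %s", file)
  line_of <- function(i) i + 1L # header occupies line 1
  bad <- which(is.na(events$value) | events$value < 0 | events$value > 1)
  if (length(bad) > 0) {
    abort(sprintf("analog value outside [0, 1] at line %d%s (value = %s).",
                  line_of(bad[1]), where, events$value[bad[1]]))
  }
  bad <- which(is.na(events$time_ms) | events$time_ms < 0)
  if (length(bad) > 0) {
    abort(sprintf("negative or missing time_ms at line %d%s.",
                  line_of(bad[1]), where))
  }
  if (nrow(events) > 1) {
    same_key <- events$participant_id == dplyr::lag(events$participant_id) &
      events$trial_index == dplyr::lag(events$trial_index) &
      events$key_id == dplyr::lag(events$key_id)
    same_key[is.na(same_key)] <- FALSE
    dt <- events$time_ms - dplyr::lag(events$time_ms)
    bad <- which(same_key & dt <= 0)
    if (length(bad) > 0) {
      abort(sprintf("non-monotone timestamps within a key at line %d%s.",
                    line_of(bad[1]), where))
    }
    dup <- which(same_key & events$value == dplyr::lag(events$value))
    if (length(dup) > 0) {
      abort(sprintf("repeated analog value within a key at line %d%s (change-only log).",
                    line_of(dup[1]), where))
    }
  }
  class(events) <- c("pp_events", class(events))
  events
}

#' @rdname read_event_log
#' @param events A validated event tibble.
#' @export
write_event_log <- function(events, path) {
  assert_columns(events, event_log_cols, "`events`")
  readr::write_csv(events[event_log_cols], path, progress = FALSE)
  invisible(path)
}

#' Read / write trial metadata
#'
#' Trial metadata is a CSV with one row per planned or recorded trial:
#' `participant_id, trial_index, task, condition, block, item, item_type,
#' correct_key, deadline_ms, rsi_ms`.
#'
#' @param path Path to the metadata CSV.
#' @return A tibble of trials in file order.
#' @export
read_trial_metadata <- function(path) {
  if (!file.exists(path)) abort(sprintf("trial metadata not found: %s", path))
  meta <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      trial_index = readr::col_integer(),
      task = readr::col_character(),
      condition = readr::col_character(),
      block = readr::col_integer(),
      item = readr::col_character(),
      item_type = readr::col_character(),
      correct_key = readr::col_character(),
      deadline_ms = readr::col_double(),
      rsi_ms = readr::col_double()
    ),
    progress = FALSE
  ))
  probs <- readr::problems(meta)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed trial metadata at line %d of %s.",
                  probs$row[1], path))
  }
  assert_columns(meta, trial_meta_cols, sprintf("trial metadata %s", path))
  if (any(meta$deadline_ms <= 0)) abort("deadline_ms must be positive.")
  meta
}

#' @rdname read_trial_metadata
#' @param trials A trial metadata tibble (extra columns are dropped).
#' @export
write_trial_metadata <- function(trials, path) {
  assert_columns(trials, trial_meta_cols, "`trials`")
  readr::write_csv(trials[trial_meta_cols], path, progress = FALSE)
  invisible(path)
}

#' Nest an event table into per-trial trajectory lists
#'
#' Builds, for each participant x trial, a named list of [key_trajectory()]
#' objects (one per response key; keys with no events get an all-zero
#' trajectory). This is the bridge from tabular logs to the single-trial
#' operations [extract_response()], [detect_partial_error()] and
#' [flag_starts_pressed()].
#'
#' @param events Event tibble as returned by [read_event_log()].
#' @param trials Trial metadata tibble; supplies `deadline_ms` (the trial
#'   duration) and `correct_key`.
#' @param keys Character vector of the two response keys for the session.
#' @return A tibble with one row per trial: the metadata columns plus a
#'   list-column `trajectories`.
#' @export
as_trajectories <- function(events, trials, keys) {
  stopifnot(length(keys) == 2L)
  assert_columns(trials, c("participant_id", "trial_index", "deadline_ms"),
                 "`trials`")
  ev_split <- events |>
    dplyr::filter(.data$key_id %in% keys) |>
    dplyr::group_by(.data$participant_id, .data$trial_index, .data$key_id) |>
    dplyr::group_split()
  lookup <- new.env(parent = emptyenv())
  for (g in ev_split) {
    assign(paste(g$participant_id[1], g$trial_index[1], g$key_id[1], sep = "\r"),
           g, envir = lookup)
  }
  trials$trajectories <- purrr::pmap(
    list(trials$participant_id, trials$trial_index, trials$deadline_ms),
    function(pid, idx, dur) {
      out <- lapply(keys, function(k) {
        g <- get0(paste(pid, idx, k, sep = "\r"), envir = lookup)
        if (is.null(g)) {
          key_trajectory(numeric(0), numeric(0), k, dur)
        } else {
          key_trajectory(g$time_ms, g$value, k, dur)
        }
      })
      names(out) <- keys
      out
    }
  )
  trials
}
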