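#' Simulation configuration for analog-trajectory generation
#'
#' Defines the generative model used by [simulate_trial()] and
#' [simulate_experiment()]: per item type, an ex-Gaussian distribution of
#' the full-press latency (the time at which the pressed key's analog value
#' crosses the 0.95 response threshold), the probability that the incorrect
#' key shows an aborted sub-threshold press (a partial error), and error /
#' no-response rates. Press kinematics are piecewise-linear: a full press
#' ramps 0 to 1 over `ramp_ms`, holds, and releases over `release_ms`;
#' partial presses are triangular pulses with amplitude drawn from
#' `partial_amp_range` (capped strictly below 0.95 so an injected partial
#' can never register as a response) and duration from `partial_dur_range`,
#' always completed before the response crossing.
#'
#' Defaults emulate the published group-level statistics of each task:
#' CIT participant mean RTs near 583 ms (probes) and 469 ms (irrelevants)
#' with partial-press rates of roughly 2.9% and 0.5%; Sternberg mean RTs
#' near 1216/941/1094 ms (intrusion/new/match) with error rates matching the
#' reported per-type exclusion fractions.
#'
#' @param task `"CIT"` or `"STERNBERG"`; selects the default item types and
#'   their parameters.
#' @param item_types Named list overriding per-item-type parameter lists;
#'   each has `mu_ms`, `sigma_ms`, `beta_ms`, `p_partial`, `error_rate`.
#' @param ramp_ms,release_ms,hold_ms Full-press rise/fall/plateau durations.
#' @param partial_amp_range Amplitude range of aborted presses, within
#'   (0, 0.95).
#' @param partial_dur_range Duration range of aborted presses (ms).
#' @param partial_onset_offset_ms Range of the partial press's onset offset
#'   relative to the correct key's movement onset (ms; uniform draw).
#' @param no_response_rate,starts_pressed_rate Trial-level rates of omitted
#'   responses and of trials beginning with a residually pressed key.
#' @param min_latency_ms Lower truncation for drawn latencies, keeping the
#'   press onset clear of the 5 ms trial-start guard window.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(task = c("CIT", "STERNBERG"),
                       item_types = NULL,
                       ramp_ms = 60, release_ms = 40, hold_ms = 50,
                       partial_amp_range = c(0.05, 0.6),
                       partial_dur_range = c(40, 120),
                       partial_onset_offset_ms = c(-30, 30),
                       no_response_rate = 0.002,
                       starts_pressed_rate = 0.002,
                       min_latency_ms = 100) {
  task <- match.arg(task)
  defaults <- if (task == "CIT") {
    list(
      probe = list(mu_ms = 460, sigma_ms = 60, beta_ms = 120,
                   p_partial = 0.029, error_rate = 0.015),
      irrelevant = list(mu_ms = 350, sigma_ms = 55, beta_ms = 120,
                        p_partial = 0.005, error_rate = 0.008),
      target = list(mu_ms = 410, sigma_ms = 65, beta_ms = 120,
                    p_partial = 0.055, error_rate = 0.04)
    )
  } else {
    list(
      match = list(mu_ms = 930, sigma_ms = 170, beta_ms = 165,
                   p_partial = 0.017, error_rate = 0.16),
      intrusion = list(mu_ms = 1050, sigma_ms = 190, beta_ms = 165,
                       p_partial = 0.017, error_rate = 0.155),
      new = list(mu_ms = 775, sigma_ms = 160, beta_ms = 165,
                 p_partial = 0.002, error_rate = 0.06)
    )
  }
  if (!is.null(item_types)) {
    for (tt in names(item_types)) {
      defaults[[tt]] <- utils::modifyList(defaults[[tt]] %||% list(),
                                          item_types[[tt]])
    }
  }
  for (tt in names(defaults)) {
    p <- defaults[[tt]]
    stopifnot(p$sigma_ms > 0, p$beta_ms > 0,
              p$p_partial >= 0, p$p_partial <= 1,
              p$error_rate >= 0, p$error_rate <= 1)
  }
  stopifnot(
    partial_amp_range[1] > 0, partial_amp_range[2] < 0.95,
    partial_amp_range[1] <= partial_amp_range[2],
    partial_dur_range[1] > 0, diff(partial_dur_range) >= 0,
    no_response_rate >= 0, no_response_rate <= 1,
    starts_pressed_rate >= 0, starts_pressed_rate <= 1,
    ramp_ms > 0, release_ms > 0, hold_ms >= 0,
    # press onset must clear the 5 ms starts-pressed guard window
    min_latency_ms >= 0.95 * ramp_ms + 7
  )
  structure(
    list(task = task, item_types = defaults, ramp_ms = ramp_ms,
         release_ms = release_ms, hold_ms = hold_ms,
         partial_amp_range = partial_amp_range,
         partial_dur_range = partial_dur_range,
         partial_onset_offset_ms = partial_onset_offset_ms,
         no_response_rate = no_response_rate,
         starts_pressed_rate = starts_pressed_rate,
         min_latency_ms = min_latency_ms),
    class = "sim_config"
  )
}

# Per-trial latent draws for a block of planned trials. Returns one row per
# trial with everything needed to lay out events deterministically.
draw_trial_params <- function(trials, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- nrow(trials)
  pars <- cfg$item_types[trials$item_type]
  bad <- vapply(pars, is.null, logical(1))
  if (any(bad)) {
    abort(sprintf("sim_config has no parameters for item type '%s'.",
                  trials$item_type[which(bad)[1]]))
  }
  mu <- unname(vapply(pars, `[[`, numeric(1), "mu_ms"))
  sigma <- unname(vapply(pars, `[[`, numeric(1), "sigma_ms"))
  beta <- unname(vapply(pars, `[[`, numeric(1), "beta_ms"))
  p_part <- unname(vapply(pars, `[[`, numeric(1), "p_partial"))
  err <- unname(vapply(pars, `[[`, numeric(1), "error_rate"))

  latency <- pmax(cfg$min_latency_ms, rexgauss(n, mu, sigma, beta))
  # grid-crossing time implied by the continuous latency (strict > 0.95)
  rt_grid <- floor(latency) + 1
  no_resp <- stats::runif(n) < cfg$no_response_rate | rt_grid > trials$deadline_ms
  is_err <- stats::runif(n) < err
  partial <- stats::runif(n) < p_part
  amp <- stats::runif(n, cfg$partial_amp_range[1], cfg$partial_amp_range[2])
  dur <- stats::runif(n, cfg$partial_dur_range[1], cfg$partial_dur_range[2])
  offset <- stats::runif(n, cfg$partial_onset_offset_ms[1],
                         cfg$partial_onset_offset_ms[2])
  sp <- stats::runif(n) < cfg$starts_pressed_rate
  sp_key_first <- stats::runif(n) < 0.5

  keys2 <- t(vapply(seq_len(n), function(i) {
    ks <- sort(unique(c(trials$correct_key[i], trials$incorrect_key[i])))
    ks
  }, character(2)))

  tibble(
    trial_index = trials$trial_index,
    correct_key = trials$correct_key,
    incorrect_key = trials$incorrect_key,
    deadline_ms = trials$deadline_ms,
    item_type = trials$item_type,
    latency = latency, rt_grid = rt_grid,
    no_response = no_resp, is_error = is_err,
    partial = partial, amp = amp, dur = dur, offset = offset,
    starts_pressed = sp,
    sp_key = ifelse(sp_key_first, keys2[, 1], keys2[, 2])
  )
}

# Lay out change events (integer-ms grid) for one participant's drawn trial
# parameters. Fully vectorised: each press/partial/blip segment is expanded
# with rep()/sequence() rather than a per-trial loop.
layout_events <- function(params, cfg, participant_id) {
  ramp <- cfg$ramp_ms
  press_key <- ifelse(params$is_error, params$incorrect_key, params$correct_key)
  other_key <- ifelse(params$is_error, params$correct_key, params$incorrect_key)
  responded <- !params$no_response

  seg <- function(trial, key, t_start, n, value_fun, ...) {
    n <- pmax(0L, as.integer(n))
    if (sum(n) == 0) {
      return(tibble(trial_index = integer(0), key_id = character(0),
                    time_ms = numeric(0), value = numeric(0)))
    }
    t <- sequence(n) - 1 + rep(t_start, n)
    tibble(
      trial_index = rep(trial, n),
      key_id = rep(key, n),
      time_ms = t,
      value = value_fun(t, n, ...)
    )
  }

  # full press: ramp 0 -> 1 crossing 0.95 at the drawn latency
  t0 <- params$latency - 0.95 * ramp         # movement onset (real)
  a <- ceiling(t0 + 1e-9)                    # first grid sample with value > 0
  b <- ceiling(t0 + ramp - 1e-9)             # first grid sample at value 1
  bc <- pmin(b, floor(params$deadline_ms))
  n_up <- ifelse(responded, bc - a + 1, 0)
  up <- seg(params$trial_index, press_key, a, n_up,
            function(t, n) pmin(1, (t - rep(t0, n)) / ramp))

  # release: 1 -> 0 after a short plateau, clipped at the deadline
  s0 <- b + cfg$hold_ms
  rel_end <- pmin(s0 + cfg$release_ms, floor(params$deadline_ms))
  n_rel <- ifelse(responded & b <= params$deadline_ms, rel_end - s0, 0)
  rel <- seg(params$trial_index, press_key, s0 + 1, n_rel,
             function(t, n) pmax(0, 1 - (t - rep(s0, n)) / cfg$release_ms))

  # aborted press of the incorrect key: triangular pulse contained in
  # [6, latency - 2] so it can never be flagged starts-pressed nor cross
  # after the response
  dur <- params$dur
  p_end_max <- params$latency - 2
  dur <- pmin(dur, pmax(4, p_end_max - 6))
  p0 <- pmax(6, pmin(t0 + params$offset, p_end_max - dur))
  feasible <- responded & params$partial & (p0 + dur <= p_end_max + 1e-9) &
    dur >= 4
  n_part <- ifelse(feasible, floor(p0 + dur) - floor(p0 + 1) + 1, 0)
  part <- seg(params$trial_index, other_key, floor(p0 + 1), n_part,
              function(t, n) {
                p0r <- rep(p0, n); dr <- rep(dur, n); ar <- rep(params$amp, n)
                half <- dr / 2
                x <- t - p0r
                v <- ifelse(x <= half, ar * x / half,
                            ar * pmax(0, 1 - (x - half) / (dr - half)))
                pmax(0, pmin(ar, v))
              })
  # force the pulse to end at rest exactly
  part_end <- floor(p0 + dur)[match(part$trial_index, params$trial_index)]
  part$value[part$time_ms == part_end] <- 0

  # starts-pressed blip: residual depression in the first few ms, released
  # shortly after the guard window
  blip_v <- c(0.04, 0.06, 0.02, 0)
  n_blip <- ifelse(params$starts_pressed, 4L, 0L)
  blip <- seg(params$trial_index, params$sp_key,
              rep(1, length(n_blip)), n_blip,
              function(t, n) rep(blip_v, times = length(t) %/% 4L))

  events <- bind_rows(up, rel, part, blip) |>
    mutate(participant_id = participant_id) |>
    arrange(.data$trial_index, .data$key_id, .data$time_ms) |>
    group_by(.data$trial_index, .data$key_id) |>
    dplyr::filter(.data$value != dplyr::lag(.data$value, default = 0)) |>
    ungroup() |>
    select("participant_id", "trial_index", "key_id", "time_ms", "value")
  events
}

#' Simulate one trial's analog trajectories
#'
#' Generative counterpart of the detection logic: draws an ex-Gaussian
#' full-press latency for the trial's item type and lays out change events on
#' the 1 ms grid. With probability `p_partial` the incorrect key receives an
#' aborted sub-threshold pulse completed before the response crossing; with
#' probability `error_rate` the key roles swap; latency draws whose grid
#' crossing falls after the deadline become no-response trials.
#'
#' @param trial A one-row trial tibble with `trial_index`, `item_type`,
#'   `correct_key`, `deadline_ms`.
#' @param cfg A [sim_config()].
#' @param keys The two response keys.
#' @param participant_id Participant label for the emitted events.
#' @param seed Integer seed.
#' @return A list with `events` (change-event tibble), `truth` (one-row
#'   ground-truth tibble) and `trajectories` (named list of
#'   [key_trajectory()]).
#' @export
simulate_trial <- function(trial, cfg, keys = c("e", "i"),
                           participant_id = "sim", seed = 1) {
  sim <- simulate_participant(trial, cfg, keys = keys,
                              participant_id = participant_id, seed = seed)
  trial$participant_id <- participant_id
  traj <- as_trajectories(sim$events, trial, keys = keys)$trajectories[[1]]
  list(events = sim$events, truth = sim$truth, trajectories = traj)
}

#' Simulate all trials of one participant
#'
#' @param design A design tibble (one participant's planned trials) with
#'   `trial_index`, `item_type`, `correct_key`, `deadline_ms`.
#' @inheritParams simulate_trial
#' @return A list with `events` and `truth` tibbles.
#' @export
simulate_participant <- function(design, cfg, keys = c("e", "i"),
                                 participant_id = "sim", seed = 1) {
  stopifnot(length(keys) == 2L, !anyDuplicated(keys))
  assert_columns(design, c("trial_index", "item_type", "correct_key",
                           "deadline_ms"), "`design`")
  if (!all(design$correct_key %in% keys)) {
    abort("design uses correct keys absent from `keys`.")
  }
  design <- design |>
    mutate(incorrect_key = ifelse(.data$correct_key == keys[1],
                                  keys[2], keys[1]))
  with_seed(seed, {
    params <- draw_trial_params(design, cfg)
    events <- layout_events(params, cfg, participant_id)
    truth <- params |>
      mutate(
        participant_id = participant_id,
        true_rt_ms = ifelse(.data$no_response, NA_real_, .data$rt_grid),
        true_partial = !.data$no_response & .data$partial,
        true_amp = ifelse(.data$true_partial, .data$amp, NA_real_),
        true_pressed_key = ifelse(.data$no_response, NA_character_,
                                  ifelse(.data$is_error, .data$incorrect_key,
                                         .data$correct_key)),
        true_starts_pressed = .data$starts_pressed
      ) |>
      select("participant_id", "trial_index", "item_type", "true_rt_ms",
             "true_pressed_key", "true_partial", "true_amp",
             "true_starts_pressed")
    list(events = events, truth = truth)
  })
}

#' Simulate a multi-participant experiment
#'
#' Runs [simulate_participant()] for each virtual participant on its own
#' seeded design (block orders re-randomized per participant, as for real
#' examinees) and optionally writes the event-log, trial-metadata and
#' ground-truth CSVs.
#'
#' @param task `"CIT"` or `"STERNBERG"`.
#' @param n_participants Number of virtual participants; conditions
#'   (low/high) are assigned alternately unless `conditions` is given.
#' @param cfg A [sim_config()]; defaults to the task's defaults.
#' @param conditions Optional character vector of per-participant conditions.
#' @param seed Top-level seed; per-participant design and trajectory seeds
#'   are derived from it.
#' @param keys The two response keys.
#' @param phase Which design phase(s) to simulate (default `"test"`).
#' @param out_dir If non-`NULL`, directory (created if needed) receiving
#'   `events.csv`, `trials.csv`, `truth.csv`.
#' @return A list with tibbles `events`, `trials`, `truth` (and `paths` when
#'   files were written).
#' @export
simulate_experiment <- function(task = c("CIT", "STERNBERG"),
                                n_participants = 1,
                                cfg = sim_config(task),
                                conditions = NULL,
                                seed = 1,
                                keys = c(no = "e", yes = "i"),
                                phase = "test",
                                out_dir = NULL) {
  task <- match.arg(task)
  if (is.null(conditions)) {
    conditions <- rep(c("low", "high"), length.out = n_participants)
  }
  stopifnot(length(conditions) == n_participants)
  res <- purrr::map(seq_len(n_participants), function(i) {
    pid <- sprintf("p%03d", i)
    design_seed <- derive_seed(seed, 2L * i)
    traj_seed <- derive_seed(seed, 2L * i + 1L)
    design <- if (task == "CIT") {
      generate_cit_design(condition = conditions[i], seed = design_seed,
                          keys = keys)
    } else {
      generate_sternberg_design(condition = conditions[i], seed = design_seed,
                                keys = keys)
    }
    design <- design |>
      dplyr::filter(.data$phase %in% !!phase) |>
      mutate(participant_id = pid)
    sim <- simulate_participant(design, cfg, keys = unname(keys),
                                participant_id = pid, seed = traj_seed)
    trials <- design |>
      mutate(participant_id = pid) |>
      select(dplyr::any_of(c(trial_meta_cols, "phase", "category",
                             "cue_color", "probe_pos")))
    list(events = sim$events, trials = trials,
         truth = sim$truth |>
           dplyr::left_join(design |> select("trial_index", "condition"),
                            by = "trial_index"))
  })
  out <- list(
    events = bind_rows(purrr::map(res, "events")),
    trials = bind_rows(purrr::map(res, "trials")),
    truth = bind_rows(purrr::map(res, "truth"))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      events = file.path(out_dir, "events.csv"),
      trials = file.path(out_dir, "trials.csv"),
      truth = file.path(out_dir, "truth.csv")
    )
    write_event_log(out$events, paths$events)
    write_trial_metadata(out$trials, paths$trials)
    readr::write_csv(out$truth, paths$truth, progress = FALSE)
    out$paths <- paths
  }
  out
}
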