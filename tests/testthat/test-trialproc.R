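test_that("extract_response finds the first strict threshold crossing", {
  tr <- make_trial(e_times = c(300, 340), e_values = c(0.5, 0.96))
  out <- extract_response(tr)
  expect_equal(out$rt_ms, 340)
  expect_equal(out$pressed_key, "e")
  expect_false(out$is_error)

  silent <- make_trial()
  out2 <- extract_response(silent)
  expect_true(is.na(out2$rt_ms))
  expect_true(is.na(out2$pressed_key))
  expect_equal(out2$exclusion_reason, "no_response")

  # a value of exactly 0.95 does not count as pressed: the rule is strict
  boundary <- make_trial(e_times = c(400, 410), e_values = c(0.95, 0.96))
  expect_equal(extract_response(boundary)$rt_ms, 410)

  # crossing after the deadline is no response
  late <- make_trial(e_times = 1600, e_values = 1, deadline = 2000)
  late$deadline_ms <- 1500
  late$trajectories$e <- traj(1600, 1, "e", 2000)
  late$trajectories$i <- traj(numeric(0), numeric(0), "i", 2000)
  expect_equal(extract_response(late)$exclusion_reason, "no_response")

  expect_error(extract_response(tr, full_press_threshold = 1), "strictly within")
})

test_that("simultaneous crossings resolve by analog value, exact tie is an error", {
  both <- make_trial(e_times = 500, e_values = 0.97,
                     i_times = 500, i_values = 0.99, correct_key = "e")
  out <- extract_response(both)
  expect_equal(out$pressed_key, "i")
  expect_true(out$is_error)

  tie <- make_trial(e_times = 500, e_values = 0.97,
                    i_times = 500, i_values = 0.97, correct_key = "e")
  out2 <- extract_response(tie)
  expect_true(out2$is_error)
  expect_equal(out2$rt_ms, 500)
})

test_that("detect_partial_error requires both keys nonzero strictly before the crossing", {
  # aborted press of the incorrect key, then the correct-key response
  tr <- make_trial(e_times = c(450, 500), e_values = c(0.5, 0.96),
                   i_times = c(250, 300), i_values = c(0.3, 0))
  out <- extract_response(tr)
  expect_true(detect_partial_error(tr, out))

  clean <- make_trial(e_times = c(450, 500), e_values = c(0.5, 0.96))
  expect_false(detect_partial_error(clean, extract_response(clean)))

  # incorrect key first moves exactly at the crossing: strictly-before fails
  at_rt <- make_trial(e_times = c(450, 500), e_values = c(0.5, 0.96),
                      i_times = 500, i_values = 0.3)
  expect_false(detect_partial_error(at_rt, extract_response(at_rt)))

  silent <- make_trial()
  expect_error(detect_partial_error(silent, extract_response(silent)),
               "responded")
})

test_that("starts-pressed flag covers the closed guard window", {
  expect_true(flag_starts_pressed(make_trial(i_times = 2, i_values = 0.1)))
  expect_true(flag_starts_pressed(make_trial(e_times = 5, e_values = 0.1)))
  expect_false(flag_starts_pressed(make_trial(e_times = 6, e_values = 0.1)))
  expect_false(flag_starts_pressed(make_trial()))
})

test_that("exclusions partition trials in fixed priority order", {
  mk <- function(rt, err, sp, it) {
    tibble::tibble(rt_ms = rt, is_error = err, starts_pressed = sp,
                   item_type = it)
  }
  toy <- dplyr::bind_rows(
    mk(600, FALSE, FALSE, "probe"),      # retained
    mk(150, FALSE, FALSE, "irrelevant"), # too fast
    mk(600, TRUE, FALSE, "probe"),       # error
    mk(NA, FALSE, FALSE, "irrelevant"),  # no response
    mk(700, FALSE, TRUE, "probe"),       # starts pressed
    mk(1600, FALSE, FALSE, "irrelevant"),# too slow
    mk(650, FALSE, FALSE, "target"),     # target trial
    mk(500, FALSE, FALSE, "irrelevant"), # retained
    mk(150, TRUE, TRUE, "target"),       # starts pressed beats all others
    mk(800, FALSE, FALSE, "probe")       # retained
  )
  out <- apply_exclusions(toy, exclusion_policy("CIT"))
  counts <- attr(out, "exclusion_counts")
  expect_equal(counts[["none"]], 3)
  expect_equal(counts[["starts_pressed"]], 2)
  expect_equal(counts[["too_fast"]], 1)
  expect_equal(counts[["too_slow"]], 1)
  expect_equal(counts[["error"]], 1)
  expect_equal(counts[["no_response"]], 1)
  expect_equal(counts[["target_trial"]], 1)
  expect_equal(sum(counts), nrow(toy)) # exhaustive partition
  expect_equal(attr(out, "exclusion_fraction"), 7 / 10)

  # Sternberg bounds: 2499 ms correct trial is retained
  stb <- apply_exclusions(mk(2499, FALSE, FALSE, "match"),
                          exclusion_policy("STERNBERG"))
  expect_equal(as.character(stb$exclusion_reason), "none")

  expect_error(exclusion_policy("CIT", rt_min_ms = -5), "positive")
})

test_that("participant summaries use retained trials and flag empty cells", {
  out <- tibble::tibble(
    participant_id = "p1",
    item_type = c(rep("probe", 4), "target"),
    rt_ms = c(500, 600, 550, 650, 500),
    is_error = FALSE,
    is_partial_error = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    exclusion_reason = factor(c(rep("none", 4), "target_trial"),
                              levels = partialpress:::exclusion_reasons)
  )
  s <- summarize_participant(out)
  probe <- s[s$item_type == "probe", ]
  expect_equal(probe$mean_rt_ms, 575)
  expect_equal(probe$prop_partial, 0.25)
  expect_equal(probe$n_valid, 4L)
  target <- s[s$item_type == "target", ]
  expect_equal(target$n_valid, 0L)
  expect_true(is.na(target$mean_rt_ms)) # absent, never 0
})

test_that("performance filter drops only below-threshold categories", {
  expect_false(participant_performance_filter(
    c(match = 0.9, intrusion = 0.55, new = 0.8)))
  expect_true(participant_performance_filter(
    c(match = 0.9, intrusion = 0.7, new = 0.8)))
  expect_true(participant_performance_filter( # boundary: exactly 60% keeps
    c(match = 0.6, intrusion = 0.6, new = 0.6)))
  expect_error(participant_performance_filter(
    c(match = 0.9, new = 0.8),
    required_categories = c("match", "intrusion", "new")), "intrusion")
  expect_error(participant_performance_filter(c(match = 1.2)), "\\[0, 1\\]")
})

test_that("vectorised processing equals the single-trial operations", {
  design <- generate_cit_design(seed = 3) |>
    dplyr::filter(phase == "test") |>
    dplyr::slice(1:80) |>
    dplyr::mutate(participant_id = "p1")
  cfg <- sim_config("CIT",
                    item_types = list(probe = list(p_partial = 0.5),
                                      irrelevant = list(p_partial = 0.3),
                                      target = list(p_partial = 0.4)),
                    starts_pressed_rate = 0.1)
  sim <- simulate_participant(design, cfg, participant_id = "p1", seed = 17)
  fast <- process_trials(sim$events, design)
  nested <- as_trajectories(sim$events, design, keys = c("e", "i"))
  for (k in seq_len(nrow(nested))) {
    trial <- nested[k, ]
    slow <- extract_response(trial)
    row <- fast[fast$trial_index == trial$trial_index, ]
    expect_equal(row$rt_ms, slow$rt_ms)
    expect_equal(row$pressed_key, slow$pressed_key)
    sp <- flag_starts_pressed(trial)
    expect_equal(row$starts_pressed, sp)
    if (!is.na(slow$rt_ms) && !sp) {
      expect_equal(row$is_partial_error, detect_partial_error(trial, slow))
    }
  }
})

test_that("lowering the full-press threshold never increases any RT", {
  design <- generate_cit_design(seed = 8) |>
    dplyr::filter(phase == "test") |>
    dplyr::slice(1:120) |>
    dplyr::mutate(participant_id = "p1")
  sim <- simulate_participant(design, sim_config("CIT"),
                              participant_id = "p1", seed = 23)
  hi <- process_trials(sim$events, design, full_press_threshold = 0.95)
  lo <- process_trials(sim$events, design, full_press_threshold = 0.5)
  both <- dplyr::inner_join(
    hi |> dplyr::select(trial_index, rt_hi = rt_ms),
    lo |> dplyr::select(trial_index, rt_lo = rt_ms),
    by = "trial_index"
  ) |>
    dplyr::filter(!is.na(rt_hi))
  expect_true(all(!is.na(both$rt_lo)))
  expect_true(all(both$rt_lo <= both$rt_hi))
})

test_that("zero-conflict simulation yields exactly zero partial errors", {
  design <- generate_cit_design(seed = 4) |>
    dplyr::filter(phase == "test") |>
    dplyr::mutate(participant_id = "p1")
  cfg <- sim_config("CIT", item_types = list(
    probe = list(p_partial = 0), irrelevant = list(p_partial = 0),
    target = list(p_partial = 0)
  ))
  sim <- simulate_participant(design, cfg, participant_id = "p1", seed = 6)
  out <- process_trials(sim$events, design)
  expect_equal(sum(out$is_partial_error), 0)
})
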