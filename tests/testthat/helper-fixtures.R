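# Small construction helpers used across the suite.

traj <- function(times, values, key = "e", dur = 1500) {
  key_trajectory(times, values, key, dur)
}

# A minimal trial record in the shape the single-trial operations expect.
make_trial <- function(e_times = numeric(0), e_values = numeric(0),
                       i_times = numeric(0), i_values = numeric(0),
                       correct_key = "e", deadline = 1500,
                       item_type = "probe") {
  list(
    participant_id = "t", trial_index = 1L, item_type = item_type,
    correct_key = correct_key, deadline_ms = deadline,
    trajectories = list(
      e = traj(e_times, e_values, "e", deadline),
      i = traj(i_times, i_values, "i", deadline)
    )
  )
}

# Long event rows for hand-built trials.
event_rows <- function(trial_index, key_id, time_ms, value,
                       participant_id = "t") {
  tibble::tibble(participant_id = participant_id,
                 trial_index = as.integer(trial_index),
                 key_id = key_id, time_ms = time_ms, value = value)
}

write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
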