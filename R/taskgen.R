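#' Synthetic item pool for the RT-CIT
#'
#' The RT-CIT uses five autobiographical information categories (name,
#' surname, date of birth, street, city) with seven candidate items per
#' category, of which one is the examinee's true detail (the probe). Real
#' studies build this pool from participant input; for simulation and testing
#' this helper emits clearly synthetic placeholder items with exactly one
#' probe per category.
#'
#' @param items_per_category Number of candidate items per category (>= 6;
#'   the design consumes 6: 1 probe, 1 target, 4 irrelevants).
#' @return A tibble with columns `category`, `item`, `is_probe`.
#' @export
default_cit_pool <- function(items_per_category = 7) {
  stopifnot(items_per_category >= 6)
  categories <- c("name", "surname", "birthday", "street", "city")
  tidyr::expand_grid(
    category = categories,
    slot = seq_len(items_per_category)
  ) |>
    mutate(
      item = sprintf("%s_%02d", .data$category, .data$slot),
      is_probe = .data$slot == 1L
    ) |>
    select("category", "item", "is_probe")
}

#' Synthetic word pool for the modified Sternberg task
#'
#' Deterministic list of unique synthetic "nouns" (consonant-vowel syllable
#' strings). The design needs roughly 6 words per trial plus one extra per
#' new trial, and no word may appear twice anywhere, so the pool must be
#' comfortably larger than `6 * n_trials`.
#'
#' @param n Number of words to generate.
#' @return Character vector of `n` unique synthetic words.
#' @export
default_word_pool <- function(n = 900) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t")
  vow <- c("a", "e", "i", "o", "u")
  syll <- as.vector(outer(cons, vow, paste0))
  words <- as.vector(outer(syll, syll, paste0)) # 3600 distinct two-syllable words
  if (n > length(words)) abort("requested word pool larger than available combinations.")
  words[seq_len(n)]
}

practice_cit_deadlines <- c(10000, 1500, 1500)
practice_cit_feedback <- c(10000, 1200, 800)
practice_sternberg_deadlines <- c(6000, 2500)
practice_sternberg_feedback <- c(6000, 1500)

#' Generate an RT-CIT trial sequence
#'
#' Builds the full concealed-information-test design: five categories with
#' six items each (1 probe, 1 target, 4 irrelevants), three practice blocks
#' of 30 trials (every item once per block) and a test phase of 20 blocks of
#' 30 trials, i.e. 600 test trials (100 probes, 100 targets, 400
#' irrelevants). Within-block order is a seeded permutation; the
#' response-stimulus interval is drawn uniformly from \[500, 1000\] ms.
#' Practice-block response deadlines are 10 s / 1.5 s / 1.5 s with
#' "too slow" feedback thresholds 10 s / 1.2 s / 0.8 s; the test deadline is
#' 1.5 s.
#'
#' @param item_pool Tibble with columns `category`, `item`, `is_probe`
#'   (exactly one probe and at least five further items per category). Items
#'   a participant flagged as personally relevant should be removed before
#'   calling; the design errors if fewer than six usable items remain.
#' @param condition `"low"` (learned targets) or `"high"` (personally
#'   familiar targets). Affects only the condition label: which concrete
#'   items serve as targets is a recruitment matter, not a sequence one.
#' @param seed Integer seed; the same seed reproduces the design exactly.
#' @param keys Named character vector `c(no = ..., yes = ...)` giving the
#'   response keys (NO is conventionally mapped to the dominant hand).
#' @return A tibble with one row per planned trial: `task`, `condition`,
#'   `phase` (`"practice"`/`"test"`), `block`, `trial_in_block`,
#'   `trial_index`, `category`, `item`, `item_type`
#'   (`probe`/`target`/`irrelevant`), `correct_key`, `deadline_ms`,
#'   `feedback_threshold_ms`, `rsi_ms`.
#' @examples
#' d <- generate_cit_design(seed = 1)
#' table(d$item_type[d$phase == "test"])
#' @export
generate_cit_design <- function(item_pool = default_cit_pool(),
                                condition = c("low", "high"),
                                seed = 1,
                                keys = c(no = "e", yes = "i")) {
  condition <- match.arg(condition)
  assert_columns(item_pool, c("category", "item", "is_probe"), "`item_pool`")
  stopifnot(all(c("no", "yes") %in% names(keys)))
  counts <- item_pool |> count(.data$category)
  if (any(counts$n < 6)) {
    abort("item pool must supply at least 6 items per category (1 probe + 5 candidates).")
  }
  n_probe <- item_pool |> dplyr::filter(.data$is_probe) |> count(.data$category)
  if (nrow(n_probe) != nrow(counts) || any(n_probe$n != 1)) {
    abort("item pool must contain exactly one probe per category.")
  }

  with_seed(seed, {
    roles <- item_pool |>
      group_by(.data$category) |>
      group_modify(function(g, key) {
        probe <- g$item[g$is_probe]
        others <- sample(g$item[!g$is_probe], 5)
        tibble(
          item = c(probe, others[1], others[2:5]),
          item_type = c("probe", "target", rep("irrelevant", 4))
        )
      }) |>
      ungroup()

    one_block <- function(phase, block) {
      idx <- sample.int(nrow(roles))
      roles[idx, ] |>
        mutate(phase = phase, block = block, trial_in_block = dplyr::row_number())
    }
    blocks <- c(
      lapply(1:3, function(b) one_block("practice", b)),
      lapply(1:20, function(b) one_block("test", b))
    )
    design <- bind_rows(blocks) |>
      mutate(
        task = "CIT",
        condition = condition,
        trial_index = dplyr::row_number(),
        correct_key = ifelse(.data$item_type == "target",
                             keys[["yes"]], keys[["no"]]),
        deadline_ms = ifelse(.data$phase == "practice",
                             practice_cit_deadlines[.data$block], 1500),
        feedback_threshold_ms = ifelse(.data$phase == "practice",
                                       practice_cit_feedback[.data$block],
                                       NA_real_),
        rsi_ms = stats::runif(dplyr::n(), 500, 1000)
      ) |>
      select("task", "condition", "phase", "block", "trial_in_block",
             "trial_index", "category", "item", "item_type", "correct_key",
             "deadline_ms", "feedback_threshold_ms", "rsi_ms")
    design
  })
}

# Exact trial-type counts for a Sternberg phase of n trials. Match trials are
# always 50%; the intrusion/new split encodes how valid familiarity is as a
# cue (low validity: 40%/10%; high validity: 15%/35%). Non-integer counts
# (only possible for ad-hoc n) are resolved by rounding intrusions half-up
# and giving the remainder to new trials.
sternberg_counts <- function(n, condition) {
  p_int <- if (condition == "low") 0.40 else 0.15
  n_match <- round(n * 0.5)
  n_int <- round(n * p_int)
  n_new <- n - n_match - n_int
  c(match = n_match, intrusion = n_int, new = n_new)
}

# Maximally even assignment of `values` to `n` slots: exact balance where n
# is divisible, otherwise remainders are assigned by a seeded draw (caller
# holds the RNG state).
balanced_fill <- function(values, n) {
  base <- rep(values, n %/% length(values))
  rem <- n %% length(values)
  extra <- if (rem > 0) sample(values, rem) else values[0]
  sample(c(base, extra))
}

#' Generate a modified Sternberg trial sequence
#'
#' Cued word recognition: each trial presents two three-word lists in colored
#' frames (blue/yellow, shown 4.8 s, then an 800 ms blank), then a probe word
#' in one of the two colors. The probe is in the cued list (*match*, YES), in
#' the other list (*intrusion*, NO), or in neither (*new*, NO). The test
#' phase has 120 trials, 50% match in both conditions; the low-validity
#' condition uses 40% intrusion / 10% new trials and the high-validity
#' condition 15% / 35%. Cue color and the probe's serial position are
#' balanced exactly across match and across intrusion trials (counts are
#' divisible at n = 120; maximal evenness with seeded remainders otherwise),
#' and no word appears more than once anywhere in the design. Two practice
#' blocks of 10 trials precede the test (deadlines 6 s / 2.5 s, feedback
#' thresholds 6 s / 1.5 s); the test deadline is 2.5 s.
#'
#' @param word_pool Character vector of distinct candidate words; must be
#'   large enough that no word repeats (about 6.5 words per trial).
#' @param condition `"low"` or `"high"` familiarity-cue validity.
#' @inheritParams generate_cit_design
#' @return A tibble with one row per trial: `task`, `condition`, `phase`,
#'   `block`, `trial_in_block`, `trial_index`, `item` (the probe word),
#'   `item_type` (`match`/`intrusion`/`new`), `cue_color`, `probe_pos`
#'   (serial position 1-3 within its list, `NA` for new trials),
#'   `cued_list`/`other_list` (semicolon-joined three-word lists),
#'   `correct_key`, `deadline_ms`, `feedback_threshold_ms`, `rsi_ms`,
#'   `list_display_ms`, `blank_ms`.
#' @examples
#' d <- generate_sternberg_design(condition = "low", seed = 2)
#' table(d$item_type[d$phase == "test"])
#' @export
generate_sternberg_design <- function(word_pool = default_word_pool(),
                                      condition = c("low", "high"),
                                      seed = 1,
                                      keys = c(no = "e", yes = "i")) {
  condition <- match.arg(condition)
  stopifnot(all(c("no", "yes") %in% names(keys)))
  if (anyDuplicated(word_pool)) abort("`word_pool` contains duplicate words.")

  n_test <- 120L
  n_practice_block <- 10L
  test_counts <- sternberg_counts(n_test, condition)
  prac_counts <- sternberg_counts(2L * n_practice_block, condition)

  with_seed(seed, {
    # trial skeletons: type, cue color, probe position, per phase
    skeleton <- function(counts, phase) {
      parts <- lapply(names(counts), function(tt) {
        n <- counts[[tt]]
        if (n == 0) return(NULL)
        if (tt == "new") {
          tibble(item_type = "new",
                 cue_color = balanced_fill(c("blue", "yellow"), n),
                 probe_pos = NA_integer_)
        } else {
          combos <- tidyr::expand_grid(cue_color = c("blue", "yellow"),
                                       probe_pos = 1:3)
          idx <- balanced_fill(seq_len(nrow(combos)), n)
          tibble(item_type = tt,
                 cue_color = combos$cue_color[idx],
                 probe_pos = combos$probe_pos[idx])
        }
      })
      bind_rows(parts)[sample.int(sum(counts)), ] |>
        mutate(phase = phase)
    }
    trials <- bind_rows(
      skeleton(prac_counts, "practice"),
      skeleton(test_counts, "test")
    )
    n_total <- nrow(trials)
    n_new_total <- sum(trials$item_type == "new")
    need <- 6L * n_total + n_new_total
    if (length(word_pool) < need) {
      abort(sprintf("word pool too small: need %d distinct words, have %d.",
                    need, length(word_pool)))
    }
    words <- sample(word_pool, need)
    list_words <- matrix(words[seq_len(6L * n_total)], ncol = 6)
    new_words <- words[(6L * n_total) + seq_len(n_new_total)]

    trials <- trials |>
      mutate(
        cued_list = apply(list_words[, 1:3, drop = FALSE], 1, paste, collapse = ";"),
        other_list = apply(list_words[, 4:6, drop = FALSE], 1, paste, collapse = ";")
      )
    probe <- character(n_total)
    is_new <- trials$item_type == "new"
    probe[is_new] <- new_words
    is_match <- trials$item_type == "match"
    probe[is_match] <- list_words[cbind(which(is_match),
                                        trials$probe_pos[is_match])]
    is_int <- trials$item_type == "intrusion"
    probe[is_int] <- list_words[cbind(which(is_int),
                                      trials$probe_pos[is_int] + 3L)]
    trials$item <- probe

    trials |>
      group_by(.data$phase) |>
      mutate(
        block = if (.data$phase[1] == "practice") {
          (dplyr::row_number() - 1L) %/% n_practice_block + 1L
        } else {
          rep(1L, dplyr::n())
        },
        trial_in_block = dplyr::row_number() -
          (.data$block - 1L) * n_practice_block
      ) |>
      ungroup() |>
      mutate(
        task = "STERNBERG",
        condition = condition,
        trial_index = dplyr::row_number(),
        correct_key = ifelse(.data$item_type == "match",
                             keys[["yes"]], keys[["no"]]),
        deadline_ms = ifelse(.data$phase == "practice",
                             practice_sternberg_deadlines[.data$block], 2500),
        feedback_threshold_ms = ifelse(.data$phase == "practice",
                                       practice_sternberg_feedback[.data$block],
                                       NA_real_),
        rsi_ms = stats::runif(dplyr::n(), 500, 1000),
        list_display_ms = 4800,
        blank_ms = 800
      ) |>
      select("task", "condition", "phase", "block", "trial_in_block",
             "trial_index", "item", "item_type", "cue_color", "probe_pos",
             "cued_list", "other_list", "correct_key", "deadline_ms",
             "feedback_threshold_ms", "rsi_ms", "list_display_ms", "blank_ms")
  })
}

#' Accuracy of a purely familiarity-based responder
#'
#' Scores the policy "answer YES if and only if the probe word occurs in
#' either memory list" against a generated Sternberg design's ground truth.
#' Such a responder is correct on match trials (probe in the cued list) and
#' new trials (probe in neither list) but always wrong on intrusion trials,
#' so its accuracy measures how valid familiarity is as a cue: 60% in the
#' low-validity design, 85% in the high-validity design.
#'
#' @param design A Sternberg design tibble from
#'   [generate_sternberg_design()].
#' @param phase Which phase to score (default the test phase).
#' @return Proportion of trials in \[0, 1\] the policy answers correctly.
#' @export
familiarity_responder_accuracy <- function(design, phase = "test") {
  assert_columns(design, c("task", "phase", "item", "item_type",
                           "cued_list", "other_list"), "`design`")
  if (!all(design$task == "STERNBERG")) {
    abort("familiarity-based responding is defined for Sternberg designs only.")
  }
  d <- design |> dplyr::filter(.data$phase %in% !!phase)
  in_lists <- purrr::pmap_lgl(
    list(d$item, d$cued_list, d$other_list),
    function(item, cued, other) {
      item %in% c(strsplit(cued, ";")[[1]], strsplit(other, ";")[[1]])
    }
  )
  policy_says_yes <- in_lists
  truth_is_yes <- d$item_type == "match"
  mean(policy_says_yes == truth_is_yes)
}

#' Practice-phase pass check
#'
#' Applies the RT-CIT practice criterion to the outcomes of the final
#' practice block: the block fails if any item type (probe, target,
#' irrelevant) has accuracy below 50% or if the overall mean response time
#' exceeds 800 ms. Trials without a response count as incorrect and
#' contribute no RT. The modified Sternberg task has no repetition
#' criterion, so Sternberg outcomes always pass.
#'
#' @param outcomes A tibble with columns `item_type`, `is_error`, `rt_ms`
#'   (`rt_ms` `NA` for no-response trials, which are scored as errors).
#' @param task `"CIT"` or `"STERNBERG"`.
#' @return A list with `pass` (logical) and `reason` (string, `"ok"` on
#'   pass).
#' @export
check_practice_pass <- function(outcomes, task = c("CIT", "STERNBERG")) {
  task <- match.arg(task)
  if (task == "STERNBERG") return(list(pass = TRUE, reason = "ok"))
  assert_columns(outcomes, c("item_type", "is_error", "rt_ms"), "`outcomes`")
  acc <- outcomes |>
    group_by(.data$item_type) |>
    summarise(accuracy = mean(!.data$is_error & !is.na(.data$rt_ms)),
              .groups = "drop")
  low <- acc |> dplyr::filter(.data$accuracy < 0.5)
  if (nrow(low) > 0) {
    return(list(pass = FALSE,
                reason = sprintf("accuracy below 50%% for item type '%s'",
                                 low$item_type[1])))
  }
  mean_rt <- mean(outcomes$rt_ms, na.rm = TRUE)
  if (is.finite(mean_rt) && mean_rt > 800) {
    return(list(pass = FALSE,
                reason = sprintf("mean RT %.0f ms exceeds 800 ms", mean_rt)))
  }
  list(pass = TRUE, reason = "ok")
}
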