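test_that("CIT designs have the exact item-type structure for every seed", {
  for (seed in 1:25) {
    d <- generate_cit_design(seed = seed)
    test <- d[d$phase == "test", ]
    expect_equal(nrow(test), 600)
    expect_equal(sort(as.vector(table(test$item_type))), c(100, 100, 400))
    expect_equal(as.vector(table(test$item_type)[c("probe", "target", "irrelevant")]),
                 c(100, 100, 400))
    # every item exactly once per block, 20 times over the test phase
    expect_true(all(table(test$item) == 20))
    per_block <- table(test$block, test$item)
    expect_true(all(per_block == 1))
    # practice: 3 blocks of 30, every item once per block
    prac <- d[d$phase == "practice", ]
    expect_equal(nrow(prac), 90)
    expect_true(all(table(prac$block, prac$item) == 1))
  }
})

test_that("CIT design metadata matches the task constants", {
  d <- generate_cit_design(seed = 2)
  expect_equal(unique(d$deadline_ms[d$phase == "test"]), 1500)
  prac <- d[d$phase == "practice", ]
  expect_equal(as.vector(tapply(prac$deadline_ms, prac$block, unique)),
               c(10000, 1500, 1500))
  expect_equal(as.vector(tapply(prac$feedback_threshold_ms, prac$block, unique)),
               c(10000, 1200, 800))
  expect_true(all(d$rsi_ms >= 500 & d$rsi_ms <= 1000))
  expect_setequal(unique(d$correct_key[d$item_type == "target"]), "i")
  expect_setequal(unique(d$correct_key[d$item_type != "target"]), "e")
})

test_that("CIT generation is seed-deterministic and validates its pool", {
  a <- generate_cit_design(seed = 7)
  b <- generate_cit_design(seed = 7)
  expect_identical(a, b)
  c <- generate_cit_design(seed = 8)
  expect_false(identical(a$item, c$item))
  small <- default_cit_pool() |>
    dplyr::group_by(category) |>
    dplyr::slice(1:5) |>
    dplyr::ungroup() # only 5 items per category
  expect_error(generate_cit_design(item_pool = small), "at least 6")
  no_probe <- default_cit_pool() |> dplyr::mutate(is_probe = FALSE)
  expect_error(generate_cit_design(item_pool = no_probe), "exactly one probe")
})

test_that("Sternberg designs have exact trial-type counts in both conditions", {
  for (seed in 1:25) {
    lo <- generate_sternberg_design(condition = "low", seed = seed)
    hi <- generate_sternberg_design(condition = "high", seed = seed)
    lo_t <- lo[lo$phase == "test", ]
    hi_t <- hi[hi$phase == "test", ]
    expect_equal(nrow(lo_t), 120)
    expect_equal(nrow(hi_t), 120)
    expect_equal(as.vector(table(lo_t$item_type)[c("match", "intrusion", "new")]),
                 c(60, 48, 12))
    expect_equal(as.vector(table(hi_t$item_type)[c("match", "intrusion", "new")]),
                 c(60, 18, 42))
  }
})

test_that("no word is presented more than once anywhere in a Sternberg design", {
  d <- generate_sternberg_design(condition = "low", seed = 13)
  all_words <- c(
    unlist(strsplit(d$cued_list, ";")),
    unlist(strsplit(d$other_list, ";")),
    d$item[d$item_type == "new"]
  )
  expect_equal(anyDuplicated(all_words), 0)
  # probes of match/intrusion trials are list members, so they are the only
  # legal second occurrences
  expect_true(all(d$item[d$item_type != "new"] %in% all_words))
  expect_error(generate_sternberg_design(word_pool = default_word_pool(100)),
               "too small")
  expect_error(generate_sternberg_design(word_pool = c("aa", "aa")),
               "duplicate")
})

test_that("cue color and serial position are balanced over match and intrusion trials", {
  d <- generate_sternberg_design(condition = "low", seed = 3)
  t <- d[d$phase == "test", ]
  m <- t[t$item_type == "match", ]
  expect_equal(as.vector(table(m$cue_color)), c(30, 30))
  expect_equal(as.vector(table(m$probe_pos)), c(20, 20, 20))
  i <- t[t$item_type == "intrusion", ]
  expect_equal(as.vector(table(i$cue_color)), c(24, 24))
  expect_equal(as.vector(table(i$probe_pos)), c(16, 16, 16))
  hi <- generate_sternberg_design(condition = "high", seed = 3)
  ih <- hi[hi$phase == "test" & hi$item_type == "intrusion", ]
  expect_equal(as.vector(table(ih$cue_color)), c(9, 9))
  expect_equal(as.vector(table(ih$probe_pos)), c(6, 6, 6))
})

test_that("the probe word sits where the trial type says it sits", {
  d <- generate_sternberg_design(condition = "high", seed = 19)
  t <- d[d$phase == "test", ]
  cued <- strsplit(t$cued_list, ";")
  other <- strsplit(t$other_list, ";")
  for (k in seq_len(nrow(t))) {
    if (t$item_type[k] == "match") {
      expect_equal(cued[[k]][t$probe_pos[k]], t$item[k])
    } else if (t$item_type[k] == "intrusion") {
      expect_equal(other[[k]][t$probe_pos[k]], t$item[k])
    } else {
      expect_false(t$item[k] %in% c(cued[[k]], other[[k]]))
    }
  }
  expect_setequal(unique(t$correct_key[t$item_type == "match"]), "i")
  expect_setequal(unique(t$correct_key[t$item_type != "match"]), "e")
})

test_that("familiarity-based responding scores 60% / 85% by design", {
  lo <- generate_sternberg_design(condition = "low", seed = 31)
  hi <- generate_sternberg_design(condition = "high", seed = 31)
  expect_equal(familiarity_responder_accuracy(lo), 0.60)
  expect_equal(familiarity_responder_accuracy(hi), 0.85)
  # with intrusion trials removed, familiarity is always a valid cue
  no_intrusion <- lo[lo$item_type != "intrusion", ]
  expect_equal(familiarity_responder_accuracy(no_intrusion), 1.0)
  expect_error(familiarity_responder_accuracy(generate_cit_design(seed = 1)))
})

test_that("practice pass rule applies the accuracy and mean-RT criteria", {
  mk <- function(acc_by_type, mean_rt) {
    rows <- lapply(names(acc_by_type), function(tt) {
      n <- 10
      n_ok <- round(acc_by_type[[tt]] * n)
      tibble::tibble(item_type = tt,
                     is_error = rep(c(FALSE, TRUE), c(n_ok, n - n_ok)),
                     rt_ms = mean_rt)
    })
    dplyr::bind_rows(rows)
  }
  good <- mk(list(probe = 0.9, target = 0.9, irrelevant = 0.9), 700)
  expect_true(check_practice_pass(good, "CIT")$pass)
  bad_acc <- mk(list(probe = 0.9, target = 0.4, irrelevant = 0.9), 700)
  res <- check_practice_pass(bad_acc, "CIT")
  expect_false(res$pass)
  expect_match(res$reason, "target")
  slow <- mk(list(probe = 0.9, target = 0.9, irrelevant = 0.9), 801)
  res2 <- check_practice_pass(slow, "CIT")
  expect_false(res2$pass)
  expect_match(res2$reason, "800")
  expect_true(check_practice_pass(good, "STERNBERG")$pass)
})
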