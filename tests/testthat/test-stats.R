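test_that("LexTALE scoring follows the averaged percent-correct formula", {
  expect_equal(lextale_score(40, 20)$score, 100)
  expect_true(lextale_score(40, 20)$included)
  expect_equal(lextale_score(0, 0)$score, 0)
  expect_false(lextale_score(0, 0)$included)
  expect_equal(lextale_score(30, 15)$score, 75)
  # a score of exactly 70 is excluded: inclusion needs > 70
  expect_false(lextale_score(40, 8)$included)
  expect_equal(lextale_score(40, 8)$score, 70)
  expect_error(lextale_score(41, 0), "0-40")
  expect_error(lextale_score(10, 21), "0-20")
  expect_error(lextale_score(10.5, 2), "integers")
})

test_that("arcsine transform matches its closed forms", {
  expect_equal(arcsine_transform(0), 0)
  expect_equal(arcsine_transform(1), pi / 2)
  expect_equal(arcsine_transform(0.25), pi / 6)
  expect_error(arcsine_transform(1.1), "\\[0, 1\\]")
  expect_error(arcsine_transform(-0.1), "\\[0, 1\\]")
})

test_that("JZS t-test BF matches independent dense-grid quadrature", {
  # fixed vector engineered to t = 3.0 at n = 20
  d0 <- scale(withr::with_seed(2, rnorm(20)))[, 1]
  d <- d0 + 3.0 / sqrt(20)
  tstat <- mean(d) / (sd(d) / sqrt(20))
  expect_equal(tstat, 3.0, tolerance = 1e-12)
  impl <- exp(tidy(jzs_ttest_bf(d))$log_bf)
  oracle <- ttest_bf_oracle(d)
  expect_equal(signif(impl, 3), signif(oracle, 3))
  # a second fixture with negative effect, one-sided variants
  d2 <- d0 - 1.2 / sqrt(20)
  expect_equal(signif(exp(tidy(jzs_ttest_bf(d2, direction = "less"))$log_bf), 3),
               signif(ttest_bf_oracle(d2, direction = "less"), 3))
  # the sided marginals average to the two-sided one
  bf_g <- exp(tidy(jzs_ttest_bf(d, direction = "greater"))$log_bf)
  bf_l <- exp(tidy(jzs_ttest_bf(d, direction = "less"))$log_bf)
  bf_2 <- exp(tidy(jzs_ttest_bf(d))$log_bf)
  expect_equal((bf_g + bf_l) / 2, bf_2, tolerance = 1e-6)
})

test_that("t-test BF handles degenerate and null inputs as specified", {
  expect_error(jzs_ttest_bf(rep(0, 10)), "zero variance")
  expect_error(jzs_ttest_bf(rep(2, 10)), "zero variance")
  expect_error(jzs_ttest_bf(1), "at least two")
  # t = 0: the null is favoured
  sym <- c(-2, -1, 1, 2)
  expect_lt(exp(tidy(jzs_ttest_bf(sym))$log_bf), 1)
})

test_that("mixed ANOVA BF detects a within effect and rejects an absent interaction", {
  sm <- make_summary_table(35, probe_shift = 110, part_sd = 60,
                           noise_sd = 30, seed = 7)
  bf <- jzs_mixed_anova_bf(sm, dv = "mean_rt", samples = 6000, seed = 1)
  td <- tidy(bf)
  expect_gt(td$log_bf[td$model_a == "Main"], log(100))
  expect_lt(td$log_bf[td$model_a == "Full"], 0)
})

test_that("ANOVA BFs are invariant to participant relabeling and dv shifts", {
  sm <- make_summary_table(16, probe_shift = 40, seed = 3)
  base <- tidy(jzs_mixed_anova_bf(sm, dv = "mean_rt", samples = 4000, seed = 5))
  relab <- sm
  relab$participant_id <- sprintf("zz_%s", rev(relab$participant_id))
  shifted <- sm
  shifted$mean_rt_ms <- shifted$mean_rt_ms + 1000
  for (variant in list(relab, shifted)) {
    td <- tidy(jzs_mixed_anova_bf(variant, dv = "mean_rt", samples = 4000,
                                  seed = 5))
    expect_equal(td$log_bf, base$log_bf, tolerance = 0.05)
  }
})

test_that("a constant dv favours the simpler model in every comparison", {
  sm <- make_summary_table(12, probe_shift = 0, part_sd = 0, noise_sd = 0,
                           seed = 1)
  sm$mean_rt_ms <- 500
  td <- tidy(jzs_mixed_anova_bf(sm, dv = "mean_rt", samples = 4000, seed = 2))
  expect_true(all(td$log_bf < 0))
})

test_that("ANOVA BF validates balance and factor structure", {
  sm <- make_summary_table(10, seed = 2)
  expect_error(jzs_mixed_anova_bf(sm[-1, ], dv = "mean_rt"), "unbalanced")
  bad_cond <- sm
  bad_cond$condition[1] <- "high"
  bad_cond$condition[2] <- "low"
  expect_error(jzs_mixed_anova_bf(bad_cond, dv = "mean_rt"),
               "exactly one between")
  one_cond <- sm
  one_cond$condition <- "low"
  expect_error(jzs_mixed_anova_bf(one_cond, dv = "mean_rt"), "2 levels")
})

test_that("under the null the within-effect BF favours the smaller model", {
  n_rep <- 50
  log_bfs <- vapply(seq_len(n_rep), function(r) {
    sm <- make_summary_table(14, probe_shift = 0, part_sd = 50,
                             noise_sd = 30, seed = 100 + r)
    td <- tidy(jzs_mixed_anova_bf(sm, dv = "mean_rt", samples = 1500,
                                  seed = r))
    td$log_bf[td$model_a == "Main"]
  }, numeric(1))
  expect_lt(median(log_bfs), 0)
})

test_that("arcsine option transforms the dv before modelling", {
  sm <- make_summary_table(12, probe_shift = 0.02, base = 0.02,
                           part_sd = 0.01, noise_sd = 0.01, seed = 9,
                           dv_name = "prop_partial")
  sm$prop_partial <- pmin(pmax(sm$prop_partial, 0), 1)
  plain <- tidy(jzs_mixed_anova_bf(sm, dv = "prop_partial", samples = 3000,
                                   seed = 4))
  asin_v <- tidy(jzs_mixed_anova_bf(sm, dv = "prop_partial", samples = 3000,
                                    seed = 4, transform = "arcsine"))
  expect_false(identical(plain$log_bf, asin_v$log_bf))
  manual <- sm
  manual$prop_partial <- arcsine_transform(manual$prop_partial)
  manual_td <- tidy(jzs_mixed_anova_bf(manual, dv = "prop_partial",
                                       samples = 3000, seed = 4))
  expect_equal(asin_v$log_bf, manual_td$log_bf, tolerance = 1e-10)
})

test_that("ex-Gaussian MLE recovers parameters and satisfies moment identities", {
  x <- withr::with_seed(31, rexgauss(4000, 500, 50, 100))
  fit <- exgauss_mle(x)
  expect_true(fit$converged)
  est <- tidy(fit)
  expect_equal(est$estimate[est$term == "mu"], 500,
               tolerance = 3 * est$std_error[est$term == "mu"] / 500 + 0.02)
  # moment identities: mean = mu + beta, var = sigma^2 + beta^2
  expect_equal(fit$conditional_mean, mean(x), tolerance = 0.01)
  expect_equal(sum(est$estimate[est$term %in% c("sigma", "beta")]^2),
               var(x), tolerance = 0.1 * var(x))
})

test_that("degenerate RT samples are flagged, not silently fitted", {
  flat <- exgauss_mle(rep(500, 100))
  expect_false(flat$converged)
  expect_error(exgauss_mle(c(-1, 400, 500)), "positive")
})

test_that("per-cell ex-Gaussian fits respect the minimum cell size", {
  d <- withr::with_seed(32, tibble::tibble(
    rt_ms = rexgauss(400, 480, 50, 110),
    item_type = rep(c("probe", "irrelevant"), each = 200),
    is_partial_error = FALSE
  ))
  fit <- fit_exgaussian(d, cell_cols = "item_type", min_cell = 50)
  expect_s3_class(fit, "exgauss_cells_fit")
  expect_equal(nrow(fit$cells), 2)
  expect_true(all(fit$cells$converged))
  expect_equal(fit$cells$conditional_mean, fit$cells$mu + fit$cells$beta)
  expect_error(fit_exgaussian(d[1:40, ], cell_cols = "item_type"),
               "below the minimum")
})

test_that("hierarchical ex-Gaussian variant recovers fixed effects approximately", {
  d <- withr::with_seed(33, {
    n_per <- 150
    g <- tidyr::expand_grid(
      participant_id = sprintf("p%02d", 1:6),
      item_type = c("irrelevant", "probe"),
      rep = seq_len(n_per)
    )
    u <- rnorm(6, 0, 30)
    g$category <- sample(c("name", "city", "street"), nrow(g), replace = TRUE)
    shift <- ifelse(g$item_type == "probe", 100, 0)
    g$rt_ms <- rexgauss(nrow(g), 450 + shift +
                          u[as.integer(factor(g$participant_id))], 50, 100)
    g$is_partial_error <- FALSE
    g
  })
  fit <- fit_exgaussian(d, hierarchical = TRUE, max_em_iter = 3)
  expect_s3_class(fit, "exgauss_hier_fit")
  co <- fit$fixef$mu
  probe_term <- co[grepl("probe", names(co))][1]
  expect_equal(unname(probe_term), 100, tolerance = 0.25 * 100)
  expect_true(is.finite(fit$loglik))
})

test_that("signed-rank BF is directional and antisymmetric under sign flips", {
  d <- withr::with_seed(41, rnorm(20, 0.5, 0.8))
  up <- tidy(signed_rank_bf(d, direction = "greater", seed = 3,
                            iterations = 1200))
  expect_gt(up$log_bf, 0)
  down <- tidy(signed_rank_bf(-d, direction = "less", seed = 3,
                              iterations = 1200))
  expect_equal(up$log_bf, down$log_bf, tolerance = 0.5 + up$error + down$error)
  flipped <- tidy(signed_rank_bf(-d, direction = "greater", seed = 3,
                                 iterations = 1200))
  expect_lt(flipped$log_bf, 0)
  expect_error(suppressWarnings(signed_rank_bf(rep(0, 10))), "nonzero")
  expect_warning(signed_rank_bf(c(0, 1, 2, 3, -1, 2, 1.5, 0.5)), "zero")
})

test_that("signed-rank BF is self-consistent across seeds within MC error", {
  d <- withr::with_seed(43, rnorm(18, 0.25, 1))
  a <- tidy(signed_rank_bf(d, seed = 1, iterations = 1500))
  b <- tidy(signed_rank_bf(d, seed = 2, iterations = 1500))
  expect_equal(a$log_bf, b$log_bf,
               tolerance = 0.5 + 2 * (a$error + b$error))
})

test_that("Bayes-factor objects print and tidy coherently", {
  d <- withr::with_seed(44, rnorm(12, 0.8, 1))
  res <- jzs_ttest_bf(d)
  expect_output(print(res), "JZS t test")
  g <- glance(res)
  expect_equal(g$n_comparisons, 1)
  td <- tidy(res)
  expect_equal(td$bf, exp(td$log_bf))
})
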