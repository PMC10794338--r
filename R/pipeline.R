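#' Run configuration
#'
#' Central configuration for the simulate / process / analyze pipeline.
#' Defaults mirror the published task constants: full-press threshold 0.95,
#' 5 ms starts-pressed guard, RT bounds 200-1500 ms (CIT) or 200-2500 ms
#' (Sternberg), ANOVA prior scale 0.5 and t-test prior scale 0.707.
#'
#' @param task `"CIT"` or `"STERNBERG"`.
#' @param condition `"low"`, `"high"`, or `"both"` (alternating assignment).
#' @param n_participants Number of virtual participants for simulation.
#' @param seed Top-level seed for all derived randomness.
#' @param out_dir Directory for pipeline inputs/outputs.
#' @param full_press_threshold,onset_guard_ms Detection thresholds.
#' @param rt_min_ms,rt_max_ms RT exclusion bounds (default by task).
#' @param anova_prior_scale,ttest_prior_scale Cauchy prior scales.
#' @param anova_samples Monte-Carlo draws per ANOVA model marginal.
#' @param keys Named `c(no = , yes = )` response keys.
#' @param overrides Named list overriding any of the above (e.g. parsed from
#'   a YAML config file via [read_run_config()]).
#' @return A list of class `run_config`.
#' @export
run_config <- function(task = "CIT", condition = "both",
                       n_participants = 2, seed = 1, out_dir = "pp_run",
                       full_press_threshold = 0.95, onset_guard_ms = 5,
                       rt_min_ms = 200,
                       rt_max_ms = NULL,
                       anova_prior_scale = 0.5, ttest_prior_scale = 0.707,
                       anova_samples = 10000,
                       keys = c(no = "e", yes = "i"),
                       overrides = NULL) {
  cfg <- list(task = task, condition = condition,
              n_participants = n_participants, seed = seed,
              out_dir = out_dir,
              full_press_threshold = full_press_threshold,
              onset_guard_ms = onset_guard_ms,
              rt_min_ms = rt_min_ms, rt_max_ms = rt_max_ms,
              anova_prior_scale = anova_prior_scale,
              ttest_prior_scale = ttest_prior_scale,
              anova_samples = anova_samples, keys = keys)
  if (!is.null(overrides)) {
    keep <- intersect(names(overrides), names(cfg))
    cfg[keep] <- overrides[keep]
    if ("keys" %in% keep) cfg$keys <- unlist(cfg$keys)
  }
  cfg$task <- match.arg(toupper(cfg$task), c("CIT", "STERNBERG"))
  cfg$condition <- match.arg(cfg$condition, c("both", "low", "high"))
  if (is.null(cfg$rt_max_ms)) {
    cfg$rt_max_ms <- if (cfg$task == "CIT") 1500 else 2500
  }
  if (cfg$full_press_threshold <= 0 || cfg$full_press_threshold >= 1) {
    abort("`full_press_threshold` must lie in (0, 1).")
  }
  if (cfg$rt_min_ms <= 0 || cfg$rt_max_ms <= cfg$rt_min_ms) {
    abort("RT bounds must be positive with max > min.")
  }
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path Path to a YAML config file whose keys override the defaults.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  run_config(overrides = yaml::read_yaml(path))
}

cfg_conditions <- function(cfg) {
  if (cfg$condition == "both") {
    rep(c("low", "high"), length.out = cfg$n_participants)
  } else {
    rep(cfg$condition, cfg$n_participants)
  }
}

#' Pipeline commands: simulate, process, analyze
#'
#' Thin wrappers tying the package together for scripted use. `cmd_simulate`
#' generates designs and simulated event logs (plus ground truth) under
#' `cfg$out_dir`; `cmd_process` reads them back, extracts outcomes and
#' writes the outcome and participant-summary tables, printing the
#' exclusion breakdown; `cmd_analyze` runs the Bayes-factor analyses on the
#' summaries and writes a JSON + markdown report. All three log the
#' resolved configuration and are deterministic given `cfg$seed`.
#'
#' @param cfg A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list of the objects written (with file paths).
#' @export
cmd_simulate <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_config(cfg, quiet)
  sim <- simulate_experiment(
    task = cfg$task, n_participants = cfg$n_participants,
    cfg = sim_config(cfg$task), conditions = cfg_conditions(cfg),
    seed = cfg$seed, keys = cfg$keys, out_dir = cfg$out_dir
  )
  if (!quiet) {
    message(sprintf("simulated %d trials (%d events) for %d participant(s) -> %s",
                    nrow(sim$trials), nrow(sim$events), cfg$n_participants,
                    cfg$out_dir))
  }
  invisible(sim)
}

#' @rdname cmd_simulate
#' @export
cmd_process <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  events <- read_event_log(file.path(cfg$out_dir, "events.csv"))
  trials <- read_trial_metadata(file.path(cfg$out_dir, "trials.csv"))
  policy <- exclusion_policy(cfg$task, rt_min_ms = cfg$rt_min_ms,
                             rt_max_ms = cfg$rt_max_ms)
  outcomes <- process_trials(
    events, trials, keys = unname(cfg$keys),
    full_press_threshold = cfg$full_press_threshold,
    onset_guard_ms = cfg$onset_guard_ms, policy = policy
  )
  summaries <- summarize_participants(outcomes)
  out_path <- file.path(cfg$out_dir, "outcomes.csv")
  sum_path <- file.path(cfg$out_dir, "summaries.csv")
  readr::write_csv(outcomes |> mutate(exclusion_reason =
                                        as.character(.data$exclusion_reason)),
                   out_path, progress = FALSE)
  readr::write_csv(summaries, sum_path, progress = FALSE)
  if (!quiet) {
    counts <- attr(outcomes, "exclusion_counts")
    message("exclusion breakdown:")
    for (nm in names(counts)) {
      message(sprintf("  %-15s %d", nm, counts[[nm]]))
    }
    message(sprintf("excluded %.2f%% of %d trials",
                    100 * attr(outcomes, "exclusion_fraction"),
                    nrow(outcomes)))
  }
  invisible(list(outcomes = outcomes, summaries = summaries,
                 paths = list(outcomes = out_path, summaries = sum_path)))
}

#' @rdname cmd_simulate
#' @export
cmd_analyze <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  summaries <- readr::read_csv(file.path(cfg$out_dir, "summaries.csv"),
                               show_col_types = FALSE)
  outcomes <- readr::read_csv(file.path(cfg$out_dir, "outcomes.csv"),
                              show_col_types = FALSE)
  report <- analyze_experiment(
    outcomes, summaries, task = cfg$task,
    anova_prior_scale = cfg$anova_prior_scale,
    ttest_prior_scale = cfg$ttest_prior_scale,
    anova_samples = cfg$anova_samples, seed = cfg$seed
  )
  json_path <- file.path(cfg$out_dir, "report.json")
  md_path <- file.path(cfg$out_dir, "report.md")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  writeLines(format_report_md(report), md_path)
  if (!quiet) message(sprintf("report written to %s and %s", json_path, md_path))
  invisible(c(report, list(paths = list(json = json_path, md = md_path))))
}

#' Bayes-factor analysis of processed outcomes
#'
#' Runs the task's standard participant-level model comparisons on a
#' summary table: for the CIT, the 2 (probe vs irrelevant) x 2 (condition)
#' mixed ANOVA on mean RTs and on partial-press proportions; for the
#' Sternberg task, the intrusion-vs-new ANOVA on RTs, the three-level ANOVA
#' on partial proportions, plus the directional pairwise signed-rank and t
#' tests between intrusion and new / match partial proportions.
#'
#' @param outcomes Trial-level outcome tibble (for exclusion counts).
#' @param summaries Participant summary tibble.
#' @param task `"CIT"` or `"STERNBERG"`.
#' @param anova_prior_scale,ttest_prior_scale,anova_samples,seed Analysis
#'   settings.
#' @return A nested list (JSON-serialisable report).
#' @export
analyze_experiment <- function(outcomes, summaries,
                               task = c("CIT", "STERNBERG"),
                               anova_prior_scale = 0.5,
                               ttest_prior_scale = 0.707,
                               anova_samples = 10000,
                               seed = 1) {
  task <- match.arg(task)
  excl <- outcomes |>
    count(.data$exclusion_reason) |>
    mutate(exclusion_reason = as.character(.data$exclusion_reason))
  cells <- summaries |>
    group_by(.data$item_type) |>
    summarise(mean_rt_ms = mean(.data$mean_rt_ms, na.rm = TRUE),
              sd_rt_ms = stats::sd(.data$mean_rt_ms, na.rm = TRUE),
              mean_prop_partial = mean(.data$prop_partial, na.rm = TRUE),
              sd_prop_partial = stats::sd(.data$prop_partial, na.rm = TRUE),
              .groups = "drop")

  rt_levels <- if (task == "CIT") c("irrelevant", "probe") else c("intrusion", "new")
  pp_levels <- if (task == "CIT") c("irrelevant", "probe") else c("intrusion", "match", "new")
  ok_sum <- summaries |>
    dplyr::filter(!is.na(.data$mean_rt_ms))
  anova_rt <- jzs_mixed_anova_bf(ok_sum, dv = "mean_rt",
                                 within_levels = rt_levels,
                                 prior_scale = anova_prior_scale,
                                 samples = anova_samples,
                                 seed = derive_seed(seed, 11))
  anova_pp <- jzs_mixed_anova_bf(ok_sum, dv = "prop_partial",
                                 within_levels = pp_levels,
                                 prior_scale = anova_prior_scale,
                                 samples = anova_samples,
                                 seed = derive_seed(seed, 12))
  report <- list(
    task = task,
    n_participants = length(unique(summaries$participant_id)),
    exclusions = excl,
    cell_means = cells,
    anova_mean_rt = tidy(anova_rt),
    anova_prop_partial = tidy(anova_pp)
  )
  if (task == "STERNBERG") {
    wide <- ok_sum |>
      select("participant_id", "item_type", "prop_partial") |>
      tidyr::pivot_wider(names_from = "item_type",
                         values_from = "prop_partial")
    if (all(c("intrusion", "new", "match") %in% names(wide))) {
      d_in <- wide$intrusion - wide$new
      d_im <- wide$intrusion - wide$match
      # zero differences are routine when partials are rare; the drop is
      # recorded in the report rather than surfaced as a warning
      report$signed_rank_intrusion_new <- tryCatch(
        suppressWarnings(tidy(signed_rank_bf(d_in, direction = "greater",
                                             seed = derive_seed(seed, 13)))),
        error = function(e) list(error = conditionMessage(e)))
      report$ttest_intrusion_match <- tryCatch(
        tidy(jzs_ttest_bf(d_im, prior_scale = ttest_prior_scale,
                          direction = "greater")),
        error = function(e) list(error = conditionMessage(e)))
    }
  }
  report
}

format_report_md <- function(report) {
  lines <- c(
    sprintf("# Analysis report: %s", report$task),
    "",
    sprintf("Participants: %d", report$n_participants),
    "",
    "## Exclusions",
    utils::capture.output(print(as.data.frame(report$exclusions))),
    "",
    "## Cell means",
    utils::capture.output(print(as.data.frame(report$cell_means))),
    "",
    "## Mixed ANOVA BFs (mean RT)",
    utils::capture.output(print(as.data.frame(report$anova_mean_rt))),
    "",
    "## Mixed ANOVA BFs (partial-press proportion)",
    utils::capture.output(print(as.data.frame(report$anova_prop_partial)))
  )
  lines
}

log_config <- function(cfg, quiet) {
  if (quiet) return(invisible())
  message("resolved configuration:")
  flat <- unlist(cfg)
  for (nm in names(flat)) message(sprintf("  %s = %s", nm, flat[[nm]]))
}

#' Command-line entry point
#'
#' Dispatches `simulate`, `process`, `analyze` or `report` (process +
#' analyze) with flags `--task`, `--condition`, `--seed`,
#' `--participants`, `--out`, `--config`. Used by the installed
#' `cli/partialpress.R` script; callable directly for testing.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit code (0 on success), invisibly.
#' @export
pp_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    message("usage: partialpress <simulate|process|analyze|report> [--task cit|sternberg] [--condition low|high|both] [--seed N] [--participants N] [--out DIR] [--config FILE]")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- list()
  rest <- args[-1]
  i <- 1
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (i + 1 > length(rest)) {
      message(sprintf("missing value for --%s", key)); return(invisible(2L))
    }
    opts[[key]] <- rest[i + 1]
    i <- i + 2
  }
  res <- tryCatch({
    base <- if (!is.null(opts$config)) {
      read_run_config(opts$config)
    } else {
      run_config()
    }
    overrides <- list()
    if (!is.null(opts$task)) overrides$task <- toupper(opts$task)
    if (!is.null(opts$condition)) overrides$condition <- opts$condition
    if (!is.null(opts$seed)) overrides$seed <- as.integer(opts$seed)
    if (!is.null(opts$participants)) {
      overrides$n_participants <- as.integer(opts$participants)
    }
    if (!is.null(opts$out)) overrides$out_dir <- opts$out
    cfg <- run_config(overrides = utils::modifyList(unclass(base), overrides))
    switch(cmd,
      simulate = cmd_simulate(cfg),
      process = cmd_process(cfg),
      analyze = cmd_analyze(cfg),
      report = { cmd_process(cfg); cmd_analyze(cfg) },
      abort(sprintf("unknown command '%s'.", cmd))
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    3L
  })
  invisible(res)
}
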