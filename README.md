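# partialpress

Detecting **partial errors** — sub-threshold presses of the *incorrect*
response key — from analog gaming keyboards in response-conflict tasks.

Analog (hall-effect) keyboards report how far every key is depressed, as a
continuous value in [0, 1] polled at 1000 Hz. In speeded conflict
paradigms such as the reaction-time Concealed Information Test (RT-CIT)
and the modified Sternberg task, conflict between the prepared and the
required response can surface as a brief, aborted movement of the wrong
key before the overt response. `partialpress` is a tidyverse-style toolkit
for researchers who want to measure that signal end to end:

* **Trajectory reconstruction** from change-only event logs (only value
  *changes* are recorded): zero-order-hold interpolation, densify/sparsify
  round trips, validated long-CSV readers and writers.
* **Outcome extraction**: response time = first analog value > .95 within
  the deadline; partial error = both keys > 0 strictly before that
  crossing; starts-pressed flagging (value > 0 in the first 5 ms); the
  standard exclusion pipeline (200 ms / deadline RT bounds, errors,
  target trials) with fixed priority order; participant × item-type
  summaries.
* **Exact task generators** for the RT-CIT (600 test trials: 100 probes,
  100 targets, 400 irrelevants, every item once per block) and the
  modified Sternberg task (120 trials; 50% match; 40/10 or 15/35
  intrusion/new split by condition; cue color and serial position
  balanced; no word repeated).
* **A seeded trajectory simulator** with ex-Gaussian latencies and
  injectable partial presses, emitting the same log format plus ground
  truth, for end-to-end validation.
* **The statistical layer**: JZS-prior Bayes-factor mixed ANOVA (Cauchy
  scale 0.5, participant random intercept), one- and two-sided JZS t-test
  BFs, an approximate rank-based BF, maximum-likelihood ex-Gaussian RT
  models (mean = mu + beta), LexTALE scoring, and the arcsine transform —
  with `tidy()`/`glance()`/`autoplot()` methods throughout.

The model at the core of the detection step is simple threshold logic on
the reconstructed analog signal $a_k(t)$ of each response key $k$:

* RT $= \min\{t \le D : a_k(t) > .95 \text{ for some } k\}$ (deadline $D$),
* partial error $\iff$ both keys satisfy $a_k(t) > 0$ for some $t <$ RT,

with strict inequalities throughout and the exclusion and aggregation
rules layered above. The Bayes-factor ANOVA compares participant-only,
+condition, +item-type, and +interaction models under default g-priors by
seeded Monte-Carlo integration, reporting log BFs with Monte-Carlo error.

## Worked example

Simulate four virtual RT-CIT participants, process their logs, and test
for the conflict effect:

```r
library(partialpress)
library(dplyr)

sim <- simulate_experiment("CIT", n_participants = 4, seed = 42)
outcomes <- process_trials(sim$events, sim$trials)
attr(outcomes, "exclusion_counts")
#> starts_pressed    no_response       too_fast       too_slow          error
#>              8              4              0              0             31
#>   target_trial           none
#>            381           1976

summaries <- summarize_participants(outcomes)
summaries |>
  group_by(item_type) |>
  summarise(mean_rt = mean(mean_rt_ms, na.rm = TRUE),
            prop_partial = mean(prop_partial, na.rm = TRUE))
#> # A tibble: 3 × 3
#>   item_type  mean_rt prop_partial
#>   <chr>        <dbl>        <dbl>
#> 1 irrelevant    476.      0.00443
#> 2 probe         582.      0.0326
#> 3 target        NaN     NaN

bf <- jzs_mixed_anova_bf(summaries, dv = "mean_rt",
                         within_levels = c("irrelevant", "probe"), seed = 1)
tidy(bf)
#> # A tibble: 3 × 5
#>   model_a model_b  log_bf       bf  error
#>   <chr>   <chr>     <dbl>    <dbl>  <dbl>
#> 1 Fam     Null    -0.461     0.631 0.0170
#> 2 Main    Fam      7.67   2137.    0.0362
#> 3 Full    Main     0.0519    1.05  0.0489
```

Reading the output: probes are slower than irrelevants (simulated means
582 vs 476 ms) and show more partial presses (3.3% vs 0.4% of valid
trials); target trials are excluded from this analysis, so their summary
cell is empty. The `Main` vs `Fam` Bayes factor (~2000) is strong evidence
for the item-type effect; `Full` vs `Main` near 1 is no evidence for an
item-type × condition interaction. `plot_trial_trajectories()`,
`plot_participant_summaries()` and the `autoplot()` methods draw the
corresponding figures.

A command-line wrapper over the same functions is installed at
`inst/cli/partialpress.R`:

```sh
Rscript inst/cli/partialpress.R simulate --task cit --participants 2 --seed 7 --out run1
Rscript inst/cli/partialpress.R report --task cit --out run1
```

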