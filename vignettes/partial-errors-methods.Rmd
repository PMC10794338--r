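---
title: "Measuring partial errors with analog keyboards: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring partial errors with analog keyboards: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(partialpress)
library(dplyr)
```

## The measurement problem

Response conflict — two response channels activated at once — is central to
speeded paradigms such as the reaction-time Concealed Information Test
(RT-CIT) and the modified Sternberg task. Its most direct behavioural
signature is the *partial error*: the incorrect response key is partially
depressed and released before the overt, correct response is produced.
Electromyography detects such aborted activations but needs electrodes and
trained staff. Analog (hall-effect) gaming keyboards offer a cheap
alternative: every key reports a continuous depression value in $[0, 1]$,
polled at 1000 Hz.

`partialpress` implements the full measurement chain for this instrument:

1. **keystream** — reconstruct per-key analog trajectories from change-only
   event logs;
2. **trialproc** — extract response times and partial errors, apply the
   standard exclusion pipeline, and aggregate per participant;
3. **taskgen** — generate the RT-CIT and modified Sternberg designs exactly;
4. **simulate** — a generative model of analog trajectories with known
   ground truth;
5. **stats** — JZS Bayes-factor model comparisons, ex-Gaussian RT models,
   LexTALE scoring, and the arcsine transform.

## Signal model and detection rules

A change-only log records `(time_ms, key_id, value)` whenever a key's
polled value differs from the previous poll. Because nothing happens
between changes, the underlying signal is reconstructed exactly by
zero-order hold: the value is 0 before the first event and holds each
event's value until the next (right-continuous step interpolation,
`value_at()`). `densify()`/`sparsify()` convert between the event list and
the 1 kHz sample grid; for grid-aligned events the round trip is the
identity, which the test suite verifies property-style.

The detection rules are threshold logic with *strict* inequalities
throughout:

* **Response**: the earliest time at which either response key's value
  exceeds 0.95 within the deadline (1.5 s CIT, 2.5 s Sternberg). The 0.95
  threshold accommodates keys pressed at an angle that never quite reach 1.
* **Partial error**: both response keys exceed 0 at some time strictly
  before the response crossing. The two keys need not move simultaneously:
  the responding key is necessarily nonzero on its way to threshold, so
  the criterion effectively asks whether the *incorrect* key moved.
* **Starts-pressed**: any response key nonzero within the first 5 ms of a
  trial marks a carry-over press; such trials are excluded, and the guard
  window is closed (`t <= 5`).

Two deliberately fixed edge policies, where the measurement rules alone do
not decide: if both keys first cross the threshold in the same millisecond
sample, the key with the larger analog value at that sample is taken as
pressed, and an exact value tie is marked an error (a deterministic rule is
required for reproducible processing; the event is essentially measure-zero
for real hardware). Both the sparse event-list implementation and a
brute-force scan of the densified 1 kHz grid implement these rules; the
suite requires exact agreement between the two routes on more than 10,000
simulated trials.

## Exclusion pipeline and aggregation

Trials are excluded with a single reason each, assigned in fixed priority
order: `starts_pressed` → `no_response` → `too_fast` (RT < 200 ms) →
`too_slow` (RT > deadline bound) → `error` → `target_trial` (CIT
probe-vs-irrelevant analyses only) → retained. The fixed order makes
per-reason counts unambiguous even though published analyses report only
aggregates. Participant summaries (`summarize_participants()`) compute per
item type the retained-trial count, mean and SD of RT, and the proportion
of retained trials with a partial error; empty cells are reported as
missing, never as 0. The per-category performance filter drops a
participant when any category accuracy falls *strictly below* 60%;
accuracy of exactly 60% keeps the participant, reading "less than 60%"
literally.

## Task designs

The CIT design is fully determined: 5 information categories × 6 items
(1 probe, 1 target, 4 irrelevants), three practice blocks of 30 trials
(deadlines 10/1.5/1.5 s, feedback thresholds 10/1.2/0.8 s), and 20 test
blocks of 30 trials in which every item appears once per block — 600 test
trials (100 probes, 100 targets, 400 irrelevants). The response–stimulus
interval is drawn uniformly from [500, 1000] ms. Only the within-block
order and the target/irrelevant role assignment are random, both seeded.

The modified Sternberg test phase has 120 trials, 50% match in both
conditions, with 40%/10% (low validity) or 15%/35% (high validity)
intrusion/new trials. Cue color and the probe's serial position are
balanced *exactly* over match and over intrusion trials — all counts are
divisible at these sizes (e.g. 60 match = 2 colors × 3 positions × 10);
for ad-hoc trial counts the generator falls back to maximal evenness with
seeded remainder assignment, a choice documented here because the original
balancing rule for non-divisible counts is not specified. No word appears
more than once anywhere in a design. A purely familiarity-based responder
("YES iff the probe is in either list") is therefore correct on exactly
match + new trials: 60% (low) and 85% (high) — the package computes this
from the generated word lists, not from the trial-type labels, so the
check also exercises list construction. Practice blocks (2 × 10 trials)
reuse the condition's trial-type proportions at maximal evenness; their
composition is not otherwise specified.

## The generative model

The simulator is a first-class module: it produces change-event logs with
known ground truth so that every detection rule can be validated end to
end.

* **Latency.** The full-press (> 0.95) crossing time of the pressed key is
  drawn from an ex-Gaussian distribution per item type. Defaults reproduce
  the published group-level means: CIT probes near 583 ms versus
  irrelevants near 469 ms; Sternberg intrusion/new/match near
  1216/941/1094 ms. Latencies are truncated below at 100 ms so that the
  press onset always clears the 5 ms guard window; draws whose grid
  crossing falls after the deadline become no-response trials.
* **Kinematics.** Presses are piecewise-linear: a rise over 60 ms, a short
  plateau, and a 40 ms release. Only crossing times and nonzero support
  matter to the threshold logic, so the simplest shape with a controllable
  crossing time suffices.
* **Partial errors.** With an item-type-specific probability, the incorrect
  key receives a triangular sub-threshold pulse. Amplitudes are uniform on
  [0.05, 0.6] and durations on [40, 120] ms — placeholder ranges, since no
  empirical distribution of partial-press amplitudes is available — and the
  pulse is always contained in [6 ms, crossing − 2 ms], so an injected
  partial can never be flagged starts-pressed, never crosses the response
  threshold (amplitude cap strictly below 0.95), and is always detectable
  on a responded trial.
* **Errors, omissions, carry-overs.** Error trials swap the key roles;
  no-response trials leave both keys below threshold; starts-pressed
  trials receive a small blip within the first 5 ms. Default error rates
  follow the published per-type exclusion fractions (e.g. the Sternberg
  task's 18%/17.5%/7.2% exclusions, 88% of which were response errors).
* **Reproducibility.** One top-level seed; per-participant design and
  trajectory streams are derived deterministically from it, and logs are
  byte-identical across runs.

Trajectories are laid out on the 1 ms grid and sparsified to change events,
exactly as the hardware records. What the simulator does *not* emulate:
finger-specific kinematic shapes, force/velocity profiles, drifting
baselines, or participants removing fingers from the keys. Passing
recovery tests therefore demonstrates correctness of the detection and
aggregation logic under the stated generative assumptions, not robustness
to every artefact of real recordings.

## Statistical layer

**Bayes-factor mixed ANOVA.** The participant-level analyses compare four
models on a 2 (item type, within) × 2 (condition, between) — or 3 × 2 —
layout: participant-only, + condition ("Fam"), + item type ("Main"),
+ interaction ("Full"). The implementation follows the default g-prior
construction for ANOVA designs: factor effects are coded with orthonormal
sum-to-zero contrasts and receive zero-mean Gaussian priors whose scale
parameter `g` carries an inverse-gamma(1/2, r²/2) prior — equivalent to a
Cauchy with scale r on standardised effects — with r = 0.5 for fixed
batches (the published prior choice) and r = 1 for the participant batch.
The grand mean and error variance carry Jeffreys priors and are integrated
analytically; the remaining low-dimensional g-integral is evaluated by
seeded Monte Carlo (default 10,000 draws) with the marginal computed
through a Woodbury-reduced determinant/quadratic form, and the MC standard
error is reported alongside each log BF. Exact numerical parity with any
particular software release is not promised; parity is with the stated
model, and the test suite checks agreement within ±0.1 log units against a
separate high-effort oracle that integrates the dense n × n covariance
directly. Location shifts of the dependent variable and participant
relabelings leave the BFs unchanged (checked property-style), and under
null simulations the within-effect BF favours the smaller model in the
median over 50 replicates.

**JZS t test.** One-sample/paired BFs are computed by adaptive quadrature
of the noncentral-t marginal over the Cauchy(0, 0.707) prior; one-sided
variants truncate and renormalise the prior. The suite checks 3
significant-figure agreement with a dense-grid trapezoid oracle and the
identity that the two one-sided marginals average to the two-sided one.

**Rank-based BF.** The Bayesian analogue of the Wilcoxon signed-rank test
is implemented by latent-normal data augmentation: latent Gaussian values
constrained to the observed signed ranks are Gibbs-sampled with the effect
size, and the BF follows from a Rao-Blackwellised Savage–Dickey ratio at
zero. The exact construction behind the published rank-based BFs is not
specified, so this sampler is labelled approximate throughout; it is
seeded, run as two chains, and reports their half-difference as its error.

**Ex-Gaussian RT model.** The trial-level distributional model
(`rt ~ item type * partial` on the Gaussian location, additive effects on
log sigma and log of the exponential mean) is fitted by maximum likelihood
rather than MCMC — a deliberate scope decision; the full Bayesian sampler
configuration of the original analysis is treated as out of scope and the
penalised-likelihood fit as its supported analogue. The per-cell variant
(independent MLE per item-type × partial cell, moment-based starts, BFGS
on log-linked scale parameters, delta-method SEs) is the primary,
always-available route and requires 50 RTs per cell. The hierarchical
variant adds Gaussian random intercepts (participant, information
category) on the location and maximises the penalised likelihood, updating
the random-effect SDs by an EM-style recursion; it is an approximation and
flags non-convergence rather than failing silently. Recovery at n = 10,000
from (mu 500, sigma 50, beta 100) lands within 3 standard errors, and the
moment identities mean = mu + beta, variance = sigma² + beta² hold on
converged fits.

**LexTALE and arcsine.** The proficiency score is
((2.5 × words correct) + (5 × nonwords correct))/2 with strict > 70
inclusion; the arcsine-square-root transform is available as the
robustness option for proportion ANOVAs, with untransformed proportions as
the primary analysis (the transform is described only as a robustness
check in the source analyses).

## Numerical and design choices

* Times are real-valued milliseconds; the canonical grid is 1 ms (1000 Hz).
* Response keys are configuration, not hard-coded; defaults are "e"
  (NO, dominant hand) and "i" (YES).
* Trial-relative time is anchored at stimulus onset = 0 by construction of
  the log format.
* RTs are standardised on the analog > 0.95 crossing (the alternative —
  OS-level key events — is not available in analog logs), so simulated and
  extracted RTs are directly comparable.
* Degenerate inputs fail loudly: zero-variance t-test inputs, unbalanced
  ANOVA tables, missing filter categories, malformed or non-monotone event
  logs (reported with file line numbers), and all-equal RT samples (a
  non-convergence flag).
* Problem sizes in the test suite (e.g. 17 × 600 trials for the dual-route
  detection check, 10 × 35-participant replicates for rate recovery,
  60,000 Monte-Carlo draws for oracle comparisons) were chosen to give the
  checks real statistical teeth while keeping a full run in the
  minutes range on a single core.

## Known limitations

* The partial-press amplitude/duration distributions are placeholders; any
  conclusion sensitive to their shape needs real calibration data.
* The rank-based BF is a labelled approximation, not a validated
  reimplementation of any specific published procedure.
* The hierarchical ex-Gaussian fit maximises a penalised likelihood; its
  random-effect SDs are not REML-quality estimates and no SEs are reported
  for that variant.
* The ANOVA BF integrates by prior sampling, which loses efficiency for
  overwhelming evidence (very large |log BF|); the reported MC error makes
  this visible.
* Group testing artefacts of real keyboards (finger off key, baseline
  drift, angled presses below 0.95) are outside the generative model.
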