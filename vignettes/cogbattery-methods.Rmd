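---
title: "Smartphone cognitive testing: battery structure, simulation model and validation analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smartphone cognitive testing: battery structure, simulation model and validation analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogbattery)
```

## The problem this package addresses

Longitudinal dementia-prevention research needs repeated measurements of
cognitive function in large cohorts, but conventional neuropsychological
examination is too burdensome to administer often. A pragmatic alternative is
a battery of short cognitive tests delivered on the participant's own
smartphone, triggered by scheduled reminders over months of follow-up.
Evaluating such a battery raises three statistical questions:

1. **Feasibility** — do participants actually perform the tests when
   reminded (adherence)?
2. **Relative validity** — does the smartphone test rank participants the
   way the established clinic-administered test does?
3. **Practice effects** — do scores drift with repeated administration, and
   how fast?

`cogbattery` implements the full chain: stimulus generation and scoring for
five smartphone-adapted tests, the reminder calendar and its adherence
statistic, a synthetic-respondent simulator, and the validation analytics.
Because real cohort data cannot ship with a package, every analysis is
exercisable end to end on simulated data whose generating model matches the
assumptions of the analyses.

## The five test engines

Each engine produces a *stimulus specification* (no rendering) and scores an
*event log*; both serialize to JSON (`write_stimulus_json()`,
`write_sessions_jsonl()`).

* **Word-recognition memory** (`generate_word_memory()`): 10 studied words,
  then a 20-item recognition list mixing the 10 studied with 10 new words;
  scoring counts yes-on-old plus no-on-new, so correct + incorrect = 20.
  The bundled pool holds 50 common concrete nouns; any pool of at least 20
  distinct words can be substituted — scoring is content-agnostic. The
  presentation pace (default 2 s/word) is metadata only.
* **Trail making** (`generate_trail_part()`): 12 labelled circles placed by
  rejection sampling in the unit square. Part 1 is 1–12, part 2 is A–L,
  part 3 alternates ascending (1-A-2-B…), part 4 alternates numbers
  ascending with letters *descending* (1-Z-2-Y…), a harder variant added
  against ceiling effects in cognitively healthy samples. Scoring walks the
  tap log: the completion time is the last correct tap minus display time;
  a wrong tap is an error and, by default, does not advance the trail (the
  conventional convention — a flag enables the alternative where an error
  consumes the target). Duplicate taps in one frame collapse to the first.
* **Stroop** (`generate_stroop_panel()`): three 30-item multiple-choice
  panels — colour names in black, coloured blocks, and colour names in a
  conflicting ink (always incongruent; requires at least two colours). Every
  item offers the full colour set (default 4) as options. Completion time
  per panel plus correct/incorrect counts; a `below_half_correct` flag feeds
  the mistake-filtered sensitivity analysis.
* **Reaction time** (`generate_reaction_trials()`): part 1 is simple
  reaction to a box turning blue after a uniform 1–3 s delay; part 2 is
  go/no-go with a configurable blue fraction (default 0.7). Exactly one
  (blue) trial per administration is the enlarged *startle* probe, whose
  latency is reported separately. Touches before the cue are flagged
  anticipatory and excluded from the latency mean; touches on red trials
  are commission errors.
* **Letter n-back** (`generate_nback()`): levels 0–3 with fixed sequence
  lengths 11, 11, 15 and 20. Level 0 targets the letter X; level *n*
  targets positions whose letter equals the letter *n* back. Targets are
  planted (defaults 3/3/4/5, roughly 30% of scorable positions) and the
  finished sequence is re-scanned against the n-back definition, so no
  accidental targets can occur. Scoring decomposes touches into hits, false
  alarms, misses and correct rejections.

All generators are bit-reproducible under a fixed seed; internal timing is
milliseconds, with completion times reported in seconds and reaction
latencies in milliseconds (the units in which such tests are conventionally
reported).

## Reminder calendar and adherence

`build_schedule()` embeds the study calendar: each test is offered four
times, spread over the 26-week follow-up, staggered so that at most one test
is due in any week (memory-word on days 1/29/99/169 through letter-n-back on
days 15/85/155/173). A reminder is *adherent* when at least one completed
session of that test falls within one week of it. Two deliberate choices:

* **Window semantics.** "Within 1 week" is the half-open interval
  $[r, r+7)$ by default: unambiguous, and the natural reading of "within"
  for day-resolution data. The closed interval $[r, r+7]$ is available via
  `window_closed = TRUE`, and the boundary day $r+7$ is asserted under both
  semantics in the tests.
* **One session, one reminder.** Sessions are assigned greedily to
  reminders in calendar order, so a single session can never satisfy two
  overlapping windows. A session between windows counts toward the separate
  "ever performed" fraction (`ever_performed_fraction()`) but toward no
  reminder.

Mean adherence per participant pools the participant's per-reminder
indicators across all tests. If a supplied configuration lists offsets, they
replace the calendar wholesale (scheduling only one test must not silently
retain the others); offsets must be strictly increasing, at least four per
test, and within the 182-day horizon.

## The synthetic-respondent model

The simulator is a statistical responder, not a cognitive model: its purpose
is to generate data with exactly the structure the analyses assume, with
known ground truth.

A single latent general ability $a_i \sim N(0, 1)$ drives all instruments.
For the timed tests (trail making, Stroop), the completion time of
participant $i$ on part $p$ at attempt $k$ is

$$ t_{ipk} = \mu_p + \sigma_b z_i - \lambda a_i + \beta_i (k - 1) +
\varepsilon_{ik}, \qquad \varepsilon_{ik} \sim \mathrm{LogNormal}(\mu_\varepsilon, \sigma_\varepsilon), $$

with a between-person speed factor $z_i \sim N(0,1)$ and a per-participant
practice slope $\beta_i \sim N(\beta, \sigma_\beta^2)$. Defaults (see
`default_population()`):

* base times 20–55 s per part, between-person SD 6 s, ability loading 5 s
  per SD of ability — moderate-size individual differences typical for
  timed attention tasks;
* practice slopes $\beta = -1.8$ s/attempt on the trail test and
  $-0.93$ s/attempt on the Stroop, with random-slope SD 0.5 — practice is
  applied to the two timed tests only, since recognition memory, n-back and
  reaction speed are typically stable under repetition in cognitively
  healthy adults;
* per-attempt noise additive lognormal with median 6 s and
  $\sigma_\varepsilon = 0.6$ (SD ≈ 4.8 s): times are positive and
  right-skewed, and this magnitude corresponds to the moderate test–retest
  reliability seen for such tests. The lognormal's positive mean only
  shifts the intercept, never the slope.

Item-based tests are binomial with logistic ability links; reaction latency
is multiplicative-lognormal around an ability-shifted mean. Adherence is
Bernoulli per reminder with probability $p_0 \cdot d^{\,w}$ in reminder week
$w$ ($p_0 = 0.68$, weekly decay $d = 0.99$, producing mean adherence near
60% that declines slowly over six months); 8% of participants draw a
uniform dropout day; self-initiated extra sessions arrive Poisson
(mean 0.5/test). Conventional baseline scores are
$c_i = \mu_c - \lambda_c a_i + N(0, \sigma_c^2)$ for the five conventional
measures (Stroop panels 1–3, trail making A and B).

**What the simulator does not emulate:** fatigue and time-of-day effects,
device heterogeneity, non-random (ability-related) dropout, floor/ceiling
compression of scores, and the heavy-tailed distribution of self-initiated
repeats seen in motivated volunteers. Tests passing on this model therefore
validate the *machinery* (scoring, selection rules, estimators) and the
qualitative patterns, not the numeric results of any real cohort — which is
also why the pipeline treats the published cohort values (≈60% adherence,
$\rho$ up to ≈.6) as patterns to recover, never as targets.

## Validity and agreement analytics

`spearman_rho()` computes the correlation of mid-ranks (average ranks for
ties — the conventional definition) with the large-sample t approximation
for the p-value; an exact permutation p-value (delegated to
`stats::cor.test`) is offered for $n \le 10$ without ties. The test suite
checks the implementation against an independent $O(n^2)$ rank oracle to
1e-12, including tied data.

Three selections of the smartphone score are correlated with the
conventional baseline (`validity_report()`):

* **first attempt** — the estimate most affected by first-use difficulties;
* **mean of all attempts** — averaging independent per-attempt error
  strengthens the correlation in expectation, a directional property the
  suite verifies by replicated simulation (sign test, $\alpha = 0.01$);
* **mistake-filtered** — the earliest attempt with at least half the items
  correct (boundary inclusive: 15/30 qualifies); participants with no
  qualifying attempt are excluded, not errored.

Pairing between smartphone parts and conventional measures is a
configuration map (`default_pairing()`): Stroop panels pair one-to-one;
for trail making the default maps smartphone part 1 to conventional part A
("numeric") and part 3 to part B ("alphanumeric"), since part 3 is the
ascending alternating variant that corresponds to the conventional B form.
Missing data are handled by pairwise deletion throughout.

Because the two instruments score on different scales, agreement uses
z-scores: `bland_altman()` standardizes both vectors over the matched pairs
and reports differences against means with limits of agreement
$\bar d \pm 1.96\, s_d$. The mean difference is 0 by construction of the
z-scoring — the plot diagnoses *pattern* (trends of disagreement across the
score range), not calibration offset.

## The practice-effect model

`fit_learning_trend()` fits

$$ y_{ik} = (\beta_0 + u_{0i}) + (\beta_1 + u_{1i})(k - 1) + e_{ik}, \qquad
(u_{0i}, u_{1i}) \sim N(0, \Sigma), $$

by REML (lme4/lmerTest) with an unstructured 2×2 random-effects covariance —
the standard mixed-model formulation of a subject-specific learning curve.
Choices worth stating:

* the attempt index is centred at the first attempt, so $\beta_0$ is
  first-attempt performance;
* REML is the default (unbiased variance components); ML is a flag;
* p-values for the fixed slope use Satterthwaite degrees of freedom;
* `random_slope = FALSE` drops the random effects and reduces exactly to
  ordinary least squares — the tests assert this equivalence;
* non-convergence raises a classed `fit_failure` with the optimizer
  messages; designs where every participant has a single attempt raise
  `degenerate_design`.

`repeat_effect_report()` runs the fit per test part on everyone and again on
the subset with at least `min_attempts` (default 9) attempts — the selective
dropout sensitivity analysis. Cells whose mixed model is unidentifiable
(too few observations for the random effects, as happens in small subsets)
are reported as `NA` rows rather than aborting the report.

## Numerical and degenerate-input choices

* Rejection sampling for trail layouts is capped at 10,000 attempts; an
  infeasible geometry (e.g. radius 0.4) raises `layout_infeasible` rather
  than looping.
* All randomness flows through explicit `rng_seed` arguments; the caller's
  RNG state is never disturbed. Seeds derived internally stay below
  $2^{31}$.
* Timed scores are floored at 0.5 s in the simulator so extreme ability
  draws cannot produce negative times.
* Constant vectors raise `undefined_correlation` /
  `undefined_standardization` instead of returning `NaN`.
* Empty tap/touch logs are incomplete sessions; duplicate taps within one
  timestamp collapse to the first.

## Verification strategy and problem sizes

The package's own calibration checks are replicated simulations chosen to
run comfortably on one CPU: slope recovery uses 200 replicates of 150
participants × 6 attempts (the fixed slope must fall within 3 Monte-Carlo
SEs of the planted −1.8 s/attempt, and null-slope p-values must be
approximately uniform); validity calibration tunes the conventional noise SD
by root finding on a 200,000-draw Monte-Carlo estimate of the population
Spearman correlation (`calibrate_conventional_noise()`), then verifies the
mean first-attempt correlation over 200 cohorts of n = 146 and the
mean-over-first improvement by sign test. The determinism contract (two
pipeline runs under one seed produce byte-identical files) is asserted on a
60-participant configuration; the property is size-independent.

## Known limitations

* The engines emit stimulus specifications and consume event logs; there is
  no rendering, so presentation-level effects (screen size, touch accuracy)
  are out of scope by design.
* No normative scoring or clinical cut-offs are provided; scores are raw.
* The adherence model treats reminders as calendar events; notification
  delivery failures are not modelled.
* Criterion validity against actual cognitive decline cannot be assessed on
  synthetic data and is outside the package's scope.
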