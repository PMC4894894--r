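---
title: "Simulating and analysing a two-task implicit-learning experiment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing a two-task implicit-learning experiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`implearn` implements the computational machinery of an implicit-learning
study that pairs a *dynamic system control* (DSC) task — the classic sugar
factory — with an *alternating serial reaction time* (ASRT) task, including
an inclusion/exclusion generation test and a weighted-choice questionnaire.
Because no raw participant data from such studies are publicly deposited,
the package ships a synthetic-participant generator as a first-class,
tested module: every downstream stage (scoring, screening, awareness
classification, chance calibration, inference) can be exercised against a
known ground truth.

```{r}
library(implearn)
cohort <- generate_cohort(seed = 42)
bundle <- run_pipeline(cohort, seed = 7)
```

## The sugar-factory task

The participant steers a hidden first-order system. On trial $t$ the
production (tons of sugar) responds to the chosen workforce $W_t$ through

$$P_t = g\,W_t - P_{t-1} + e_t,\qquad e_t \in \{-1000, 0, +1000\},$$

with gain $g = 20$ tons per worker, the result clamped to
$[1000, 12000]$ tons, and the three error values equiprobable. The goal is
a production of 9000 tons; a trial is *on target* when
$|P_t - 9000| \le 1000$, inclusive at both endpoints (the band is stated as
8000–10000, and target hits are conventionally coded as $\pm 1000$ around
the goal, which an exclusive band would contradict). The workforce is
entered on a circular 12-value grid (100–1200 in steps of 100, wrapping at
the ends), and the counter's starting value is re-randomized uniformly over
the whole grid on every trial. Sessions comprise 5 blocks of 20 trials;
only the first 19 trials per block enter scoring, reproducing the logging
truncation of the original protocol (`recorded_trials_per_block` restores
the untruncated variant). Clamping is applied after the error is added; the
protocol statement gives no ordering, and for this parameterisation the
choice only matters in states where the raw value leaves the limits, which
are never on target either way.

Two structural facts anchor the chance model. First, the thousand-ton grid
is closed under the clamped update law, so the production state is a
12-state Markov chain under random responding. Second, the one-trial
on-target probability resolves by the parity of the previous production:
5/36 from odd-thousand states, 4/36 from even ones. `dsc_chance_exact()`
propagates the chain from the displayed initial state (6000 tons — the
protocol does not state which start its own simulation used; this
convention reproduces the published chance level) and gives 2.363 expected
on-target trials per 19-trial block; the 10,000-replicate Monte-Carlo
estimate of `dsc_chance_simulation()` agrees within sampling error and
reproduces the published 2.38 to within its standard error of about 0.015.

After every trial the participant rates confidence that the production will
fall in the band, on an ordinal 1–6 slider. We require a rating on every
recorded trial (the original interface forced a fresh rating before the
next trial could start, so skipped ratings should not occur in conforming
logs).

## The ASRT task

Four screen positions are numbered left to right. Targets alternate between
a fixed cycle over the positions — 4, 3, 2, 1 — and random positions
(`4 r 3 r 2 r 1 r`), which makes the regularity hard to notice. Each of the
10 blocks starts with 8 random warm-up trials followed by 200 alternating
trials (2080 trials per session); the cycle's starting phase and whether
the first alternating trial is pattern or random are drawn uniformly per
block. Targets occur in every position with equal frequency: the generator
balances the random-trial multiset exactly within each block, warm-up
included, so each position appears exactly 52 times per block. (Whether the
original balancing included the warm-up trials is not stated; including
them keeps whole-block balance, and none of the chance quantities depend on
the choice.) Trial types are recorded as construction metadata and never
inferred from the data. No response–stimulus interval is modelled.

### Triplets

For analysis, position sequences are reduced to overlapping windows of
three. A window is *pattern consistent* when its third element is the
cyclic successor of its first (the forms 4-r-3, 3-r-2, 2-r-1, 1-r-4),
a *repetition* when all three elements are equal, a *span* when it has the
x-y-x shape, and *inconsistent* otherwise. The precedence repetition →
span → pattern-consistent is stated for clarity; under any pattern that
visits each position once the positive categories cannot overlap, because
no position is its own successor. Exhaustive enumeration of the 64 ordered
triples gives 25.0% pattern-consistent, 18.8% span, 6.2% repetition and
50.0% inconsistent (percentages rounded half-to-even to one decimal, which
maps the exact 6.25 to the conventionally printed 6.2).

On the stimulus stream itself, windows that start and end on pattern trials
are pattern consistent *by construction* (about 48% of windows), and
windows starting on random trials are consistent at the 25% chance rate;
the total lands at about 61%, which `asrt_stream_triplet_expectation()`
reproduces by simulation. Stream triplets are coded on stimulus positions,
warm-up included, ignoring response correctness — the composition of the
presented stream is a property of the stimuli, not of performance.

### Generation task

Under inclusion instructions the participant generates an 80-position
sequence resembling the learned material; under exclusion instructions they
must avoid it. Runs of one position longer than three are silently
rejected (`constrain_generation_input()`). An 80-position sequence yields
78 triplets; above-chance pattern-consistent proportions under *exclusion*
indicate knowledge that is expressed automatically rather than under
conscious control.

## The synthetic cohort

`agent_profile()` stipulates a participant's behaviour; archetypes plant
the cases the screening stage must detect. The defaults are the study
conditions and are not tuned per analysis:

* **DSC learning.** The inversion learner applies $W^\* = (9000 +
  P_{t-1})/20$ (nearest grid value, ties resolved downward by `which.min`)
  with probability $q_b = 0.08 + 0.04(b-1)$ in block $b$, otherwise
  responding at random. This yields roughly 2.9 rising to 4.8 on-target
  trials per block, matching the published order of magnitude (2.89 in the
  first block, above 4.26 in the last three). A perfect inverter is on
  target with probability 1 from odd-thousand states and 2/3 from even
  ones.
* **ASRT speed.** Trial RT is `530 − 7·(block−1) − advantage(block)·[pattern]`
  ms plus ex-Gaussian noise (Gaussian SD 20 ms plus an exponential with
  scale 60 ms, floored at 150 ms), with the pattern advantage growing
  linearly from 0 to 10 ms across blocks. Baselines and gains sit in the
  published descriptive range (first-block means near 530–545 ms falling to
  the 440–480 ms range, final-block pattern–random differences of 5–10 ms).
  The positively skewed noise family is a stipulation — RT distributions
  for these participants were never published — and is configurable.
* **Accuracy.** Error probabilities of 0.04 (pattern) and 0.055 (random)
  give the ~96%/94% accuracy split. A negligent agent answers one block
  with error probability 0.6, guaranteeing detection by the 75% screen.
* **Awareness.** Aware-DSC agents add 1.5 confidence points (before
  ordinal rounding/clipping with noise SD 0.8) on on-target trials; unaware
  agents rate independently of outcome. Aware-ASRT agents allocate 5–9 of
  the 12 questionnaire points to the sequence aspect, unaware agents 0–4.
* **Generation.** At every second slot the agent emits the successor of
  the position two back with probability `generation_knowledge` (default
  0.16, which puts the inclusion proportion near the published 0.31);
  under exclusion it suppresses that successor with probability
  `exclusion_control` (default 0.1) and otherwise applies the regularity
  automatically.
* **Response bias.** The anchored policy moves a Poisson-distributed
  number of circular steps (mean `anchor_strength`, default 0.8 for the
  planted archetype) from the randomized start value, landing well below
  the mean-change-of-2 exclusion threshold; independent responding has an
  exact expected change of 3 steps.

The default demo cohort (33 participants per condition) plants 8/5
anchored, 7/2 negligent, 3/6 outcome-coupled-confidence and 2/4
questionnaire-aware agents in the single/multiple conditions, mirroring the
published exclusion and awareness counts. In the multiple condition each
day contributes 1 DSC block and 2 ASRT blocks (five consecutive days); the
split is configurable since only the total exposure is fixed by design.
Session tags are metadata: the simulator programs no consolidation,
fatigue or circadian structure, so passing tests say nothing about whether
*real* distributed practice alters learning — they validate the
measurement pipeline, not the psychology.

## Screening and awareness criteria

All boundaries are strict as specified: mean circular change < 2 excludes
(exactly 2 is retained); any block below 75% pooled accuracy excludes
(exactly 75% is retained); at least 5 questionnaire points classify as
aware. The per-participant Welch test is one-sided — the criterion is
being *more* confident on on-target trials — and pools trials across
blocks, deliberately ignoring practice effects. With fewer than two
ratings in a group, or zero variance in both groups, the test is reported
as not classifiable rather than silently aware or unaware; how such ties
were originally handled is unstated, so this is a stipulation. Participants
are excluded independently per task, and the analyses are re-run with aware
participants removed as a robustness check whose outputs keep the same
structural shape.

## Inference

`mixed_anova()` is a split-plot engine for up to one between-subjects and
two within-subjects factors: the participant-by-cell response matrix is
projected onto orthonormal within-effect contrasts, each stratum is tested
against its own error with Type III sums of squares (sum-to-zero coding, so
hypotheses concern unweighted marginal means under unequal group sizes —
interactions were expected in this design, hence Type III). Per stratum
with more than two levels, Mauchly's statistic and the Greenhouse–Geisser
epsilon are computed from the eigenvalues of the stratum error covariance;
degrees of freedom are rescaled by epsilon when Mauchly's p < 0.05 (the
correct-when-violated reporting convention). Generalized eta squared treats
the session factor as observed: effects containing an observed factor
contribute their sum of squares to every denominator. The engine is matched
against `car::Anova` (an independent Type III implementation) to 1e-6 on a
fixture in the test suite, and its type-I error is calibrated on null data.
Participants with any undefined cell — e.g. an undefined on-target
confidence mean — are dropped case-wise with a warning.

Tukey's HSD uses the studentized range with the Tukey–Kramer standard error
for unequal cells; with two cells it reduces to the unadjusted two-sided
t-test. Pearson correlations and Pearson chi-square (no continuity
correction by default) round out the published analysis set.

### Cross-task indices

Learning is summarised per participant as the final-block random/pattern
median-RT ratio, the cumulative random-minus-pattern RT difference, the
cumulative successive-block ratio difference (telescoping exactly to last
minus first ratio), the mean trials on target, and the cumulative
successive-block on-target difference. A caution established with
`simulate_ability_cohort()`: even with a strong shared latent ability
(latent correlation 0.6), the recovered index correlation is attenuated to
roughly 0.3, because a single session's final-block median-RT ratio has
limited reliability (median standard errors of ~8 ms per trial type against
programmed advantages of at most 25 ms). Small observed cross-task
correlations are therefore compatible with a substantial shared ability —
a measurement limitation inherent to the index, not a simulation artifact.

## Numerical conventions and problem sizes

Degenerate inputs fail loudly: off-grid worker values, out-of-range
productions, sequences shorter than three positions, questionnaires not
summing to 12, zero-variance correlations and empty contingency margins
all raise errors naming the violated constraint. Stochastic functions take
explicit seeds and are bitwise reproducible; enumeration results are
seed-free. The generation sampler escapes a blocked deterministic proposal
by drawing uniformly among admissible positions, so it cannot stall when
knowledge is 1.

The shipped tests and the acceptance script use sizes chosen to put Monte-
Carlo error well inside the asserted bands on a single CPU: 10,000
replicates for the DSC chance level (SE ≈ 0.015 trials), 1000 blocks for
the stream composition (SE ≈ 0.05 points), cohorts of 50–100 agents per
planted class for screening sensitivity/specificity, 100 agents for
advantage recovery, cohorts of 120 for correlation recovery, and 500
replicates for type-I calibration.

## Limitations

The agent families are stipulations, not fits: no published trial-level
human data exist to estimate them, so recovery results demonstrate internal
consistency of the pipeline, not behavioural realism. Published group-level
F statistics from the original human sample are out of reach without those
data and are deliberately not reproduction targets; the inference stage is
instead validated by oracle fixtures and calibration. High/low-frequency
triplet contrasts used by other ASRT designs are out of scope.
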