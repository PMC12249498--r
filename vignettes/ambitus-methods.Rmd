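---
title: "Scoring, simulating and analyzing corridor-maze behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, simulating and analyzing corridor-maze behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ambitus)
```

## The experiment this package models

The Ambitus maze is a rectangular Plexiglas corridor with four segments,
each carrying two inner and two outer side boxes (16 in total) and a
midpoint infrared sensor. A food-restricted rat is released at a corner
and explores freely for 300 s while beam-breaks record, at 1 ms
resolution, corridor-midpoint crossings, box entries/exits and reward
consumption. Three baiting tasks are used: all 16 boxes (task 1, the
symmetric task), only the 8 inner boxes (task 2), only the 8 outer boxes
(task 3). A study consists of five phases: a pre-treatment day with two
all-baited and two inner-baited trials, then — after a treatment period —
sixteen trials over four days (2 all-baited, 6 outer-baited, 8
inner-baited). `make_schedule()` encodes exactly this plan; `task_config()`
the baiting sets.

Two conventions in the static model deserve a note, because the study
design leaves them implicit:

* **Task 3 baits the outer boxes.** The outer-baited task is the natural
  complement of the inner-baited one and matches the "EX" (external)
  phase naming; nothing else in the design is consistent with an
  asymmetric third task.
* **"Entries into the corridors" are midpoint-sensor crossings.** The
  midpoint beam is the only corridor-level sensor in the apparatus, so
  locomotion and skipping counts are defined over its events.

## The eleven behavioral parameters

`score_trial()` computes, per trial: locomotion `loco`, exploration
`expl`, exploration frequencies `expl_fr_rw`/`expl_fr_nrw` (counts of
rewarded/non-rewarded box visits up to the collection of all rewards,
scaled by 300/Eat_T), latencies `lat_rw`/`lat_nrw` (s), `skipping`,
adequate exploration `a_e`, learning capacity `l_c`, working memory `w_m`
and reference memory `r_m`. `Eat_N` is the number of rewards consumed;
`Eat_T` is the time of the last reward when all were collected.

Boundary conventions, fixed once and tested:

* **Censoring.** If not all rewards are collected, `Eat_T` is the full
  300 s window. This makes `l_c = Eat_N / n_rewards × 100` in the
  incomplete case — the score degrades gracefully to the fraction
  collected. A latency with no qualifying visit is likewise censored at
  300 s.
* **Closed windows.** "Up to Eat_T" and "up to 5 min" are closed
  intervals (timestamp ≤ bound), so the visit that consumes the final
  reward counts in the rewarded-visit tallies, and an event at exactly
  300 s is inside the trial.
* **Skipping** counts corridor crossings strictly before the first box
  entry of any kind. The defining formula (entries before the first
  exploration) is used rather than the looser "corridors walked without
  exploration" gloss sometimes attached to the concept; the two disagree
  on corridor passes between explorations, and only the former is an
  explicit calculation rule.
* **Undefined ratios stay missing.** `w_m` with zero rewarded visits, or
  `a_e`/`r_m` on a trial without explorations, are 0/0 and are reported
  as `NA` with a reason code — never zero-filled. The four
  side-restricted parameters (`expl_fr_nrw`, `lat_nrw`, `w_m`, `r_m`)
  are `NA` by construction under the symmetric task, where "rewarded
  side" is not defined.
* Box visits are counted by `box_entry` events; exits are validated for
  ordering but no formula uses dwell time.

Every scoring run is backed by two invariants worth knowing:
`r_m` plus the non-rewarded visit share always equals 100 exactly, and
`w_m = 100` precisely when no rewarded box was revisited before
collection completed. The test suite also maintains an independent
brute-force scorer (a plain linear scan written before the
implementation) and requires exact agreement on a thousand simulated
trials per run.

## Phase normalization

The analyzed quantities are phase-level z-scores. `aggregate_phase()`
reduces each animal's trials within a phase to their mean (missing trials
ignored); this reduction is the conventional one and makes per-animal
phase values available to both ANOVA designs. `zscore_phase()` then
standardizes each (phase, parameter) cell over *all* animals pooled —
phase is the only stratifier — and flips the sign for latencies and
skipping, so a positive z always reads "more active / better
performing". The standard deviation is the sample SD (n−1); a
`sd_type = "population"` switch exists because "SD of the population" is
ambiguous between the statistical population and the divisor, and the
choice is a pure rescaling within each cell (z-scores are affine
invariant either way). Cells with zero spread or fewer than two values
are flagged and left missing rather than silently zeroed.

## The statistical battery

* `one_way_anova()` — classical between-groups F, delegated to `lm()`;
  mean squares are exposed so `fisher_lsd()` can reuse the pooled error.
* `mixed_anova_gg()` — split-plot design (between: group; within: phase)
  computed from a multivariate linear model with Type-III sums of squares
  and sum-to-zero contrasts (via `car::Anova`), which handles unequal
  group sizes correctly. Sphericity is assessed by Mauchly's test;
  the Greenhouse–Geisser epsilon is always reported and, under the
  default `gg = "auto"` rule, the corrected p-value is adopted when
  Mauchly's p < 0.05. "Where appropriate" has to be operationalized
  somehow; Mauchly-gating is the textbook rule, and `always`/`never`
  overrides are provided. With two within-levels sphericity holds
  trivially and epsilon is 1. Incomplete animals are dropped listwise
  with a warning — the classical univariate approach, chosen over
  mixed-model imputation deliberately: the battery mirrors what standard
  commercial packages compute.
* `fisher_lsd()` — unadjusted pairwise t-tests on the ANOVA error mean
  square. No multiplicity control is applied because that is the
  definition of LSD; consumers should treat the p-values accordingly.
* `unpaired_t()` — Student's pooled-variance form by default (the
  classical default of the software era this battery mirrors), Welch
  behind a flag.
* `exclude_outliers()` — single-pass mean ± 2 SD rule, not iterated,
  with mean and SD computed once from all values.

The test suite checks this battery against hand-computed ANOVA tables, a
textbook split-plot sums-of-squares oracle on balanced fixtures, the
F = t² identity, an exactly compound-symmetric covariance fixture (where
epsilon must be 1), and a 500-replicate null calibration in which the
empirical type-I error of every effect must sit within Monte-Carlo error
of α = 0.05. Note one subtlety: the GG correction is guaranteed to raise
the p-value only in the rejection region; for F below ~1 shrinking both
degrees of freedom can lower it, which is why the conservativeness check
is conditioned on p ≤ 0.1.

## Saturation binding

`specific_binding()` averages replicates within concentration and
subtracts nonspecific from total binding; `fit_one_site()` fits
B(L) = Bmax·L/(Kd+L) by unweighted Levenberg–Marquardt least squares.
The start heuristic is deterministic — Bmax₀ = 1.2 × the largest specific
value, Kd₀ the interpolated concentration at half Bmax₀ — so fits are
reproducible without randomness, and robust on saturating designs.
Specific binding is formed by subtraction *before* fitting (the named
one-site specific-binding model fits specific binding only), and the fit
is unweighted, matching that model's default. Fits with Kd beyond three
times the largest tested concentration are flagged poorly constrained.
Negative specific values are flagged and floored only at reporting.
Standard errors come from the estimate covariance; across independent
assay repeats the between-fit SEM is the other spread measure of
interest, and `compare_binding()` treats assay repeats (not duplicate
wells) as the experimental units for the pairwise pooled t-tests,
because independent repetitions are the defensible independence level.

`dpm_to_fmol()` implements the unit identity 1 Ci = 2.22 × 10¹² dpm, so a
ligand of specific activity SA Ci/mmol emits 2.22 × SA dpm per fmol;
counting efficiency divides the counts first.

## Densitometry and dose accounting

`normalize_densitometry()` computes (target − background)/(actin −
background) per lane, invalidates lanes with non-positive actin net OD,
and applies the 2 SD rule within group; group summaries are mean ± SEM
with SEM = sample SD/√n after exclusions. `compute_intake_dose()`
converts daily fluid records to mL/kg/day and multiplies by drinking-water
concentrations for per-drug mg/kg/day; days are averaged within animal
first, then animals within group — the averaging order is not dictated by
the quantities themselves, so it is fixed here and documented.

## The simulator: what it emulates, and what it does not

`simulate_trial()` is a discrete-event process on the corridor graph.
Inter-transition times are exponential with rate `move_rate` (the design
specifies no kinematics; the memoryless choice is the simplest process
with the right count/latency semantics). On each corridor pass the rat
may lapse (`lapse_prob`, suppressing exploration — this is what produces
skipping), otherwise explores a side box with probability `explore_prob`.
Under asymmetric baiting the baited side is chosen with probability
`baited_side_bias` (under the symmetric task side choice is uniform —
side memory is only measurable asymmetrically); on the baited side,
already-emptied boxes are avoided except with probability `revisit_prob`
(the working-memory failure knob). Entering a baited, non-empty box
consumes its single reward with probability `consume_prob`; each box
yields at most one reward per trial, eating and dwelling occupy
`dwell_ms` on average, and the stream ends at 300 s.

The baseline profile (move_rate 0.25/s, explore_prob 0.6, side bias 0.65,
revisit 0.3, consume 0.9, lapse 0.15, dwell 2 s) was chosen once to
produce trials in the realistic range for a motivated rat — on the order
of 60–80 corridor passes and 20–40 box visits per 300 s trial, with most
but not all rewards collected — and is not tuned thereafter. Group
effects are abstract multiplicative modifiers on the traits with
log-normal between-animal variability (CV 0.15 by default);
pharmacokinetics are deliberately out of scope. Randomness is controlled
by a single master seed with per-(animal, trial) sub-seeds derived by a
documented linear scheme, so cohorts are bit-reproducible.

What passing tests on simulated data *show*: the scoring formulas,
normalization, and statistical battery are correct and calibrated, and
designed trait effects propagate monotonically into the matching scored
parameters (more movement → higher locomotion; more lapses → more
skipping; stronger side bias → higher reference memory; more revisits →
lower working memory) with high power at cohort sizes of ten per group.
What they *do not* show: that real rats satisfy the exponential-move,
independent-choice process, or anything about real treatment effect
sizes. The simulator validates the analysis code, not the biology.

## Problem sizes and numerical choices

The routine test run uses cohorts of up to 10 animals per group over the
full 20-trial schedule, 1000 random trials for the oracle-equivalence
sweep, 500 replicates for the null-calibration study and 20 replicate
cohorts for the power study; these sizes give Monte-Carlo error
comfortably below the tested margins while keeping the suite quick.
Degenerate inputs are handled as data, not crashes: zero-variance ANOVA
cells, 0/0 scores, all-equal z-cells and non-converged fits each carry an
explicit flag, and validation reports list every violation rather than
stopping at the first.

## Known limitations

* The mixed ANOVA is the classical univariate split-plot; no linear
  mixed-effects alternative (and hence no principled handling of missing
  phases beyond listwise deletion).
* No robust (median/MAD) normalization variant.
* One-site binding only: no two-site, Hill or kinetic models.
* Densitometry starts from band optical densities; image processing is
  out of scope.
* Event streams are discrete sensor events; there are no trajectories,
  dwell-time analytics or video-tracking features.
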