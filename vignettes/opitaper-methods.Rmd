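---
title: "Methods: linear opioid tapering, rotation, tablet packing and consensus statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linear opioid tapering, rotation, tablet packing and consensus statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opitaper)
```

## The dosing model

All internal arithmetic runs in oral morphine equivalents (OME), mg per
24 h. A drug dose converts as `ome = dose_mg × factor(drug)` with the
factor taken from a loadable formulary, never hard-coded; oral morphine has
factor 1 by definition. Only the oral route is supported: parenteral and
transdermal conversion involve route-dependent bioavailability, and
methadone's conversion is dose-dependent (nonlinear), so both are refused
explicitly rather than approximated. The shipped `default_formulary()`
follows the 2016 edition of the CDC oral MME table (the 2022 revision
changes some factors, e.g. hydromorphone); the file's `version` field
records this, and users who need a different edition load their own file.
Doses remain exact reals throughout; rounding happens exactly once, in the
formulation mapper.

### Baseline and stabilization

The taper baseline is the patient's *total* consumption over the last
24 h, fixed plus back-up doses: back-up use is real consumption, and
excluding it would start the taper below the dose the patient actually
needs. Reduction begins only once the patient is stable on the regimen.
"Stable" is a qualitative clinical notion; `is_stabilized()` parameterizes
it as ≥ 48 h of stable pain (values below 24 h are rejected — the
clinically accepted window is 24–48 h), at most 2 back-up doses, and
back-up consumption at most 10% of the fixed dose per 24 h. All three
thresholds are arguments with these defaults.

### Linear reduction

The single most consequential design decision is that the per-step
reduction is a fixed fraction *of the post-stabilization baseline*, not of
the current dose. With baseline $B$, fraction $f$ and target $T$, the dose
after $r$ reductions is

$$D(r) = \max(B - r f B,\; T),$$

so the trajectory is a straight line: with $f = 0.25$ any baseline reaches
zero in exactly 4 steps, with $f = 0.10$ in exactly 10, and the number of
reductions is always $\lceil (B-T)/(fB) \rceil$. A fraction-of-current-dose
rule would decay exponentially and never terminate; the test suite asserts
explicitly that the dose after two reductions is $B(1-2f)$, not
$B(1-f)^2$, because that compounding variant is the most likely
mis-implementation. When $B - T$ is not a multiple of $fB$, the final step
is smaller so the plan lands exactly on the target — it clamps, never
overshooting below the target.

Day 0 is baseline establishment. The first reduction falls on day 1 for
both presets; subsequent reductions follow every `step_interval_days`
(2 for acute, 3 for chronic, giving reduction days 1, 3, 5, 7 and
1, 4, ..., 28 respectively). The gradual preset's first-reduction day is
not fixed by the clinical source material, which specifies only "every
third day"; starting it on day 1 keeps the two presets aligned and is
configurable via `first_reduction_day`.

The four shipped trajectory presets combine the two rates with an optional
discharge grace period: plan 1 (10%, no grace), plan 2 (10% + grace),
plan 3 (25%, no grace), plan 4 (25% + grace).

### Grace period

`apply_grace_period()` interprets the two-day discharge grace period as
"hold before continuing to reduce": every reduction scheduled strictly
after the discharge day is delayed by `grace_days`, so the dose in effect
at discharge is held longer and the tail of the schedule shifts rigidly.
The multiset and order of dose levels are invariant — only timing changes —
and a discharge after the last reduction leaves the plan untouched.
`plan_for_case()` also skips the grace step when the discharge day falls
beyond the plan's span, where it cannot affect any reduction.

### Tiered taper

For chronic users with an acute pain episode, the excess above the
maintenance dose is removed first: phase 1 uses the rapid policy with step
size `f × excess` (a fraction of the excess, keeping the phase linear and
4-step for f = 0.25) down to exactly the maintenance dose; an optional
phase 2 continues from there toward the chronic target under the gradual
policy. The concatenation is continuous at the boundary by construction.

### Back-up allowance

The back-up (rescue) dose is a constant fraction of the *initial* baseline
— the clinical guidance brackets it at 1/10 to 1/6 "throughout the
reduction process", which we read as constant rather than shrinking with
the fixed dose; fractions outside the bracket are rejected, not clamped.
The default is 1/8, the midpoint-ish value inside the bracket, chosen once
because the source gives a bracket, not a point. The allowance is dropped
on the day the fixed dose reaches the target.

## Rotation

`rotate_dose()` composes the two exact conversions and the scheme
fraction: `from_ome(to_drug, to_ome(from_drug, dose)) × c`. The three
shipped schemes (c = 0.30, 0.50, 1.00) reflect incomplete cross-tolerance;
the fraction is applied *before* any tablet rounding, so the mapper sees
the exact rotated dose. `build_rotation_plans()` generates one full taper
per scheme; switching schemes mid-course (`reanchor_plan()`) keeps the
history up to the switch day and regenerates the remainder from the dose
in effect that day, which keeps the trajectory continuous — the mechanics
of "switching plans by patient response" are not specified clinically, and
re-anchoring is the choice that never produces a dose jump.

## Formulation packing

`map_daily_dose()` searches unit combinations in order of increasing total
pill count and stops at the first feasible count, which therefore is the
minimum; feasibility means the achieved total deviates from the
prescription by at most `tolerance` (default 15% — the acceptable rounding
deviation is a documented choice, not a clinical constant, and is
configurable). Ties at the minimal pill count are broken by (a) preferring
an achieved dose at or below the prescription (under-dosing is the safe
direction when the goal is dose reduction), then (b) fewer distinct
strengths (fewer chances for intake errors), then (c) the most even mg
split across slots. The consequence — deliberate — is that an exact but
two-strength combination loses to a slightly-under single-strength one at
the same pill count. Infeasibility raises an error listing the nearest
achievable totals; the tool never rounds silently. The enumeration is
bounded at 8 units/day (beyond that pill burden is itself a barrier), and
an independent exhaustive oracle in the test suite confirms optimality on
randomized instances. Two safety guards: `single_strength` restricts the
search to one strength (simplified regimens for cognitively impaired
patients), and drugs available only as extended-release formulations
refuse slot layouts closer than 8 h apart. Administration slots use fixed
clock times (08:00/20:00 for two slots) rather than intervals, per patient
feedback incorporated into the handout design.

## Handout and readability

`render_handout()` is a deterministic Markdown renderer: per day it prints
the tablet intake at each clock time, the food instruction, and the
back-up allowance, preceded by a plain-language note that occasional pain
spikes are normal (and what the back-up is for) and a functional goal
line. It refuses plans with uncovered days rather than skipping them.

`count_text_units()` defines its counting rules exactly so scores are
bit-reproducible: sentences are `.`/`!`/`?`-delimited segments containing
at least one alphanumeric character, with a per-locale abbreviation guard
list (e.g. "z.B.", "Dr.") protected before splitting; words are
whitespace tokens that retain a letter or digit after punctuation
stripping; syllables are maximal vowel-letter runs (vowel sets `aeiouy`
for English, plus umlauts for German), which counts diphthongs once, with
the English silent final *e* subtracted (except after consonant + *l*, as
in "table") and a floor of one syllable per word. This is a heuristic —
no dictionary-free syllable counter is exact; vowel-hiatus words like
"Beamte" undercount — but it is deterministic, documented, and consistent
between drafts, which is what delta tracking needs.

Both score variants are implemented and the report always carries the
variant, because a bare score is uninterpretable: Flesch Reading Ease
(206.835 − 1.015·ASL − 84.6·ASW) and the German Amstad recalibration
(180 − ASL − 58.5·ASW). German text defaults to Amstad. Draft deltas
report absolute and percent changes with percent rounded to integers for
display.

## Consensus statistics

The consensus rule is deliberately two-part: an item reaches consensus
when the share of non-missing ratings at or above the agreement cut is
≥ 80% *and* the mean rating is ≥ 4.5 on the 7-point scale. The phrase
"≥ 80% per item" is ambiguous about what is counted; we count respondents
at or above an agreement cut, defaulting the cut to 5 (the first
clearly-agree scale point), with all three thresholds exposed as
arguments. Missing ratings are excluded from numerator and denominator
(pairwise deletion, never imputation).

Round-to-round stability is computed on unchanged items only — a reworded
item carries no test-retest information — by pairing item mean ratings
across rounds. Because the estimator behind a published "average
inter-rater reliability" is rarely identifiable, both routes are provided
and always named in the output: Pearson correlation of item means
(symmetric in round order), and ICC(A,1), the two-way single-measure
absolute-agreement intraclass correlation, computed from the ANOVA mean
squares with its standard F-based confidence interval (Satterthwaite
degrees of freedom for the denominator). The ICC implementation is
cross-checked in the tests against an independently computed reference
value on a fixed 10×8 table. The stability flag uses the conventional
≥ 0.70 cut. Degenerate inputs (fewer than 3 unchanged items, zero variance
on either side) raise errors naming the problem; a panel whose second
round exactly duplicates the first returns coefficient 1.0 under both
estimators rather than a division-by-zero artifact.

Intercoder agreement is the raw share of identically coded units;
the Brennan–Prediger coefficient corrects it for uniform chance over `q`
categories, $\kappa_{BP} = (P_o - 1/q)/(1 - 1/q)$ — the number of
categories must be supplied, since it is a property of the coding scheme,
not of the observed codes. As $q \to \infty$, $\kappa_{BP} \to P_o$, which
the tests assert numerically at $q = 1000$.

## Synthetic data generator

`make_patient_cases()` and `make_delphi_panel()` generate every input the
toolkit consumes, deterministically from a single seed (the caller's RNG
state is saved and restored). Patient cases mix acute/chronic pain and
naive/chronic-user status with 24-h baselines uniform on 20–120 mg OME —
the range typical of post-surgical inpatient regimens — split ~85–95%
fixed / 5–15% back-up, prehospital doses for chronic users at 10–60% of
the baseline, and a discharge day present in about half the cases. Delphi
panels draw planted-item ratings from {5, 6, 7} with probability
`consensus_strength` (default 0.95) and from {1..4} otherwise, non-planted
items with probability 0.3; round 2 copies round 1 on unchanged items with
a one-point symmetric perturbation at rate 0.1. Planted items are marked
unchanged and non-planted items reworded, mirroring how non-consensus
items are revised between rounds.

What the generator emulates is the *statistical structure the rules
assume* — mixtures of dose magnitudes, agreement concentrated above the
cut, small between-round jitter. What it does not emulate: correlated
rating styles between respondents, informative missingness, real
formulary market availability, or within-day dose timing. Passing tests
therefore demonstrate the algorithms' correctness on well-specified
inputs, not clinical performance on real patients.

## Problem sizes and determinism

The test suite and the acceptance script use 100–200 randomized instances
per property (baselines, packing instances, rotation formularies) and
panels of 10 respondents × up to 49 items — sizes at which the exhaustive
packing oracle (≤ 8 units over ≤ 4 strengths) is exact and the whole suite
runs in well under a minute. All stochastic checks fix their seeds;
`scripts/acceptance.R` derives every stream from its `--seed` flag.

## Known limitations

* Oral route only; no methadone, buprenorphine, or transdermal fentanyl.
* Syllable counting is heuristic (see above); scores are comparable
  between drafts counted with the same rules, not with other tools.
* The formulation mapper does not split tablets and does not check
  pharmacy stock; extended-release pharmacokinetics are reduced to a
  minimum-gap guard.
* The taper engine schedules doses, not symptoms: withdrawal monitoring
  and pain-score ingestion are out of scope.
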