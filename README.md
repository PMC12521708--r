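# opitaper

Individualized opioid taper (deprescribing) schedules for hospitalized
patients, plus the agreement and readability statistics used when such
deprescribing frameworks are developed by expert consensus.

## The problem

Opioids started in hospital for acute pain are too often continued after
discharge for lack of a concrete reduction plan. `opitaper` turns a
patient's last-24-hour opioid consumption into a day-indexed, strictly
**linear** dose-reduction schedule expressed in oral morphine equivalents
(OME):

* the starting dose is the total of fixed **and** back-up (rescue) use over
  the last 24 h, converted to OME via per-drug conversion factors
  (`dose_mg × factor`);
* each reduction removes a fixed slice `f × baseline` of the
  *post-stabilization baseline* — never a fraction of the current dose — so
  the schedule is linear: after `r` reductions the dose is
  `max(B − r·f·B, target)`. An acute-pain preset (`f = 0.25`, every other
  day) reaches complete cessation in exactly 4 steps; a chronic-pain preset
  (`f = 0.10`, every third day) in exactly 10;
* opioid-naive patients taper to zero, chronic users back to their
  prehospital dose; patients with chronic pain plus an acute episode get a
  two-phase (tiered) schedule that removes the excess above the maintenance
  dose first;
* a two-day **grace period** around hospital discharge postpones every
  later reduction without changing the dose levels;
* a back-up allowance of 1/10–1/6 of the initial dose (default 1/8) is
  carried until the target is reached;
* switching opioids applies incomplete cross-tolerance: the new drug starts
  at 30%, 50% or 100% of the equianalgesic dose;
* exact daily doses are packed into commercially available tablet
  strengths, minimizing pill count within a stated tolerance (default 15%)
  and preferring under- over over-dosing; deviations are reported, never
  hidden;
* a Markdown patient handout presents the plan with fixed clock times
  (08:00/20:00), food instructions and a functional goal.

The companion `consensus_stats` functions implement the Delphi consensus
rule (consensus when ≥ 80% of respondents rate an item at/above the
agreement cut *and* the mean rating is ≥ 4.5 on a 7-point scale),
round-to-round test-retest stability (Pearson on item means or ICC(A,1)
with F-based confidence interval; stable when ≥ 0.70), intercoder percent
agreement, the Brennan–Prediger coefficient
`κ_BP = (P_o − 1/q)/(1 − 1/q)`, and the Flesch Reading Ease /
Amstad (German) readability scores.

## Worked example

An opioid-naive patient with acute pain used 64 mg fixed plus 16 mg
back-up oral morphine in the last 24 h and is discharged on day 1:

```r
library(opitaper)
form <- default_formulary()
case <- patient_case(
  opioid_status = "naive", pain_type = "acute",
  last24h = list(consumption_entry("morphine", 64, "fixed"),
                 consumption_entry("morphine", 16, "backup")),
  discharge_day = 1L, pain_stable_hours = 48)
summary(plan_for_case(case, form))
#> Taper plan plan4
#>   baseline:   80 mg OME/24h
#>   target:     0 mg OME/24h
#>   step size:  20 mg OME (linear, fixed)
#>   reductions: 4 on day(s) 1, 5, 7, 9
#>   back-up:    10 mg OME/24h until target reached
#>   duration:   9 day(s)
```

The baseline is 64 + 16 = 80 mg OME; the acute preset removes 25% of it
(20 mg) per step. Without discharge the reductions would fall on days
1, 3, 5, 7; the two-day grace period holds the day-1 dose through day 4, so
the remaining reductions shift to days 5, 7 and 9. The back-up allowance is
80/8 = 10 mg OME per day until cessation.

Packing an exact dose into tablets:

```r
map_daily_dose(37.5, form$opioids$morphine, n_slots = 2)
#> <regimen> morphine: 37.5 mg/day prescribed, 40 mg/day achieved (+6.7%), 2 unit(s)
#>   08:00 (morning): 1 x 20 mg
#>   20:00 (evening): 1 x 20 mg
```

40 mg is the closest dose reachable with two tablets within the 15%
tolerance; the +6.7% deviation is printed so the clinician can accept or
reject it.

## Command line

A thin Rscript front end lives at `inst/cli/opitaper` (after installation:
`system.file("cli", "opitaper", package = "opitaper")`):

```sh
opitaper plan --patient case.json --out outdir      # plan.json + plan.csv
opitaper rotate --from-drug morphine --to-drug oxycodone --dose 60 --out outdir
opitaper formulate --drug morphine --dose 40 --out outdir
opitaper handout --patient case.json --drug morphine --out outdir
opitaper readability --text pamphlet.txt --locale de --out outdir
opitaper delphi --ratings ratings.csv --out outdir
opitaper fixtures --seed 1 --out fixtures/
```

Exit status 0 on success, 2 on validation errors (unknown drug, malformed
input), 1 on internal errors. Flags can also be given via `--config
config.yaml`.

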