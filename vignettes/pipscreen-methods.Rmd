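---
title: "Methods: operationalising explicit prescribing criteria on dispensing claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: operationalising explicit prescribing criteria on dispensing claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pipscreen)
```

## What is being measured

Potentially inappropriate prescribing (PIP) is here defined by *explicit*
criteria: rules that can be judged from a dispensing record alone, without
clinical notes. The package targets middle-aged adults (45–64), screening a
study year of reimbursement claims in which each row is one dispensed
supply — patient, date, drug code (ATC or BNF), quantity, unit strength.
The primary outcome is *any PIP*: at least one criterion triggered. Claims
carry no diagnoses, no stop dates and no dosage instructions, so every
clinical notion a criterion mentions (duration of use, maintenance dose,
first-line choice, co-prescription) must be operationalised. Those
operationalisations — not the arithmetic — are where screening studies
genuinely differ, so each one here is an explicit, documented parameter.

## Exposure model

**Episodes.** Continuous use is reconstructed by chaining: dispensings of
one drug class whose consecutive dates differ by at most
`gap_tolerance_days` belong to one episode, and the final dispensing is
assumed to cover `default_coverage_days` further days, so

> duration = (last date − first date) + coverage.

Defaults: gap tolerance **63 days** (two missed monthly cycles before use
is deemed interrupted) and coverage **28 days** (the standard monthly
supply in both source systems, which lack a days-supply field). Both are
arguments of `build_episodes()`, because the correct values are a property
of the dispensing system, not of the criteria. A consequence worth knowing:
with 28-day coverage a *single* dispensing yields exactly a 28-day episode,
which sits precisely on the ">4 weeks" boundary and does not trigger — a
duration rule therefore needs at least two chained dispensings.

**Dose intensity.** An episode's mean daily dose is total dispensed mass
over duration, Σ(quantity × strength)/duration. Episode-averaging is robust
to pack-size variation; the alternative (maximum single-dispensing dose) is
deliberately not the default because one large pack would then flag a
patient who simply collects less often. One nuance follows: a
dose-plus-duration flag is *not* monotone in added evidence, since an
appended low-dose dispensing can extend the episode and dilute the mean
below the threshold. The duration-only and duplication rules are monotone,
and the property tests assert exactly that set.

**Months.** Co-prescription and duplication are judged per calendar month,
matching the monthly cadence of claims reimbursement: duplication is ≥ 2
distinct chemical-level codes (full ATC code; full BNF entry) of one class
in one month; a co-prescription violation is a month with a target-class
dispensing and none of the required companion classes.

## Rule categories and thresholds

Five structural categories cover the shipped rule set
(`inst/extdata/prompt_vocabulary.json`): `DURATION`, `DOSE_DURATION`,
`CO_PRESCRIPTION`, `FIRST_LINE`, `DUPLICATION`. All thresholds are strict:
">4 weeks" is 29+ days. Fixed-length conversions are 4 weeks = 28 days,
8 weeks = 56 days, 3 months = 90 days (a fixed 90 keeps the threshold
auditable; calendar 3-months would vary by start date).

The first-line rules implement a new-user condition: the episode must start
in the observation year with **no** earlier dispensing of the target class
*or* of any preferred alternative class — looked up over the 3-month
lead-in and any earlier in-window events. The lead-in exists solely for
this lookback; lead-in events never enter episodes, occupancy or
polypharmacy.

Maintenance-dose thresholds (for the PPI rule) are configuration, resolved
by longest-prefix match so a chemical-level entry overrides its subgroup
default; when an episode spans chemicals the *highest* involved maintenance
dose applies (the dose must exceed every involved drug's maintenance level
to flag — the conservative reading). The shipped values are
formulary-derived placeholders, clearly marked in the config, because
explicit criteria sets typically do not print them.

**Duplication and the any-PIP outcome.** Summary tables in this literature
report same-month duplication as its own row, so by default duplication
flags do not count toward `n_pip`/`any_pip` and are summarised separately
(`any_duplication`); `duplication_in_any_pip = TRUE` folds them in, one
flag per duplicated class.

## Cohort decisions

"Follow-up until the 65th birthday (month)" is ambiguous about the birthday
month itself. Decision: the window ends on the last day of the *preceding*
month — the conservative reading of "until" — with
`include_birthday_month = TRUE` documenting the alternative. Age is in
completed years at study start; 64-year-olds with a January birthday
therefore have an empty window and drop out. The denominator keeps only
patients with ≥ 1 observation-year dispensing
(`require_any_dispensing = TRUE`), the usual convention when a claims
database cannot distinguish "registered but undispensed" from "absent".

## Statistics

Prevalence is percent with a **Wald** interval on the percent scale,
rounded half-up to one decimal (base R's round-half-even would differ in
the last digit often enough to matter when comparing against published
tables; `prevalence_ci()` reproduces standard published claims-screening
prevalence rows exactly under this convention). Wilson is available via
`method = "wilson"` for small numerators, where Wald is known to misbehave;
at the denominators this design targets (10^5) the two agree to the printed
decimal. Intervals are clamped to [0, 100].

Determinants are modelled by logistic regression (`stats::glm`, binomial):
one model per covariate (unadjusted ORs) and one joint model of
polypharmacy + gender + age band (adjusted), no interactions. CIs are Wald
on the log-odds scale. Perfect separation and non-convergence are detected
and reported as errors with actionable messages rather than silently huge
ORs.

## The synthetic generator: what a green test establishes

`generate_dataset()` states a world: study year 2012 plus 3-month lead-in;
49.4% female; age-band shares 28.5/25.9/22.1/23.5%; planted criterion rates
defaulting to the published criterion prevalences of a full-population
claims dataset (the unprinted tricyclic first-line rate is set to 1%);
background dispensing calibrated so ~20.3% of patients meet the
polypharmacy definition; 28-unit packs, 10 mg units (PPI plantings: 20 mg,
double packs). Where the sources are silent (pack size, unit strength,
background process) values were chosen once for plausibility and are
flagged in the config.

Plantings are deterministic given the patient's window: each criterion has
a fixed day-offset schedule, and schedules of rules sharing a drug class
are separated by more than the 63-day gap tolerance or placed in distinct
calendar months, so planted labels are *exactly* recoverable — on
zero-background data the engine's sensitivity and specificity against the
truth table are 1.0 by construction, and the acceptance suite verifies
this at 5,000 patients. Hard negatives sit exactly on rule boundaries
(28/56/90 days, same-month laxative cover, an alternative agent in the
lead-in, repeated rather than distinct chemicals), pinning the
strict-inequality convention. Patients censored too early to hold a
pattern are simply not planted (truth records 0); with default
demographics this affects ~4–5% of draws for the late-schedule criteria.

What the generator does **not** emulate: deprivation gradients, mortality
and migration, practice-level data-quality filters, correlated
multi-morbidity prescribing, seasonal effects, or any association between
planted criteria and the background classes that drive polypharmacy. A
green pipeline run therefore establishes that the *machinery* is correct —
not that real-world prevalence or odds ratios are reproduced; published
adjusted ORs require the original individual-level data, and the
acceptance suite substitutes a parameter-recovery simulation (true ORs
{polypharmacy 8.0, female 1.5, age bands 1.1} at n = 20,000, Wald CI
coverage checked over 200 replicates).

## Numerical and degenerate-input choices

* All randomness flows from one seed (`withr::with_seed`); identical
  config + seed gives byte-identical CSV output.
* Config validation collects *every* problem before failing.
* Unknown drug codes resolve to no class and are ignored by the engine;
  episodes with missing strength are dose-unknown and never trigger dose
  rules; drugs absent from the dose table are skipped with a warning.
* Empty inputs (zero events, empty cohort) return empty, correctly-typed
  tables rather than errors.
* `pip_count_table()` refuses profile tables whose count categories fail
  to partition the any-PIP count — a structural invariant, not a test.

## Known limitations

* Chained-dispensing episodes cannot see actual intake; non-adherent
  stockpiling inflates durations.
* The BNF sub-section splits used to separate sedating from non-sedating
  antihistamines are synthetic placeholders; real BNF data needs the
  genuine section codes in the config.
* Only the criteria expressible from drug lists are shipped; rule sets
  requiring diagnoses are out of scope, though the five categories are
  config-extensible.
* The polypharmacy calibration targets the marginal rate through
  background dispensing only; planted criterion drugs add a small surplus
  on top.
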