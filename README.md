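# pipscreen

Screening prescription-dispensing claims for potentially inappropriate
prescribing (PIP) in middle-aged adults.

## The problem

Explicit (criterion-based) prescribing standards — in the tradition of
STOPP and Beers, but written for adults aged 45–64 — flag medication use
that is potentially inappropriate from a drug list alone: a benzodiazepine
used for more than 4 weeks, a proton pump inhibitor above its maintenance
dose for more than 8 weeks, a strong opioid dispensed in a month with no
laxative cover, a tricyclic antidepressant started first-line, two distinct
opioids dispensed inside one calendar month. Administrative dispensing
databases (one row per reimbursed supply: patient, date, drug code,
quantity, strength) let such criteria be applied at population scale, but
only after several operationalisation steps that this package makes
explicit, configurable and testable:

* **Cohort** — adults aged 45–64 in completed years at study start, followed
  for a study year, censored at the month of the 65th birthday, with a
  3-month lead-in retained solely to establish prior medication history.
* **Vocabulary** — drug classes defined by code prefixes in *both* common
  coding dialects (WHO ATC codes; BNF section codes), so one rule set runs
  against either kind of database.
* **Exposure** — continuous-use episodes built by chaining dispensings of a
  class whose dates differ by at most `gap_tolerance_days` (default 63),
  each dispensing covering `default_coverage_days` (default 28); and
  calendar-month class occupancy for same-month rules.
* **Criteria engine** — declarative rules of five structural categories
  (`DURATION`, `DOSE_DURATION`, `CO_PRESCRIPTION`, `FIRST_LINE`,
  `DUPLICATION`) evaluated with strict inequalities at every threshold.
* **Polypharmacy** — the number of distinct medication classes (5-character
  ATC subgroup / BNF section) dispensed ≥ 3 times in the study year;
  ≥ 4 such classes is the conventional polypharmacy indicator.
* **Statistics** — prevalence as percent with a Wald 95% CI,
  100·(p̂ ± 1.96·√(p̂(1−p̂)/N)), rounded half-up to one decimal; and
  unadjusted/adjusted logistic regression of any-PIP on polypharmacy,
  gender and 5-year age band, reported as odds ratios
  OR = exp(β̂) with Wald intervals exp(β̂ ± 1.96·SE).

Real claims databases are not publicly deposited, so the package ships a
synthetic generator (`generate_dataset()`) that emulates their structure
and can *plant* criterion-positive and hard boundary-negative dispensing
patterns with a per-patient truth table — every downstream stage is
testable end to end with no data access.

## Worked example

```r
library(pipscreen)

vocab <- load_vocabulary()                     # shipped rule set: 11 criteria
cfg   <- sim_config(n_patients = 1000, seed = 42)
ds    <- generate_dataset(cfg, vocab)          # registry + events + truth
prof  <- evaluate_cohort(ds$events, ds$windows, vocab, "ATC")
pip_count_table(prof)
```

```
           row numerator denominator percent ci_low ci_high
1: overall_pip       233         977    23.8   21.2    26.5
2:       pip_1       211         977    21.6   19.0    24.2
3:       pip_2        21         977     2.1    1.2     3.1
4:   pip_3plus         1         977     0.1    0.0     0.3
5: duplication        53         977     5.4    4.0     6.8
```

977 of the 1000 simulated patients were dispensed at least one prescription
during the study year (the denominator convention for claims studies);
23.8% of them triggered at least one counting criterion, and 5.4% had a
same-month duplication (reported separately by default). The
category rows partition the any-PIP count (211 + 21 + 1 = 233), which
`pip_count_table()` asserts structurally.

```r
obs      <- filter_events(ds$events, ds$windows)[phase == "observation"]
poly     <- compute_polypharmacy(obs, "ATC")
analysis <- build_analysis_table(prof, ds$windows, poly)
fit_logistic(analysis)   # unadjusted + adjusted ORs vs male / 45-49 / no polypharmacy
```

```
           term  level or_adjusted    lo    hi
1: polypharmacy  FALSE        1.00    NA    NA
2: polypharmacy   TRUE        1.36  0.96  1.95
3:       gender   male        1.00    NA    NA
4:       gender female        1.00  0.74  1.34
...
```

(The default generator plants criteria independently of the background
dispensing that drives polypharmacy, so the adjusted OR for polypharmacy is
near 1 here — by design; see the methods vignette.)

The same pipeline runs as one call, writing CSV tables, a log and a
manifest: `run_pipeline("out/", cfg)`, or from the shell via
`Rscript inst/cli/pipscreen.R run --out out/ --n 1000 --seed 42`.

## Layout

* `R/` — vocabulary, cohort, exposure, criteria engine, polypharmacy,
  statistics, simulator, pipeline.
* `inst/extdata/prompt_vocabulary.json` — shipped classes, dose thresholds
  (formulary-derived placeholders) and rule set; user-overridable.
* `vignettes/pipscreen-methods.Rmd` — model, operationalisation decisions,
  what the simulator does and does not emulate.
* `tests/testthat/` — unit, property and acceptance tests, including
  brute-force oracle implementations independent of the package internals.
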