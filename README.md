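# chwvitals

Can community health workers (CHWs) count births and child deaths well enough
to track under-five mortality in "real time"? In most low-income countries
civil registration captures only a few percent of vital events, so under-five
mortality rates (U5MR) come from retrospective household surveys that are
years out of date. One proposed interim solution is routine monthly reporting
of pregnancies, births and deaths by CHWs over defined catchment areas,
validated against full birth/pregnancy histories (FBH/FPH) collected by
survey or census.

`chwvitals` implements that validation analysis as a tested pipeline for
biostatisticians and demographers evaluating community-based vital-events
surveillance:

* a **demographic microsimulator** producing a ground-truth ledger of
  pregnancies, births and under-five deaths (constant per-woman-month
  fertility; sequential neonatal / post-neonatal / child mortality hazards;
  configurable sex ratio at birth and stillbirth risk; monthly CMC dating);
* explicit **observation models**: CHW capture probabilities by event type,
  wholesale loss of catchment-month reports, stillbirths misclassified as
  neonatal deaths; survey census/household-sampling, recall omission of dead
  children growing with years since death, age heaping of deaths onto 12
  months, birth-date displacement;
* the **validation metrics** applied identically to both data streams over
  rolling 12-month windows stepping by 3 months.

## The statistics

With century month codes `cmc = (year − 1900) × 12 + month`, events are
tabulated per window `[t, t+11]`; deaths by death date, births by birth date.
Period rates are plain ratios, not synthetic-cohort probabilities:

```
NMR = 1000 · D_neonatal / B      CBR = 1000 · B / population
IMR = 1000 · D_infant  / B      U5MR = 1000 · D_under5  / B
```

Completeness compares CHW-documented events with expected events from the
validation source: expected births = reference CBR × population / 1000,
expected under-five deaths = reference U5MR × expected births / 1000.
Accuracy is the average annual ratio, the unweighted mean over windows of
100 × (CHW rate / reference rate). Data quality uses the sex ratio at birth
(reference band 102–107 males per 100 females), the neonatal:infant and
infant:under-five death ratios, and a 12-month age-heaping index
`5 · d(12) / [d(10)+…+d(14)]`. Costs are CPI-inflated, converted to base-year
USD, and summarised as total, annual cost per 1,000 population
(`total · 12/months / (pop/1000)`) and cost per reported event.

## Worked example

```r
library(chwvitals)
cfg <- pipeline_preset("mali_like", seed = 7)  # high-capture scenario
rep <- run_pipeline(cfg, quiet = TRUE)
rep
#> <validation_report> 2 windows; coverage 100.0%
#>   completeness: births 90.7%, under-five deaths 90.2%
#>   accuracy (avg annual ratio %): CBR 90.7, NMR 107.5, IMR 109.3, U5MR 99.4
```

Read this as: CHWs configured to capture 90.3% of births documented 90.7% of
the births the (error-free-denominator) survey implies; recall omission and
stillbirth misclassification push the CHW neonatal and infant rate *above*
the survey reference (ratios > 100) even though absolute capture is below
100% — the survey under-counts old deaths, shrinking its denominator rates.

```r
render_tables(rep)$death_ratios
#>   source avg_deaths_neonatal avg_deaths_infant avg_deaths_under5 pct_neonatal_of_infant pct_infant_of_under5
#> 1    chw                17.5              47.5              82.5                   36.8                 57.6
#> 2    fbh                18.0              48.0              91.5                   37.5                 52.5

round1(death_ratio(125, 188))   # published Ethiopia neonatal:infant panel
#> [1] 66.5
```

The `gold` preset (perfect observation) returns completeness 100 and all
accuracy ratios exactly 100 — the end-to-end identity the test suite pins.

A shell entry point with verbs `simulate | observe | analyze | cost | all`
is installed at `system.file("cli", "chwvitals.R", package = "chwvitals")`.

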