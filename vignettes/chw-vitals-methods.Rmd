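---
title: "Validating community-based vital-events reporting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating community-based vital-events reporting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chwvitals)
```

## The problem

Community health workers (CHWs) reporting births and under-five deaths
monthly for a defined catchment are one candidate source of "real-time"
under-five mortality estimates in settings where civil registration is
nearly absent. Validating such a system means comparing it with the current
best practice — retrospective full birth/pregnancy histories (FBH/FPH)
collected by survey or census — while recognising that the reference itself
suffers recall errors. `chwvitals` casts that comparison as a simulation
study: a known ground truth, two imperfect observation channels, and the
validation metrics computed identically on both.

## Ground-truth model

Time is discrete in months, dated by century month code (CMC,
`(year − 1900) × 12 + month`), the standard survey birth-recode convention;
it matches the monthly CHW reporting cadence, and neonatal deaths carry an
extra age in days (uniform on 0–27) for the finer age class.

Each woman contributes an independent Bernoulli draw per calendar month with
probability `monthly_birth_prob`. Reproductive careers are not aged over the
short (≤ 4-year) horizon: fertility decline and parity structure are
second-order for window-level counts. Each outcome is a stillbirth with
`stillbirth_prob`, otherwise a live birth, male with odds `srb_true : 100`.
Survival passes sequentially through three hazard segments — neonatal
(days 0–27), post-neonatal (months 1–11), child (months 12–59) — with ages
at death uniform within the dying segment. On a closed cohort the implied
under-five mortality is

$$ q_5 = 1 - (1-h_{nn})(1-h_{pnn})(1-h_{child}), $$

and `implied_u5mr()` exposes it; a property test checks the simulated cohort
converges to it. Multiple births and migration are out of scope.

### Default parameters and why

Defaults describe the high-fertility, high-mortality rural settings these
systems target:

| parameter | default | rationale |
|---|---|---|
| `monthly_birth_prob` | 0.02 | ≈ TFR 7 spread over a 30-year reproductive span |
| `hazard_neonatal` | 0.040 | NMR 40 per 1,000 |
| `hazard_postneonatal` | 0.0625 | with the above, IMR 100 per 1,000 |
| `hazard_child` | 0.18 | cohort U5MR 262 per 1,000, a published regional benchmark for the highest-mortality site |
| `srb_true` | 105 | middle of the 102–107 demographic reference band |
| `stillbirth_prob` | 0.02 | ≈ 20 stillbirths per 1,000 deliveries |
| world size | 20 catchments × 100 households × 1 woman | ≈ 2,000 women (a small pilot area of ~10,000 residents, cf. 4,200 households in the smallest published site); large enough that every 12-month window contains births and deaths of each age class, so period rates are defined |

These were chosen once as a stated world; tests measure against it rather
than tuning it.

## Observation models

**CHW channel.** Every true event in the reporting period is captured
independently with a type-specific probability (births; neonatal,
post-neonatal and child deaths separately — field studies consistently find
deaths under-reported more than births). Stillbirths enter as spurious
neonatal deaths with `p_stillbirth_as_neonatal`, reflecting the documented
misclassification concern. Finally whole catchment-month reports go missing
with `p_monthly_report_missing`; captured events in those months are lost
and — deliberately — *no adjustment* is made, mirroring the analysis
convention of the validation studies.

**Survey channel.** A census or Bernoulli household sample; live births
only (stillbirths never appear in a birth history); survival status as of
the interview date. The dominant error mode is recall omission of dead
children, with per-child omission probability
`1 − (1 − p_omit_per_year_recall)^years-since-death`; survivors are assumed
reported. Deaths at true age 10–14 months are relabelled exactly 12 months
with `p_heap_to_12m` (the classic age-heaping artifact), and birth dates get
a rounded normal displacement. Reported death dates are reconstructed as
reported birth date + reported age, as survey recodes do — so heaping moves
deaths across window boundaries, which is exactly the distortion it causes
in real data.

All random draws in both channels are generated up-front in fixed ledger
order. With a fixed seed, raising one error probability only grows the
affected set (common random numbers); this is what makes the degradation
property below hold pathwise, not merely in expectation.

## Metrics

Period rates are **ratios of events dated to the same 12-month window**
(deaths ÷ births, × 1,000), not synthetic-cohort probabilities — the
definition the validation literature states for this design. Consequence
(documented, accepted): under changing birth rates the ratio is biased
relative to cohort q(5), so tests assert rate recovery only under the
simulator's demographic stationarity. Deaths are allocated by death date and
births by birth date, so a window can contain a death whose birth it does
not. Windows are inclusive of both endpoint months and step by 3 months.

Completeness uses expected events from the reference rates (CBR ×
population, then U5MR × expected births) rather than raw survey counts
scaled by the sampling fraction; the two coincide under a census. The
population denominator is held at its census value for every window (the
published analyses fix it likewise); the simulator models only women, so the
pipeline carries an explicit `population` (default 5 residents per woman).
Completeness and the CBR accuracy ratio are invariant to this constant
because it enters numerator and denominator alike. For sampled surveys the
reference CBR denominator is scaled by the realised household sampling
fraction, which is the point-estimate analogue of survey weighting.

The **average annual accuracy ratio** is the unweighted mean over windows of
the per-window percent ratio. The documented alternative — ratio of means —
was rejected as a less plain reading of "average annual ratio"; with 12-month
windows every window has equal standing.

Register verification uses greedy one-to-one matching within catchment and
event type by nearest event month, tolerance 1 month by default, ties broken
by the earliest reference event. The published studies give no linkage
algorithm (individual matching was attempted in one site "with limited
success"), so the simplest reproducible rule was chosen.

Costing inflates each line item by `cpi(base)/cpi(year)`, converts at the
base-year exchange rate, and annualises as `total × 12/months`. The
annualisation formula is never stated in the published tables; the rule
adopted here reproduces the Malawi figure ($434 per 1,000) exactly, while
the Ethiopia figure ($523) is not reproducible from its printed inputs under
any simple rule, so only Malawi is a test target.

### Numerical conventions

* Internal values are full precision; presentation rounding is
  round-half-up to one decimal (`round1()`), applied only in
  `render_tables()`.
* Zero births in a window make mortality rates undefined: `period_rates()`
  raises an error rather than propagating NaN; likewise a zero reference
  rate in `accuracy_ratios()`.
* Empty match samples report `NA` percentages, not 0/0.
* All pipeline randomness derives from one seed: simulator `seed`, CHW
  observation `seed + 1`, survey observation `seed + 2`.

## What the synthetic world does and does not establish

A green test suite establishes the *internal consistency* of the analysis
machinery: error-free observation reproduces truth exactly on every window
(completeness 100, all ratios 100); capture probabilities are recovered
unbiasedly by the completeness construction; omission of dead children in
the reference mechanically inflates CHW:reference mortality ratios above
100 — the mechanism behind published >100% neonatal/infant ratios in the
best-performing site. It does **not** establish anything about real CHW
behaviour: the simulator has no spatial or temporal heterogeneity in
capture, no CHW turnover process, no correlation between a child dying and
being missed, no migration, and singleton births only. Scenario presets
(`gold`, `mali_like`, `malawi_like`, `ethiopia_like`) use published
completeness figures as illustrative capture parameters, not estimates.

## Known discrepancies in the published tables

The bundled reference tables record published values as printed; three
internal inconsistencies are worth knowing. (1) The source abstract says the
best site's U5MR was under-estimated by 9% while its summary table prints an
accuracy ratio of 100.6; the table convention is used here. (2) The text
quotes a neonatal:infant ratio difference of 9.6 for one site where the
table arithmetic gives 8.6; only table-derived values are asserted. (3) The
smallest site's population appears as 32,128 (study census, used here) and
~53,205 residents elsewhere; the reference CSV records the census value.

## Limitations

Survey-design variance (cluster jackknife) and statistical testing of ratio
differences are out of scope: everything is a point estimate. The period
ratio is not a cohort probability; comparisons across sources remain valid
because both sources use the identical definition, which is the design's
central trick.
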