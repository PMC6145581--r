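---
title: "Methods: nested case-control estimation of NSAID-associated stroke risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nested case-control estimation of NSAID-associated stroke risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsaidstroke)
library(data.table)
```

## The design

`nsaidstroke` implements a case-control study nested in a cohort of new
users of non-steroidal anti-inflammatory drugs (NSAIDs), the design used in
multi-database pharmacoepidemiological studies of ischemic stroke (IS)
risk under individual NSAIDs. The package covers the whole chain: a
synthetic claims generator with known true effects, new-user cohort
construction, drug supply episode algebra, incidence-density sampling of
matched controls, confounder assessment, and conditional logistic
estimation with Wald inference.

The rationale for each stage:

* **New-user cohort.** Prevalent users under-represent people harmed early
  by a drug (depletion of susceptibles), so the cohort admits only
  initiators with a 12-month enrolled, NSAID-free, cancer-free lookback
  (non-melanoma skin cancer exempt), aged 18+. Entry is the first
  qualifying dispensing; follow-up ends at the earliest of study end,
  first IS, enrollment interruption, malignant cancer, or death.
* **Risk-set (incidence-density) sampling.** For each case, up to 100
  controls still at risk on the case's event day are drawn from the same
  database and sex with age at cohort entry within ±1 year. Controls
  inherit the case's index date, so matching on calendar time is implicit.
  Under this sampling the conditional odds ratio estimates the incidence
  rate ratio.
* **Past use as reference.** Comparing current users with *past* users of
  any NSAID (rather than never-users) confines the contrast to people who
  were all judged to need an NSAID at some point, which blunts confounding
  by indication.

## Exposure algebra

Time is modelled in whole days and all intervals are closed. Each
dispensing supplies `recorded_duration` days when recorded, otherwise its
DDD quantity at one DDD per day; the supply runs from the dispense date to
`start + duration - 1`. Prescriptions whose gap (next start minus previous
supply end) is **less than 14 days** belong to one continuous-use episode.
At an index date a substance is

* **current** — a supply overlaps the index or ended within the 14 days
  before it (`end >= index - 14`),
* **recent** — no supply is current and the latest supply ended 15–183
  days before the index,
* **past** — the latest supply ended more than 183 days before the index.

These three windows partition all histories with at least one dispensing
on or before the index, which the new-user design guarantees for every
cohort member. The 14-day stitching gap is measured end-to-start
exclusive; "within the 14-day period before" means `end` in
`[index - 14, index - 1]`. This convention makes the 15-day lower bound of
the recent window exactly contiguous with current, and is fixed by
boundary tests at ±1 day around every edge.

Duration of continuous use is categorised as `<7`, `7–29`, `30–89`,
`>=90` days and is truncated at the index date: supply dispensed after the
event cannot contribute to exposure duration at the event. Subjects
current on two or more substances carry a separate `current_multiple`
indicator and never contribute to a single-substance contrast, keeping
substance-specific estimates uncontaminated.

## The estimator

With exactly one case per matched set the Breslow conditional likelihood
is exact (no tie handling is needed):

$$\ell(\beta) = \sum_s \Big[ x_{\text{case},s}^\top\beta -
  \log \sum_{j \in s} e^{x_j^\top \beta} \Big].$$

`fit_clogit()` maximises it by Newton–Raphson from $\beta = 0$ with
step-halving (a step is halved until the log-likelihood does not
decrease), declaring convergence when the maximal absolute score falls
below `1e-8` (at most 50 iterations). The observed information is computed
analytically and supplies Wald standard errors; 95% intervals are
$\exp(\hat\beta \pm 1.959964\,\mathrm{se})$. Degenerate inputs are handled
explicitly: sets without a case or without controls are excluded with a
logged count; columns with no variation inside any set carry no
information and are reported as not estimable rather than silently
dropped; coefficients exceeding 20 in absolute value flag separation and
mark the fit non-converged. Starting at zero with step-halving makes the
optimisation deterministic, and on every random small design the optimum
is verified in tests against a derivative-free maximiser and against an
independent implementation of the likelihood.

**Confounder scheme.** Diagnosis covariates and "prior use" drug
covariates are assessed in `[entry - 365, entry]`; concurrent drug
covariates in `[index - 90, index - 1]` (30 days for acute treatments).
The index day itself is excluded from concurrent windows so that treatment
triggered by the event is not read as prior exposure. A fixed a-priori
tier (stroke, TIA, myocardial infarction, heart failure, atrial
fibrillation/flutter, diabetes, hyperlipidemia, hypertension, smoking,
antihypertensive drug classes, cardiac glycosides, lipid-modifying drugs,
aspirin, anticoagulants, platelet-aggregation inhibitors) is always
retained; the remaining candidates pass through backward elimination that
repeatedly removes the candidate with the largest two-sided Wald p-value
at or above 0.05. The elimination criterion and its threshold are design
choices of this package — Wald-based removal, worst-first, stay level
0.05 — made because they are cheap, deterministic and reproducible;
likelihood-ratio-based elimination would be a drop-in alternative.
Stratified analyses reuse the pooled model's retained covariates rather
than re-running elimination within each stratum, so strata remain
comparable.

## The synthetic claims generator

The generator emulates the structure of multi-database dispensing claims:
persons with database label, sex, birthdate and enrollment spans; NSAID
treatment chains (initiation while untreated at a per-day rate, one
substance per chain, refills with configurable probability and gap
distribution, 30-DDD packs by default, a recorded duration on a
configurable fraction of fills); baseline confounders sampled once per
person and materialised as diagnosis records in the year before first use
or as recurring co-medication dispensings; and an event process whose
per-day probability is a sex- and age-band-specific baseline hazard
multiplied by `exp` of the log rate ratios of the day's exposure state and
the person's confounders. Death, cancer and disenrollment are independent
censoring processes.

Two properties make parameter recovery a well-posed test of the
*estimator* rather than of convention agreement:

1. the event process classifies each day's exposure state with the same
   episode algebra (same stitching, same 14/183-day windows) the analysis
   uses, via piecewise-constant hazard segments with geometric waiting
   times — an exact simulation of a daily Bernoulli process;
2. confounding by indication is induced by letting confounders raise the
   NSAID initiation rate (`log_rr_init`), so the crude current-vs-past
   contrast is biased upward by construction and only the adjusted
   estimate should recover the truth.

What the generator does *not* emulate: real terminologies (one sentinel
code per concept stands in for harmonised code lists), dose heterogeneity
within a substance, over-the-counter use, seasonality, and dependence of
refill behaviour on health status. Passing tests therefore demonstrate
that the pipeline is a faithful implementation of the design and an
approximately unbiased, correctly calibrated estimator under the design's
assumptions — not that those assumptions hold in any particular real
database.

## Validation studies and problem sizes

The package validates itself with two simulation studies
(`recovery_study_config()`, `run_recovery_replicate()`), sized to give a
meaningful case count while keeping a full replicate around a second:
10,000 persons over a two-year study period, a flat per-day stroke hazard
of 6e-5 (roughly 350 observed cases per replicate), a single marketed
substance, and 1:10 risk-set sampling.

* **Coverage.** With a true current-use rate ratio of 1.5 and active
  confounding by indication, the adjusted 95% Wald interval covers
  `log 1.5` in approximately 95% of 200 replicates (tolerance: three
  binomial standard deviations).
* **Calibration.** With every rate ratio at 1 (confounder-initiation
  association kept), the adjusted Wald test of the current-use
  coefficient rejects at 5% ± 3 binomial standard deviations over 200
  replicates, and the estimates are centred at zero.

Numerical and convention choices collected in one place: 1 year =
365.25 days for all age arithmetic (the 12-month lookback is exactly 365
days); "continuous enrolment" means a single span covering
`[entry - 365, entry]`; the NSAID- and cancer-free lookbacks are
`[entry - 365, entry - 1]`; baseline covariate windows are
`[entry - 365, entry]`; cohort-exit ties are broken IS > death > cancer >
disenrollment > study end; an IS on the entry day itself is a case (the
boundary of "after entry" is resolved as on-or-after); controls are
sampled without replacement within a set and may be reused across sets; a
person is at risk at an index when their follow-up ends strictly later;
percentages are rounded half-up to one decimal and odds ratios to two, the
table style of epidemiological reports. Default age strata for stratified
analyses are 18–59, 60–69, 70–79, 80+ at the index date.

## Known limitations

* Exact conditional inference and robust variances are out of scope;
  Wald inference is accurate at the case counts the design targets but
  optimistic in strata with very few exposed cases (reported as wide or
  not-estimable rather than suppressed).
* The backward-elimination criterion is one reasonable choice among
  several; results with correlated candidates can depend on removal
  order.
* Re-entry into the cohort after an enrollment interruption is not
  modelled; only the first qualifying entry is used.
* Pooling fits all matched sets in one conditional likelihood (sets are
  the strata); meta-analytic pooling of per-database estimates is
  deliberately not offered.
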