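---
title: "Daily organ-dysfunction scoring and its time-varying predictive validity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Daily organ-dysfunction scoring and its time-varying predictive validity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

The sequential organ failure assessment (SOFA) score summarises acute organ
dysfunction in ICU patients across six domains — respiration,
coagulation/hemostasis, liver, cardiovascular, brain and renal — each graded
0–4, for a total of 0–24. Two threshold systems are in use: the classical
1996 system ("SOFA-1") and a 2025 recalibration ("SOFA-2") that changes
several cut-offs and lets modern organ support (ECMO, renal replacement
therapy, delirium-requiring medication) contribute points. `sofaval`
computes daily scores under both systems from time-stamped electronic ICU
records, quantifies how the systems reclassify patients relative to one
another day by day, and evaluates each system's predictive validity for
30-day and ICU mortality over the first ICU week.

# Scoring procedure

## Windows and aggregation

Scores are computed in 24-hour windows since ICU arrival: window *k* is the
half-open interval [24(k−1), 24k) hours, so an observation at exactly
24.0 h belongs to day 2. The choice is deterministic and makes the window
partition exact: every event belongs to exactly one day. No scores are
produced after ICU discharge; a partial final day still counts as a day.

Within a window the engine applies the worst-value convention used
throughout the SOFA literature: minimum for platelets, P/F and S/F ratios,
mean arterial pressure and GCS; maximum for bilirubin, creatinine and the
noradrenaline-equivalent rate; the daily total for urine output. The P/F
ratio is formed on temporally paired measurements — each PaO~2~ is paired
with the most recent preceding FiO~2~ (falling back to the nearest
following value, then to room air 0.21) — and the lowest paired ratio in
the window is kept. Pairing before taking the minimum avoids combining a
low PaO~2~ with a high FiO~2~ recorded hours apart, which would exaggerate
severity. An FiO~2~ of zero is a validation error.

GCS handling: when eye/verbal/motor components are all present the total is
their sum of per-window worst values; an explicitly recorded total overrides
component sums in the same window, on the view that the recorded total
carries the assessor's intent.

Therapy intervals (mechanical ventilation, RRT, ECMO, delirium-related
medication, vasopressor infusions) contribute a support flag to every day
they overlap; duplicate or overlapping intervals are merged so they are
never double counted. Vasopressor exposure is collapsed to a
noradrenaline-equivalent rate (µg/kg/min): each drug's maximal rate in the
window times a configurable equivalence factor, summed over drugs
(noradrenaline 1, adrenaline 1, dopamine 0.01, phenylephrine 0.1,
metaraminol 0.125, vasopressin 2.5 per U/min, angiotensin II 10 per
µg/kg/min). Summing per-drug maxima is a deliberate worst-case convention:
it assumes the infusions were concurrent at their peaks.

## Threshold tables are configuration

The engine is threshold-agnostic: a `ScoreTable` (YAML) maps predicates
over worst-value aggregates and support flags to points, evaluated
highest-points-first with first match winning and 0 as the default. The
shipped `sofa1.yaml` transcribes the classical system, with the
cardiovascular domain banded on noradrenaline equivalents (>0–0.1 → 3,
>0.1 → 4; dobutamine/milrinone → 2; MAP < 70 → 1) as is standard for
EHR-derived scoring. The shipped `sofa2.yaml` follows the structure of the
2025 recalibration — S/F ratio accepted alongside P/F, ECMO scoring in the
respiratory and cardiovascular domains, RRT → renal 4, delirium-requiring
medication → brain ≥ 1, higher noradrenaline-equivalent bands — with
numeric cut-offs shipped as editable defaults. Deployments scoring real
patients should verify each band against the primary publication of the
recalibrated system; all package analyses treat both tables as versioned
configuration, so replacing a table changes no code.

Units are normalised at ingest (µmol/L for bilirubin and creatinine,
10^9/L platelets, mmHg pressures, FiO~2~ as a fraction) through a
conversion table carried by the ScoreTable. Records failing validation
(negative times, out-of-range FiO~2~ or GCS components, unknown units) are
rejected into a logged validation-error table, never silently dropped.

## Missing data

The primary policy (`normal_locf`) mirrors common practice for
retrospective daily SOFA: a domain with no measurement on day 1 is scored
at its configured normal values (scoring 0 in every domain under the
shipped tables); from day 2 on, the domain's most recent aggregate raw
values are carried forward and re-scored. Carrying forward *raw aggregates*
rather than subscores keeps unit handling and threshold logic in one place
and lets a carried value interact correctly with same-day support flags.
Per-domain provenance (`measured`, `normal_imputed`, `locf`) is recorded on
every admission-day. `complete_case` leaves missing domains as `NA`
subscores and flags the day incomplete; `mice_ready` does the same while
preserving the aggregate grid for the chained-equations sensitivity
analysis. The imputation pass is deterministic and idempotent.

# Reclassification analysis

Each admission-day with both systems' totals is classified by
sign(total~SOFA-2~ − total~SOFA-1~) into *equal* (reference),
*SOFA-2 higher*, or *SOFA-2 lower*. Daily group shares are reported with
Wilson score intervals (the binomial method is not dictated by the
analysis; Wilson behaves well near 0 and 1 and never produces degenerate
`NaN` limits). Daily mortality odds ratios per group come from one
logistic model with a categorical-day × group interaction; because day is
categorical and group is the only other term, the model is saturated and
each per-day OR equals the corresponding 2×2 contingency OR — the package
tests assert this equivalence to 10^-6^ relative error, and the model is
fitted with a tightened IRLS tolerance (10^-12^) for that reason. When
several day-contrasts are reported together, confidence intervals use the
1 − α/m level and p-values are multiplied by m (Bonferroni); m defaults to
the number of reported contrasts (7 days × 2 groups = 14) and is
configurable, since the appropriate family depends on what a table
displays. A day lacking a group is reported absent rather than
extrapolated; quasi-separation is flagged through infinite interval bounds
rather than silently corrected.

# The validity battery

For each analysis day *d* the risk set is the admissions still in the ICU
on day *d* (those with a day-*d* score); the outcome remains 30-day
mortality from admission (or ICU mortality). This is the natural
"conditional on being assessable" population; it embeds the survivor
selection that any daily-score analysis faces, which is exactly why
discrimination is expected to drift over the week.

* **AUROC** uses the Mann–Whitney estimator with ties counting one half —
  identical to the AUROC of a univariate logistic model of any monotone
  score. Inference (CI and paired comparison between the two systems on
  the same risk set) uses the DeLong structural-component estimator; the
  test suite cross-checks both the estimate and the paired p-value against
  an independent reference implementation and a seeded bootstrap.
* **Calibration** is evaluated on the in-sample probabilities of the
  univariate logistic model: the slope is the coefficient of a logistic
  refit on the model logit, the intercept is calibration-in-the-large
  (logistic intercept with the model logit as offset). In-sample these are
  identically (0, 1) by the maximum-likelihood score equations — asserted
  to 10^-6^ as a self-check — and become informative under resampling or
  transportation. Probabilities are clipped at ε = 10^-12^ before the
  logit, with a warning.
* **Optimism correction** follows the standard bootstrap scheme: refit on
  each resample, evaluate on the resample and on the original data, and
  subtract the mean difference from the apparent estimate; the interval is
  the percentile interval of the original-data evaluations. B defaults to
  500; resamples with a single-class outcome are redrawn (capped retries).
  Fixed seed ⇒ bit-identical results.
* **Continuous NRI** uses strict inequalities (ties in predicted risk move
  nothing); its interval uses the usual large-sample variance of the two
  net proportions. **IDI** components are conditional mean probability
  changes among events and non-events.
* **Per-point ORs** are exponentiated slopes of univariate logistic models
  with Wald intervals; separation is flagged, never silently reported.
* **Repeated admission-days** are handled two ways, as in the analysis the
  package reproduces: a population-averaged logistic model with
  cluster-robust (admission-level sandwich, CR0 with G/(G−1) adjustment)
  standard errors for the subscore × day interaction, and
  conditional random-intercept logistic models (Laplace approximation via
  `lme4`) compared by AIC across the null / total + time / subscores +
  time specifications.
* **Multiple-imputation sensitivity**: a compact chained-equations imputer
  (Bayesian linear regression draws per variable, cycling over variables)
  completes the domain-day table m times; downstream metrics are pooled by
  Rubin's rules. The predictor set for each variable is all other numeric
  variables — a reasonable default given that nothing in the source
  analysis pins down the predictor matrix; it is configurable by passing a
  restricted table.

# The synthetic cohort generator

No patient-level data are available to this package, so the generator
produces cohorts with the statistical structure the analyses assume, and
the test suite plants known truths and checks they are recovered.

A latent daily severity follows a stationary AR(1)
(s~1~ ∼ N(0,1), ρ = 0.85): persistence without memory of the full past is
the simplest structure consistent with organ dysfunction evolving
gradually. Each domain's raw measurements load on current severity with
realistic locations and noise (e.g. platelets and P/F fall, bilirubin and
creatinine rise, GCS deficits grow with severity); therapies trigger with
severity-dependent probabilities (ventilation from admission ≈ 60% of
admissions, vasopressors, RRT, ECMO, delirium-related medication).
Death and discharge compete through daily hazards (ties resolved
death-first, the conservative choice): death risk rises with current
severity and with a constant admission-level *frailty* (unmeasured baseline
burden), while discharge favours low severity. The severity weight in the
death hazard decays geometrically over days (factor 0.8/day), while the
frailty contribution stays constant — encoding the well-described pattern
that admission physiology dominates early mortality risk and baseline
characteristics dominate later. Together with the selection induced by
severity-linked discharge and death, this yields the qualitative
signature the analyses look for: the AUROC of the *generating* severity
for 30-day death declines from day 1 to day 7. Post-discharge deaths
within the 30-day window follow a logistic probability in the last
observed severity and frailty.

Default sizes and rates were chosen once to be of the order seen in large
mixed ICU cohorts — 30-day mortality ≈ 12–14%, ICU mortality ≈ 7–9%,
median length of stay 2 days, median day-1 totals ≈ 5 (SOFA-1) and 4
(SOFA-2), about three quarters of day-1 admission-days reclassified
between the systems — and are documented as qualitative only. Day-1
missingness defaults are 27.7% for liver and 14.2% for coagulation (the
domains dominated by daily laboratories), near-complete respiratory and
renal domains, and a geometric decay of rates over later days; an optional
severity-linked (MAR) mechanism tilts deletion towards low-severity
admission-days. Sepsis labels (prevalence 17.5%) are planted together with
consistent culture/antibiotic event pairs so the retrospective
suspected-infection logic recovers them exactly; trauma (10%) shifts age
and admission type.

What the generator does **not** emulate: real pharmacology and dosing
patterns, inter-ICU transfers, calendar-time drift, measurement batching
and device artefacts, informative *measurement* (sicker patients sampled
more often), and correlated multi-domain failure beyond what a single
latent severity induces. Passing tests therefore demonstrate that the
pipeline's logic and estimators behave correctly under a controlled
data-generating process of the assumed shape — not that any clinical
conclusion transfers to real records.

# Numerical and design choices

* Delta scores are **signed** by default (`unsigned = TRUE` available):
  "change relative to day 1 / the preceding day" is read as a difference,
  and the sign carries clinically relevant direction.
* The sepsis-at-admission window is two-sided, [−24 h, +24 h], matching a
  window "around" admission; laterality is configurable. The acute
  organ-dysfunction criterion is optional (`sofa_threshold`): with the
  retrospective baseline-of-zero convention, essentially every scored ICU
  admission meets a ≥ 2-point rise, so the infection-timing criterion is
  the binding one.
* The day-30 boundary is inclusive (death on day 30 counts).
* Exclusion filters run in the order invalid-SSN → external-ICU → age;
  order affects only per-step tallies, not the final cohort. Published
  flow counts whose flag totals exceed the implied exclusions are
  reconciled by overlapping flags in the fixture generator.
* Mean and maximum stay-level scores use **all** ICU days, not only days
  1–7, matching their definitions.
* `glm` fits that feed exact-equivalence checks use IRLS tolerance
  10^-12^; bootstrap and simulation procedures take explicit seeds and are
  bit-reproducible; the pipeline writes a manifest (seed, config, table
  versions) and re-runs byte-identically.
* Degenerate inputs: empty stays produce empty outputs (not errors);
  single-class outcomes are errors for discrimination metrics; perfect
  separation yields zero DeLong variance with a degenerate but finite CI.

# Problem sizes used by the test-suite

Unit and property tests run on small randomized instances (≤ 5 admissions
× 3 days for engine-oracle equivalence; n ≤ 200 for AUROC oracle
equivalence, 1,000 instances). Recovery simulations use 200 replicates of
n = 5,000 for the per-point OR, 50 replicates of 300 clusters × 5 days for
the random-intercept SD, and 15 generator seeds of n = 20,000 admissions
for the declining-discrimination trend. These sizes give Monte-Carlo error
comfortably inside the asserted bands while keeping the default test run
fast.

# Known limitations

The shipped SOFA-2 cut-offs are structural defaults, not a certified
transcription; real deployments must validate them. The engine's
worst-case concurrent-vasopressor assumption can overstate
noradrenaline-equivalent exposure when infusions do not overlap at their
peaks. LOCF dampens day-to-day variation by construction — the
chained-equations sensitivity path exists precisely to quantify that. The
chained-equations imputer uses normal linear models, adequate for the
roughly log-scale-symmetric aggregates it sees here but not a general
replacement for a full multiple-imputation framework. Finally, the
generator's single latent severity cannot reproduce domain-specific
failure trajectories (e.g. isolated liver failure), so domain-level
results on synthetic data are structural checks only.
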