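---
title: "Methods: from meta-analytic relative risks to preventable burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from meta-analytic relative risks to preventable burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dairyburden)
```

## The model

`dairyburden` implements a theoretical comparative-risk calculation in three
stages.

**1. Evidence inclusion.** The input is a registry of summary relative risk
estimates (SRREs): pooled high-vs-low intake relative risks from
meta-analyses of prospective studies, one row per (outcome, exposure
category) with a 95% CI, study count, heterogeneity statistics and source
metadata. Two deterministic gates decide inclusion:

- *significance*: the CI must lie entirely below the null
  (`ci_upper < 1`). A CI touching 1.0 is excluded — such findings are at
  best marginally significant, and the strict inequality is the
  conservative reading. Harmful-direction estimates are excluded by the
  same rule: the workflow is defined for protective exposures only, and
  routing an increased-risk estimate into a "preventive" fraction would be
  a sign error, not an analysis.
- *burden availability*: the outcome must have a cause-level DALY entry;
  outcomes without one (osteoporosis, obesity in the US 2019 catalogue)
  cannot enter a burden calculation and are dropped with a logged warning
  rather than an error.

When several meta-analyses cover one topic, the most recently published
wins; ties break by study count, then first author. "Most analytically
comprehensive" has no unique measurable definition, so study count is used
as its proxy — the only quantity in the registry that orders comprehensiveness
at all. The final alphabetic tie-break exists purely to make selection a
pure function of the candidate set, invariant to row order.

**2. Fractions.** For each included estimate and each exposure prevalence
`Pr` in the scenario grid:

- preventive fraction `PF = Pr (1 − RR)` — the proportion of disease
  prevented if a fraction `Pr` of the population consumed dairy at the
  studies' highest intake stratum;
- population attributable risk proportion
  `PARP = Pr (RR_I − 1) / [1 + Pr (RR_I − 1)]` with `RR_I = 1/RR` — the
  proportion of current disease attributable to *low* intake, Levin's
  attributable fraction applied to the inverted estimate.

Both are computed at full floating precision; the algebraic identity
`PARP = Pr(1 − RR) / (RR + Pr(1 − RR))` serves as an independent oracle in
the tests (agreement to 1e−12 relative error). For `RR < 1` and
`0 < Pr < 1` the PARP strictly dominates the PF, both increase in `Pr` and
in `1 − RR`, and both vanish at the null — all property-tested.

**3. Burden.** Each fraction is multiplied by the cause-level DALY total:
`preventable = PF × DALY`, `attributable = PARP × DALY`. The DALY follows
the WHO decomposition `DALY = YLL + YLD`, `YLL = N × L` (deaths × standard
loss years) and `YLD = I × DW × L` (incident cases × disability weight ×
duration). The engine accepts either pre-aggregated cause totals (the usual
pathway — the packaged US 2019 figures are WHO aggregates) or a stratified
table of raw `N, L, I, DW, L` inputs per (cause, sex, age group, year),
collapsed by `aggregate_burden()`. Age-weighting and time-discounting are
omitted, matching the convention of the aggregates consumed. Loss-function
years and disability weights are opaque inputs: the package never hard-codes
a life table.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| prevalence grid | 0.15, 0.25, 0.35, 0.50 | proportion of population at high intake | conservative range spanning current US adherence (~12% meet dairy recommendations) up to an ambitious half-population scenario |
| significance rule | `ci_upper < 1` | — | strict CI-below-null; touching the null is excluded |
| display rounding | 2 dp (percents), 1 dp (DALYs) | — | matches the published tables; applied only at report time |
| cohort `baseline_risk` | 0.05 | probability | a realistic cumulative incidence for chronic disease over follow-up; any value with `baseline_risk × RR_I ≤ 1` is valid |
| cohort size `n` | 10^6 | persons | binomial SE of the empirical PAF ≈ 0.002 at these rates, small enough to resolve PARP differences between grid cells |

## What the synthetic generators emulate — and what they do not

`generate_evidence()` draws true protective RRs log-normally, truncated to
(0, 1), with symmetric log-scale CIs of configurable width and plausible
study counts: the statistical *shape* of a protective-only SRRE registry.
It does not simulate meta-analytic pooling (random-effects weights,
between-study heterogeneity feeding the CI), publication bias, or correlated
estimates across outcomes — SRREs are drawn directly, because SRREs are
inputs to this pipeline, never computed by it.

`generate_daly_inputs()` produces stratified burden inputs across sex × age
strata with Poisson death/incidence counts, loss years in 5–45, disability
weights uniform on [0, 1] and durations 0.5–20 years — wide, plausible
ranges chosen once to exercise the YLL/YLD algebra, not to mimic any
particular cause's epidemiology.

`simulate_cohort()` is the empirical ground for the PARP formula: binary
exposure (LOW intake — the harmful direction, avoiding sign confusion
between PF and PARP validation) at prevalence `pr`, and a binary
cumulative-incidence outcome at `baseline_risk` (unexposed) or
`baseline_risk × RR_I` (exposed). Group sizes and case counts are drawn as
binomial counts — the exact sampling distribution of the individual-level
model at O(1) cost. `empirical_paf()` then computes the model-free excess
fraction `(observed − N × rate_unexposed)/observed`, which the tests compare
with the closed-form PARP within three delta-method binomial standard
errors, across a (Pr, RR) grid spanning the registry's range (RR 0.68–0.94,
Pr 0.15–0.50) at n = 10^6 per cell.

Passing these tests shows the algebra and its implementation are correct
for the stated model. It does *not* validate the epidemiological
assumptions on real data: that the SRREs are causal, transportable to the
US population, or free of confounding — see limitations.

## Numerical choices

- **Rounding.** Base R rounds half to even; the published tables round half
  up (0.0257879… prints as 2.58%). `round_half_up()` therefore implements
  commercial rounding, with a relative epsilon (1e−9) guarding against
  binary floating point: products such as 0.0135 × 4,275,100 are exactly
  57,713.85 in decimal but sit a few ulps below the .5 boundary as doubles,
  and must round to 57,713.9. DALY cells are rounded on the product of the
  *unrounded* fraction and the total — rounding the fraction first does not
  reproduce the published burden table.
- **Known discrepancies.** Two published cells are inconsistent with the
  stated formula: low-fat dairy / breast cancer at Pr 35% prints a 4.80%
  preventive fraction (Pr(1−RR) gives 5.60%; 4.80% corresponds to Pr 30%)
  and a 62,016.0 DALY product (formula: 72,352.0). The pipeline always
  outputs the formula values; the golden harness
  (`verify_against_golden()`) reports these two cells separately, so a
  faithful run shows zero unexplained mismatches and exactly two documented
  ones.
- **Domain guards.** `rr > 1` in the preventive fraction and `RR_I < 1` in
  the PARP raise typed errors rather than returning negative fractions. CI
  propagation (`interval_fractions()`) is the one place a null-crossing
  bound is tolerated: the conservative bound is clamped to 0 and flagged,
  since a CI is an input's uncertainty, not an inclusion decision. A
  degenerate CI equal to the point estimate reproduces the point fractions.
- **Determinism.** The analysis path draws no random numbers; identical
  inputs produce byte-identical CSV reports. Seeds exist only in the
  synthetic module, where identical seeds reproduce identical draws.

## Design decisions that were genuinely open

- *Interval propagation is advisory.* The published analysis reports point
  estimates only; `interval_fractions()` exists because CI-substitution is
  cheap and informative, but it is excluded from golden comparisons and
  flagged as non-published output.
- *Exclusions are data, not side effects.* Every row dropped by a gate is
  recorded in an `exclusions` table with the triggering rule
  (`not_significant`, `no_daly_entry`, `superseded`) and surfaced as
  messages, making the inclusion funnel auditable.
- *The low-fat/coronary-heart-disease case* (a significant estimate whose
  outcome has no overall-CVD burden entry) is handled by the generic
  catalogue gate, not a special case.

## Problem sizes

The test suite runs the full canonical analysis (16-row registry → 14
estimates × 4 scenarios = 56 cells), dense algebraic grids of ~40,000
(pr, rr) pairs, and 21 microsimulated cohorts of 10^6 individuals; the
whole suite completes in a few seconds because cohort draws are binomial
counts.

## Limitations

- The analysis is theoretical: it assumes the meta-analytic associations
  are causal and transportable, performs no causal assessment, and inherits
  every limitation of self-reported dietary exposure data.
- Single-factor attributable fractions: no adjustment for competing risk
  factors or interactions; summed attributable fractions across factors can
  exceed 100%.
- No dose–response integration: exposure is a binary high-vs-low contrast
  at an assumed prevalence, not an integral over a consumption
  distribution.
- Uncertainty in the SRREs propagates to the fractions only through the
  advisory interval bounds; the burden tables carry no confidence
  intervals, mirroring the published point-estimate design.
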