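---
title: "Methods: building and validating the psoriasis relapse risk score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and validating the psoriasis relapse risk score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psorelapse)
```

## The problem and the model

Many psoriasis patients who reach remission on a biologic relapse within
six months of stopping it. The score implemented here converts
meta-analytically pooled relative risks of relapse into an additive
clinical point system: for each risk factor the model weight is
$\beta = \ln \mathrm{RR}$, and the point value is $10\,\beta$, rounded.
A patient's total score is the sum over eight factors — BMI, smoking,
disease course over two years, psoriatic arthritis, higher lesion
relief (PASI 90 achieved), faster lesion relief (PASI 75 within eight
weeks), previous biologic exposure, and treatment course (with courses
of at most 10.75 months scored) — and ranges from 0 to 23.5 in half-point
steps. Higher totals mean higher 6-month relapse risk; cutpoints at 6,
11.25 and 17.5 points define low, intermediate, high and very-high risk
groups.

## Meta-analytic pooling

Per-study effects arrive as OR, RR or HR with 95% CIs. Everything is
mapped to the RR scale first: HR is used as RR over the fixed 183-day
horizon; OR is converted with the Zhang–Yu formula
$\mathrm{RR} = \mathrm{OR} / ((1-p_0) + p_0\,\mathrm{OR})$, with $p_0$
the study's control-group event proportion, defaulting to 0.447 (the
6-month relapse proportion of the validation-style population) when a
study does not report one. Each conversion is recorded in the output.

Pooling is inverse-variance on the log scale, with the log standard
error recovered from the CI as
$(\ln c_{hi} - \ln c_{lo}) / (2 \times 1.959964)$. A fixed-effects fit
supplies Cochran's $Q$ (with $k-1$ degrees of freedom) and
$I^2 = \max(0, (Q-(k-1))/Q)$; between-study variance $\tau^2$ is the
DerSimonian–Laird moment estimator. The model gate follows the usual
heterogeneity rule: random effects when the $Q$ p-value is below 0.10
or $I^2$ exceeds 50%, fixed effects otherwise; a sensitivity switch
re-pools under the other model. DerSimonian–Laird was chosen over REML
because it is the conventional default for this gate-style workflow and
is exactly reproducible by hand, which the test suite exploits: pooled
estimates are checked to six decimals against a step-by-step
transcription of the formulas. The fitting itself is delegated to
`metafor`.

When a study reports several estimates for one factor, the
deduplication filter keeps the most adjusted estimate, breaking ties by
the longest follow-up. Factors pass a collinearity screen before
scoring: only factors whose pooled CI lies on one side of the null are
kept (a bound printed exactly at 1.00 — an artifact of two-decimal CI
rounding — still counts), and of each overlapping pair (weight vs BMI,
duration in years vs the binary duration over two years) the redundant
member is dropped, leaving the eight model factors. No publication-bias
testing is performed: with at most a handful of studies per factor such
tests are uninformative.

## From pooled RRs to points

Binary factors score $|10 \ln \mathrm{RR}|$ on their scored stratum.
The absolute value matters for the two protective remission factors
(RR 0.60 and 0.73) and for treatment course (RR 0.70 per course beyond
10.75 months, so the *short* course carries the 3.5 points). BMI is
pooled per kg/m², so its strata score
$|10 \ln(\mathrm{RR}) \cdot \Delta|$ with $\Delta$ the stratum's offset
from the reference in units — 5 for 24–27.99 and 10 for ≥ 28 kg/m²,
which reproduces the published 1.5 and 3 points from RR 1.03.

No single rounding rule reproduces the published table:
$10\ln 1.71 = 5.37$ prints as 5 (nearest integer), while
$10|\ln 0.70| = 3.57$ prints as 3.5 (nearest half). Rounding is
therefore a named policy argument, the *canonical* table shipped with
the package is authoritative for scoring patients, and the derived
table is used for verification: every stratum's unrounded
$|10\beta|$-scale value must sit within 0.5 points of the canonical
entry (the worst gap, 0.365, is the duration factor).

One genuine ambiguity is documented rather than resolved: the published
table awards 5 and 3 points to *achieving* higher/faster lesion relief
even though both pool as protective. The canonical file ships exactly
as printed — the printed very-high range 18–23.5 is only consistent
with the printed rows — and
`canonical_score_table(invert_remission = TRUE)` provides the
risk-direction variant that moves those points to the "No" strata.
Neither encoding is asserted as the source's intent.

## Scoring and risk groups

Each factor contributes exactly one stratum's points; strata predicates
are machine-readable and checked to match exactly once per patient. At
the BMI boundary the published strata ("24 ~ 27.99" and "≥ 28") are
read as $[24, 28)$ and $[28, \infty)$, so 27.995 kg/m² falls in the
middle stratum. Risk-group intervals are closed above on the lower
group — $[0,6]$, $(6,11.25]$, $(11.25,17.5]$, $(17.5,\infty)$ — which
resolves the overlap in the published group labels and matches the
Youden semantics "score above 11.25 predicts relapse" (11.25 is a
midpoint of the half-point lattice, between 11 and 11.5). Outcome
fields are optional for pure scoring; validation requires them.

## Validation machinery

**ROC / Youden.** The AUC and its 95% CI come from `pROC` (DeLong
variance); the test suite verifies the AUC equals brute-force pairwise
concordance with ties counted one half, exactly, on cohorts up to
n = 200. Cutoff candidates are the midpoints between consecutive
distinct observed scores; the optimal cutoff maximises
$J = \text{sens} + \text{spec} - 1$, with exact ties broken toward the
higher-specificity (larger) cutoff. The midpoint convention is why a
published cutoff like 11.25 can arise from half-point scores.

**Decision curve.** Net benefit of the model at threshold $t$ is
$TP/n - (FP/n)\, t/(1-t)$, with treat-all
($\pi - (1-\pi)t/(1-t)$, $\pi$ the prevalence) and treat-none (0) as
references, over the threshold band 0.254–0.597 in steps of 0.001 —
the range of 6-month relapse rates reported across discontinuation
studies. The score is unitless, so probabilities come from a monotone
logistic calibration of outcome on score fitted on the same cohort;
this mapping is a documented stand-in, since no canonical mapping
exists for a point score.

**Survival.** Product-limit relapse-free curves per risk group
(cumulative risk $1 - S(t)$) and proportional-hazards contrasts against
the low-risk group with Efron tie handling, via `survival`. With no
censoring the cumulative risk reproduces the empirical cumulative
incidence exactly, which the tests check against an eight-patient hand
computation. Raw two-sided p-values are reported without multiplicity
adjustment, matching how such three-contrast comparisons are
conventionally presented. Follow-up is administratively censored at
183 days.

## The synthetic cohort generator

Because the real 416-patient validation cohort is not public, the
generator emulates its marginal structure: BMI strata
41.1/40.9/18% (uniform within stratum), smoking 42.8%, disease course
over two years 89.9%, PsA 9.4%, prior biologics 17.3%, faster relief
73.3%, higher relief 84.4%; treatment course log-normal with median 10
months and quartiles 8 and 12 (meanlog $\ln 10$, sdlog
$(\ln 12 - \ln 8)/(2 z_{0.75}) \approx 0.30$). Relapse times are
exponential with rate
$\lambda_i = \lambda_0 \exp(\gamma\,(s_i - \bar s))$; $\lambda_0$ is
calibrated by root-finding so the cohort's expected 183-day relapse
probability equals 0.447, and the exact per-patient probabilities are
retained so the *oracle* AUC — the probability-weighted concordance the
score achieves in expectation — is computable without Monte-Carlo
error. The default slope $\gamma = 0.30$ per point was calibrated once
so the oracle AUC is ≈ 0.80 under the default marginals, a
property-level stand-in for the published discrimination, not a
reproduction of it.

What the generator deliberately does not emulate: predictor
correlations (the source quantifies none; independence is the only
defensible default, and it concentrates the synthetic score around a
mean of ≈ 15 points, far from the published group sizes), PASI
trajectories, drug-specific effects, and non-constant hazards. Passing
recovery tests on synthetic cohorts therefore demonstrates that the
machinery estimates what the generator encodes — not that the published
cohort-dependent numbers (AUC 0.796, cutoff 11.25, group hazard
ratios) are reproduced; those depend on the unavailable patient data.
A side effect of the independence assumption is that the low-risk tail
is thin (about 1.5% of patients), so hazard-ratio contrasts against
the low-risk reference are estimated on larger simulated cohorts
(n = 20 000 in the acceptance script) while discrimination and
calibration checks use n = 5 000; with zero events in the reference
group the contrast is reported as undefined rather than extrapolated.

## Numerical conventions

The confidence level is fixed at 95% with $z = 1.959964$ throughout.
Rounding of points is half-up (so 2.25 → 2.5 on the half lattice), in
steps of 0.5 to match both the published table and the 11.25 cutoff.
Degenerate inputs fail fast with named errors: single-study pooling,
mixed factors, nonpositive ratios, baseline risks outside (0,1),
BMI outside (10, 70) kg/m², single-class outcomes, unreachable
calibration targets (0 or 1). All randomness flows from the single
seed in the generator or pipeline configuration; identical
configurations produce byte-identical outputs.

## Limitations

The OR→RR conversion and the per-study extraction rules of the source
are not published in its main text; the Zhang–Yu conversion and the
deduplication rule here are documented stand-ins. The logistic
score-to-probability mapping for the decision curve is likewise a
choice, not an attribution. The synthetic cohorts share only marginals
with the real population, so external performance claims cannot be
made from them; the package's exactly reproducible surface is the
score-construction arithmetic, the table totals, the factor screen,
and the internal consistency of the validation machinery.
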