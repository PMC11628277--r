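# psorelapse

Tools for building and validating an additive clinical point score for
the risk of psoriasis relapse within six months of discontinuing
biologic therapy.

Relapse after stopping a biologic is common — roughly half of patients
who reached PASI 75 remission relapse within six months — and clinicians
lack simple tools to tell high-risk patients (candidates for long-term
maintenance) from low-risk ones (candidates for dose reduction). The
package is aimed at biostatisticians and dermatology researchers who
want to reproduce, stress-test or extend this kind of score.

## The model

For each risk factor with pooled relative risk RR, the model weight is

    beta = ln(RR),    points = |10 * beta|  (rounded)

and a patient's total score is the sum over eight factors:

| Factor | Strata | Points |
|---|---|---|
| BMI (kg/m²) | <24 / 24–27.99 / ≥28 | 0 / 1.5 / 3 |
| Smoking | no / yes | 0 / 1 |
| Disease course | ≤2 y / >2 y | 0 / 5 |
| Psoriatic arthritis | no / yes | 0 / 1 |
| Higher lesion relief (PASI 90) | no / yes | 0 / 5 |
| Faster lesion relief (PASI 75 in 8 wk) | no / yes | 0 / 3 |
| Previous biologic exposure | no / yes | 0 / 2 |
| Treatment course | ≤10.75 mo / >10.75 mo | 3.5 / 0 |

Totals range 0–23.5 in half-point steps; cutpoints 6 / 11.25 / 17.5
define low, intermediate, high and very-high risk groups.

Upstream, per-study effects (OR/RR/HR + 95% CI) are converted to RRs
and pooled per factor with heterogeneity-gated fixed/random-effects
meta-analysis (Cochran's Q, I², DerSimonian–Laird τ²; random effects
when p < 0.10 or I² > 50%). Downstream, a cohort validation computes
ROC/AUC with DeLong CI, the Youden-optimal cutoff, decision-curve net
benefit over the 0.254–0.597 threshold band, and Kaplan–Meier
risk-group curves with proportional-hazards contrasts. A calibrated
synthetic cohort generator emulates the validation population's
marginal structure so the whole pipeline runs without patient data.

## Worked example

```r
library(psorelapse)

# score one patient against the canonical table
p <- data.frame(bmi = 25, smoker = TRUE, disease_course_gt2y = TRUE,
                psa = FALSE, higher_relief = TRUE, faster_relief = FALSE,
                prior_biologics = FALSE, treatment_months = 11)
score_cohort(p)[, c("total_score", "risk_group")]
#>   total_score risk_group
#> 1        12.5       high
```

The 12.5 is the hand-checkable sum 1.5 (BMI 25) + 1 (smoking) + 5
(course > 2 y) + 5 (PASI 90 achieved); 12.5 > 11.25 puts the patient
in the high-risk group.

```r
# synthetic validation-style cohort, scored and validated end to end
cohort <- generate_cohort(generator_config(n = 5000, seed = 42))
scored <- score_cohort(cohort)
validate_cohort(scored)
#> Validation report (n = 5000, relapse prevalence 0.457)
#> AUC 0.798 (95% CI 0.786-0.810); cutoff 15.75: sens 0.698, spec 0.747
#> Hazard ratios vs low-risk:
#>    risk_group        hr     ci_low    ci_high      p_value
#>  intermediate  2.391306  0.7512896   7.611374 1.399772e-01
#>          high 12.044289  3.8793384  37.394235 1.667850e-05
#>     very_high 39.045387 12.5681964 121.301593 2.351024e-10
#> Decision curve above both references on 100% of the 0.254-0.597 band

oracle_auc(cohort)   # the AUC the generator encodes: 0.803
```

The estimated AUC (0.798) recovers the generator's oracle AUC (0.803)
within Monte-Carlo error; the relapse prevalence sits near the 0.447
calibration target; hazard ratios rise monotonically across risk
groups; and the decision curve dominates both treat-all and treat-none
across the plausible relapse-rate band. The synthetic optimal cutoff
(15.75) and the hazard-ratio magnitudes are properties of the
synthetic score distribution, not reproductions of the published
cohort's values — see the methods vignette
(`vignettes/relapse-risk-model.Rmd`).

`run_pipeline(pipeline_config(out_dir = "results"))` executes the whole
chain (pooled RRs → derived table + verification → scored cohort →
validation report) and writes every stage output plus a run manifest.
A thin command-line wrapper with `simulate` / `meta` / `build-score` /
`score` / `validate` / `run-all` subcommands is in
`inst/scripts/psorelapse.R`.

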