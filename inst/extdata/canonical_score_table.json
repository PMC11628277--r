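{
  "version_tag": "canonical-v1",
  "provenance": "canonical",
  "items": [
    {"factor_id": "bmi", "stratum_label": "<24", "field": "bmi", "op": "lt", "value": 24, "points": 0},
    {"factor_id": "bmi", "stratum_label": "24 ~ 27.99", "field": "bmi", "op": "between", "value": 24, "value2": 28, "points": 1.5},
    {"factor_id": "bmi", "stratum_label": ">=28", "field": "bmi", "op": "ge", "value": 28, "points": 3},
    {"factor_id": "smoking", "stratum_label": "No", "field": "smoker", "op": "eq_false", "points": 0},
    {"factor_id": "smoking", "stratum_label": "Yes", "field": "smoker", "op": "eq_true", "points": 1},
    {"factor_id": "disease_course", "stratum_label": "<=2 years", "field": "disease_course_gt2y", "op": "eq_false", "points": 0},
    {"factor_id": "disease_course", "stratum_label": ">2 years", "field": "disease_course_gt2y", "op": "eq_true", "points": 5},
    {"factor_id": "psa", "stratum_label": "No", "field": "psa", "op": "eq_false", "points": 0},
    {"factor_id": "psa", "stratum_label": "Yes", "field": "psa", "op": "eq_true", "points": 1},
    {"factor_id": "higher_relief", "stratum_label": "No", "field": "higher_relief", "op": "eq_false", "points": 0},
    {"factor_id": "higher_relief", "stratum_label": "Yes", "field": "higher_relief", "op": "eq_true", "points": 5},
    {"factor_id": "faster_relief", "stratum_label": "No", "field": "faster_relief", "op": "eq_false", "points": 0},
    {"factor_id": "faster_relief", "stratum_label": "Yes", "field": "faster_relief", "op": "eq_true", "points": 3},
    {"factor_id": "prior_biologics", "stratum_label": "No", "field": "prior_biologics", "op": "eq_false", "points": 0},
    {"factor_id": "prior_biologics", "stratum_label": "Yes", "field": "prior_biologics", "op": "eq_true", "points": 2},
    {"factor_id": "treatment_course", "stratum_label": "<=10.75 months", "field": "treatment_months", "op": "le", "value": 10.75, "points": 3.5},
    {"factor_id": "treatment_course", "stratum_label": ">10.75 months", "field": "treatment_months", "op": "gt", "value": 10.75, "points": 0}
  ]
}
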