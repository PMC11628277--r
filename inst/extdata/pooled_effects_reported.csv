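factor_id,rr,ci_low,ci_high,source
bmi,1.03,1.00,1.07,reported
smoking,1.09,1.02,1.17,reported
disease_course,1.71,1.23,2.36,reported
psa,1.13,1.07,1.19,reported
faster_relief,0.73,0.51,0.92,reported
higher_relief,0.60,0.40,0.91,reported
prior_biologics,1.19,1.04,1.37,reported
treatment_course,0.70,0.64,0.76,reported
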