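factor_id,rr,ci_low,ci_high,source
weight,1.02,1.01,1.04,synthetic
disease_course_years,1.05,1.01,1.10,synthetic
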