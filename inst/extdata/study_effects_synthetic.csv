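study_id,factor_id,effect_type,estimate,ci_low,ci_high,n,baseline_risk,adjustment_rank,followup_months
studyA,bmi,RR,1.04,1.01,1.08,220,,2,12
studyB,bmi,RR,1.02,1.00,1.05,705,,1,6
studyA,smoking,OR,1.25,1.02,1.53,220,0.45,2,12
studyB,smoking,RR,1.10,1.01,1.20,705,,1,6
studyC,smoking,HR,1.08,0.98,1.19,233,,1,6
studyA,disease_course,OR,2.40,1.35,4.27,220,0.45,2,12
studyB,disease_course,RR,1.55,1.10,2.18,705,,1,6
studyD,disease_course,RR,1.90,1.15,3.14,169,,1,6
studyB,psa,RR,1.12,1.05,1.20,705,,1,6
studyC,psa,HR,1.15,1.04,1.27,233,,1,6
studyA,higher_relief,RR,0.62,0.42,0.92,220,,2,12
studyD,higher_relief,RR,0.58,0.35,0.96,169,,1,6
studyB,faster_relief,RR,0.72,0.50,0.93,705,,1,6
studyC,faster_relief,RR,0.76,0.52,0.99,233,,1,6
studyB,prior_biologics,RR,1.22,1.03,1.45,705,,1,6
studyC,prior_biologics,HR,1.15,0.99,1.34,233,,1,6
studyB,treatment_course,RR,0.70,0.63,0.78,705,,1,6
studyC,treatment_course,HR,0.71,0.62,0.81,233,,1,6
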