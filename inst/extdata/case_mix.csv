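# Default case mix, version 1: whole-cohort percentages per attribute.
# Percentages are renormalized to sum to 1 per attribute at load time
# (printed columns sum to 99.9-100.1 because of rounding).
attribute,category,pct
reason,fever,14.2
reason,respiratory,16.3
reason,digestive,15.0
reason,trauma,13.0
reason,other,41.5
priority,high,13.1
priority,moderate,57.3
priority,low,29.6
blood_tests,0,83.7
blood_tests,1,15.6
blood_tests,2,0.8
imaging,0,72.5
imaging,1,25.1
imaging,2,2.1
imaging,3,0.3
specialist,0,77.2
specialist,1,19.6
specialist,2,2.9
specialist,3,0.4
treatment,0,86.9
treatment,1,12.6
treatment,2,0.6
senior_evals,0,33.6
senior_evals,1,51.0
senior_evals,2,15.3
disposition,home,77.4
disposition,short_stay,10.9
disposition,ward,9.9
disposition,lwbs,1.3
disposition,picu,0.5
sex,male,52.6
sex,female,47.4
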