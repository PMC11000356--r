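# Care-stage interval calibration, version 1.
# Printed median [q1-q3] in minutes per arm; zero_inflated marks stages whose
# printed median/lower quartile is 0 and which need a point-mass-at-zero fit.
stage,arm,median,q1,q3,zero_inflated
admission_to_triage,control,15,8,23,0
admission_to_triage,optimum,15,8,27,0
triage_to_first_eval,control,23,11,45,0
triage_to_first_eval,optimum,21,10,50,0
first_eval_to_junior,control,29,19,45,0
first_eval_to_junior,optimum,30,19,47,0
admission_to_senior,control,71,47,102,0
admission_to_senior,optimum,76,49,118,0
blood_prescription_to_sampling,control,40,25,60,0
blood_prescription_to_sampling,optimum,41,20,75,0
blood_sampling_to_results,control,122,73,171,0
blood_sampling_to_results,optimum,129,81,180,0
imaging_prescription_to_results,control,63,35,118,0
imaging_prescription_to_results,optimum,59,35,100,0
specialist_prescription_to_consult,control,39,10,110,0
specialist_prescription_to_consult,optimum,45,8,106,0
treatment_prescription_to_admin,control,25,12,48,0
treatment_prescription_to_admin,optimum,21,9,43,0
final_decision_to_end_of_care,control,0,0,97,1
final_decision_to_end_of_care,optimum,0,0,88,1
end_of_care_to_discharge,control,33,16,73,0
end_of_care_to_discharge,optimum,29,14,62,0
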