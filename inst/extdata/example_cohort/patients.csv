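patient_id,age_at_admission,sex,admission_date,discharge_date,n_comorbidities,n_prior_hospitalizations,target_drug_classes
p001,57.3,female,2022-02-10,2022-02-18,6,2,sildenafil;ambrisentan
p002,0.33,male,2022-05-02,2022-05-05,1,1,beraprost
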