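patient_id,drug_name,start,stop,is_target_pah_drug,stopped_abruptly
p001,sildenafil,2022-02-10T10:00:00Z,2022-02-18T10:00:00Z,TRUE,FALSE
p001,ondansetron,2022-02-12T10:00:00Z,2022-02-14T10:00:00Z,FALSE,FALSE
p002,beraprost,2022-05-02T10:00:00Z,2022-05-05T10:00:00Z,TRUE,FALSE
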