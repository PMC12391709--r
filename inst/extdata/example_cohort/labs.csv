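patient_id,analyte,value,timestamp
p001,hemoglobin,104,2022-02-11T08:30:00Z
p001,creatinine,64,2022-02-10T09:00:00Z
p001,creatinine,151,2022-02-15T09:00:00Z
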