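patient_id,term,timestamp
p001,nausea,2022-02-12T14:00:00Z
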