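patient_id,sb,ogm,lr
Pt7,1400,1223,1192
Pt10,4746,3226,3363
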