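test_name,ref_low,ref_high,unit
ALT,7,40,IU/mL
AST,10,40,IU/mL
platelets,150,400,10^9/L
bilirubin total,0.1,1.2,mg/dL
INR,0.8,1.1,ratio
albumin,3.5,5.0,g/dL
creatinine,0.6,1.2,mg/dL
hemoglobin,12,17,g/dL
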