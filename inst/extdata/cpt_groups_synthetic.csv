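start,end,group
10021,19499,Surgery-Integumentary
20100,29999,Surgery-Musculoskeletal
30000,32999,Surgery-Respiratory
33010,37799,Surgery-Cardiovascular
38100,39599,Surgery-Hemic-Lymphatic
40490,49999,Surgery-Digestive
50010,53899,Surgery-Urinary
70010,79999,Radiology
80047,89398,Pathology-Laboratory
90935,90999,Dialysis
99201,99499,Evaluation-Management
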