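system,code,phecode,phecode_label
ICD10,E11.9,250.2,Type 2 diabetes
ICD9,250.00,250.2,Type 2 diabetes
ICD10,I10,401.1,Essential hypertension
ICD9,401.9,401.1,Essential hypertension
ICD10,E78.5,272.1,Hyperlipidemia
ICD9,272.4,272.1,Hyperlipidemia
ICD10,E66.9,278.1,Obesity
ICD9,278.00,278.1,Obesity
ICD10,G47.33,327.3,Obstructive sleep apnea
ICD10,K21.9,530.11,Gastroesophageal reflux disease
ICD10,Z72.0,318.0,Tobacco use disorder
ICD9,305.1,318.0,Tobacco use disorder
ICD10,J45.909,495.0,Asthma
ICD10,F41.9,300.1,Anxiety disorder
ICD10,F32.9,296.2,Depression
ICD10,N39.0,591.0,Urinary tract infection
ICD10,J18.9,480.0,Pneumonia
ICD10,A41.9,994.2,Sepsis
ICD10,I48.91,427.21,Atrial fibrillation
ICD10,C80.1,195.0,Malignant neoplasm unspecified
ICD10,E55.9,261.4,Vitamin D deficiency
ICD10,K76.0,571.5,Other chronic nonalcoholic liver disease
ICD10,K75.81,571.5,Other chronic nonalcoholic liver disease
ICD10,K76.9,571.5,Other chronic nonalcoholic liver disease
ICD9,571.5,571.5,Other chronic nonalcoholic liver disease
ICD9,571.8,571.5,Other chronic nonalcoholic liver disease
ICD9,571.9,571.5,Other chronic nonalcoholic liver disease
ICD10,C22.0,155.0,Cancer of liver
ICD9,155.0,155.0,Cancer of liver
ICD10,N18.3,585.3,Chronic kidney disease
ICD9,585.3,585.3,Chronic kidney disease
ICD10,I25.10,411.4,Coronary atherosclerosis
ICD9,414.01,411.4,Coronary atherosclerosis
ICD10,I21.0,411.2,Myocardial infarction
ICD9,410.71,411.2,Myocardial infarction
ICD10,K74.60,571.51,Cirrhosis of liver
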