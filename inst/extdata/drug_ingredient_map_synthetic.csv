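drug_name,ingredient
metformin,metformin
Glucophage,metformin
insulin glargine,insulin
insulin,insulin
aspirin,aspirin
lisinopril,lisinopril
amlodipine,amlodipine
metoprolol,metoprolol
atorvastatin,atorvastatin
Lipitor,atorvastatin
omeprazole,omeprazole
Prilosec,omeprazole
acetaminophen,acetaminophen
Tylenol,acetaminophen
oxycodone,oxycodone
gabapentin,gabapentin
furosemide,furosemide
Lasix,furosemide
albuterol,albuterol
Ventolin,albuterol
fluticasone,fluticasone
cholecalciferol,cholecalciferol
vitamin D,cholecalciferol
amiodarone,amiodarone
methotrexate,methotrexate
tamoxifen,tamoxifen
valproate,valproate
prednisone,prednisone
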