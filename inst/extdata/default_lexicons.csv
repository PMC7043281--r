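concept,term
steatosis,steatosis
steatosis,steatohepatitis
steatosis,fatty liver
steatosis,hepatic steatosis
steatosis,NASH
steatosis,NAFLD
death,deceased
death,expired
death,passed away
death,death
cirrhosis,cirrhosis
cirrhosis,cirrhotic
cirrhosis,hepatic decompensation
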