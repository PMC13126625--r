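smiles,protein_id,activity_type,value_nM,qualifier
Cc1ccccc1,TOYPROT,IC50,2000,
Oc1ccccc1,TOYPROT,Ki,85,
Clc1ccccc1,TOYPROT,IC50,10000,
CCCCCC,TOYPROT,IC50,250000,
Nc1ccccc1,TOYPROT,qualitative,,active
CCO,OTHERPROT,Kd,50000,
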