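material,test,experimental_value,unit
amlodipine_besylate,bfe,209.0,mJ
smcc_90,bfe,235.0,mJ
pvp_k25,bfe,121.0,mJ
ccm_na,bfe,341.0,mJ
st_mg,bfe,16.7,mJ
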