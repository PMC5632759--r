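source,target,type
VV-A11_198,LCMV-GP_34,strong
LCMV-GP_34,VV-A11_198,strong
VV-A11_198,LCMV-GP_118,weak
VV-A11_198,LCMV-NP_205,weak
VV-A11_198,PV-NP_205,weak
VV-A11_198,VV-E7_130,weak
LCMV-NP_205,PV-NP_205,strong
PV-NP_205,LCMV-NP_205,strong
VV-A11_198,OVA_258,none
LCMV-GP_118,VV-E7_130,none
LCMV-NP_205,LCMV-NP_205-V3A,none
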