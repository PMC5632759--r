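id,sequence,mhc
VV-A11_198,AIVNYANL,H-2Kb
LCMV-GP_34,AVYNFATC,H-2Kb
LCMV-GP_118,ISHNFCNL,H-2Kb
VV-E7_130,STLNFNNL,H-2Kb
LCMV-NP_205,YTVKYPNL,H-2Kb
PV-NP_205,YTVKFPNM,H-2Kb
OVA_258,SIINFEKL,H-2Kb
LCMV-NP_205-V3A,YTAKYPNL,H-2Kb
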