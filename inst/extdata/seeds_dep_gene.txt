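# Differentially expressed proteins: stroke non-survivors vs survivors
SERPINC1
PROC
PROS1
VWF
F8
FBG
CRP
ALB
TNF
IL10
IL6
TGFB1
FTH1
VCAM1
SELE
# Mortality-associated genes from the literature
SERPINE1
ITGB3
MPG
PROCR
HABP2
COL3A1
FGB
VKORC1
INADL
RETN
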