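gene,probe_id,coef,p
G0S2,cg19534438,0.34,1.19e-7
BBS9,cg20152234,0.18,1.83e-6
,cg11504264,0.24,2.09e-6
,cg08000207,-0.35,6.64e-6
AHRR,cg05575921,-0.13,9.16e-6
RCCD1,cg25526519,-0.16,9.66e-6
NCK1,cg09423651,-0.53,1.13e-5
CHST11,cg04130728,0.15,1.19e-5
TMLHE,cg12115116,0.25,1.53e-5
,cg20974659,0.11,1.68e-5
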