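gene,probe_id,disc_coef,disc_p,brain_coef,brain_p
CHST11,cg04130728,0.15,1.19e-5,0.32,0.00032
FBXL7,cg11339964,0.11,1.97e-4,0.14,0.020
PHACTR,cg19686983,-0.15,0.00017,-0.31,0.030
OR2AG1,cg12186981,1.12,8.49e-5,-1.15,0.033
C12orf34,cg02742775,0.087,5.18e-5,-0.12,0.042
F9,cg03155646,-0.43,4.32e-5,0.27,0.045
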