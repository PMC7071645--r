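gene,probe_id,disc_coef,disc_p,repl_coef,repl_p
AHRR,cg05575921,-0.13,9.16e-6,-0.23,1.15e-10
APBA2,cg27184903,0.063,0.00023,0.044,4.51e-5
APBA1,cg13580827,-0.060,0.0070,-0.042,6.37e-5
G0S2,cg19534438,0.34,1.19e-7,0.067,0.00092
LOC285696,cg23987134,0.093,8.82e-5,0.039,0.0033
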