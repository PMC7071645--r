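gene,probe_id,coef,p
AHRR,cg05575921,-0.13,9.16e-6
CLEC9A,cg20098659,0.087,0.0098
BRSK1,cg02357741,0.054,0.045
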