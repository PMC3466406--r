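species	in_mis	mutated	excluded_basal
pi3k	1	1	0
c_met	1	1	0
prb	1	1	0
egfr	1	1	0
jak	1	1	0
p53	1	1	0
akt	1	0	0
c_myctrans	1	0	0
pten	0	1	1
raf	0	1	0
arf	0	1	1
smad	0	1	1
atm_atr	0	1	1
ink4a	0	1	1
apc_cdh1	0	0	0
ink4c	0	0	1
c_ebp_alpha	0	0	0
mkk4_7	0	0	0
tsc	0	0	0
fbw7	0	0	0
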