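label	clamps	species	value	source
HGF	EGF=0,HGF=1,IL6=0,Insulin=0,TGFb=0,TNFa=0	DNA_synthesis	1	DNA-content assay, discretized
EGF	EGF=1,HGF=0,IL6=0,Insulin=0,TGFb=0,TNFa=0	DNA_synthesis	1	DNA-content assay, discretized
IL6	EGF=0,HGF=0,IL6=1,Insulin=0,TGFb=0,TNFa=0	DNA_synthesis	1	DNA-content assay, discretized
Insulin	EGF=0,HGF=0,IL6=0,Insulin=1,TGFb=0,TNFa=0	DNA_synthesis	0	DNA-content assay, discretized
TNFa	EGF=0,HGF=0,IL6=0,Insulin=0,TGFb=0,TNFa=1	DNA_synthesis	0	DNA-content assay, discretized
TGFb	EGF=0,HGF=0,IL6=0,Insulin=0,TGFb=1,TNFa=0	DNA_synthesis	0	DNA-content assay, discretized
Insulin+TNFa	EGF=0,HGF=0,IL6=0,Insulin=1,TGFb=0,TNFa=1	DNA_synthesis	1	DNA-content assay, discretized
IL6+Insulin	EGF=0,HGF=0,IL6=1,Insulin=1,TGFb=0,TNFa=0	DNA_synthesis	1	DNA-content assay, discretized
IL6+TNFa	EGF=0,HGF=0,IL6=1,Insulin=0,TGFb=0,TNFa=1	DNA_synthesis	1	DNA-content assay, discretized
HGF+TGFb	EGF=0,HGF=1,IL6=0,Insulin=0,TGFb=1,TNFa=0	DNA_synthesis	0	DNA-content assay, discretized
HGF+Insulin+TGFb	EGF=0,HGF=1,IL6=0,Insulin=1,TGFb=1,TNFa=0	DNA_synthesis	0	DNA-content assay, discretized
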