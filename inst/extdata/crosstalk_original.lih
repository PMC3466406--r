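# Reduced hepatocyte mitogen cross-talk model, original wiring.
# Six ligand inputs feed the JAK, MAPK and PI3K modules; DNA synthesis
# requires both pathways and the absence of TGFb. The mutual
# MAPK <-> PI3K cross-talk arcs carry time scale 2 so the unstimulated
# initial response is determined (the positive loop is opened).
species:
DNA_synthesis 1 normal -
EGF 1 normal -
HGF 1 normal -
IL6 1 normal -
Insulin 1 normal -
JAK 1 normal -
MAPK 1 normal -
PI3K 1 normal -
TGFb 1 normal -
TNFa 1 normal -
rules:
jak_il6: JAK = IL6
mapk_hgf: MAPK = HGF
mapk_egf: MAPK = EGF
mapk_jak: MAPK = JAK
mapk_ins: MAPK = Insulin
mapk_tnfa: MAPK = TNFa
mapk_pi3k: MAPK = PI3K @2
pi3k_hgf: PI3K = HGF
pi3k_egf: PI3K = EGF
pi3k_jak: PI3K = JAK
pi3k_ins: PI3K = Insulin
pi3k_tnfa: PI3K = TNFa
pi3k_mapk: PI3K = MAPK @2
dna: DNA_synthesis = MAPK · PI3K · !TGFb
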