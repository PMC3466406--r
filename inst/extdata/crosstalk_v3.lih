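# Reduced hepatocyte mitogen cross-talk model, refined wiring (version 3).
# Identical to the original except that the single Insulin and TNFa arcs
# into MAPK and PI3K are each replaced by one AND gate requiring
# coactivation by Insulin AND TNFa, capturing their cooperative effect.
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
mapk_ins_tnfa: MAPK = Insulin · TNFa
mapk_pi3k: MAPK = PI3K @2
pi3k_hgf: PI3K = HGF
pi3k_egf: PI3K = EGF
pi3k_jak: PI3K = JAK
pi3k_ins_tnfa: PI3K = Insulin · TNFa
pi3k_mapk: PI3K = MAPK @2
dna: DNA_synthesis = MAPK · PI3K · !TGFb
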