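# MAPK cascade toy with negative feedback from ERK to Raf via a dummy.
# The cycle-closing reaction ERK -> FBdummy carries time scale 2: at full
# time scales the loop leaves Raf/MEK/ERK/FBdummy undetermined (the logical
# image of sustained oscillations), while the initial response opens the
# loop (FBdummy falls to its default 0) and the signal propagates to ERK.
species:
ERK 1 normal -
FBdummy 1 dummy 0
MEK 1 normal -
Raf 1 normal -
Ras 1 normal -
Stimulus 1 normal -
rules:
ras_stim: Ras = Stimulus
raf_ras: Raf = Ras · !FBdummy
mek_raf: MEK = Raf
erk_mek: ERK = MEK
fb_erk: FBdummy = ERK @2
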