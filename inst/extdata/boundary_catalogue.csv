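gene,boundary_id,facing
bcd,1,posterior
cad,1,anterior
hb,1,anterior
hb,2,posterior
hb,3,anterior
hb,4,posterior
Kr,1,anterior
Kr,2,posterior
gt,2,posterior
gt,5,anterior
gt,6,posterior
gt,7,anterior
kni,1,anterior
kni,2,posterior
kni,3,anterior
kni,4,posterior
tll,1,anterior
tll,2,posterior
hkb,1,posterior
hkb,2,anterior
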