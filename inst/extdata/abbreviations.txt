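# biomedical abbreviations that never terminate a sentence (one per line,
# compared against the token ending at a candidate boundary, lower-cased)
al.
e.g.
i.e.
vs.
etc.
fig.
figs.
eq.
eqs.
ref.
refs.
approx.
ca.
cf.
dr.
prof.
no.
nos.
sp.
spp.
subsp.
wt.
vol.
resp.
st.
conc.
max.
min.
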