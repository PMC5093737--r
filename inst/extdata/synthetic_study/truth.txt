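g0066
g0003
g0027
g0067
g0030
g0076
g0018
g0064
g0075
g0042
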