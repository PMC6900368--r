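# Multiplex deletion-screen band interpretation
wt_band: 481
del_band: 254
tolerance: 10
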