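probe_id	sampleA	sampleB
cg0001	90	95
cg0002	110	105
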