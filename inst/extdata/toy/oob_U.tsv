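probe_id	sampleA	sampleB
cg0001	85	88
cg0002	100	99
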