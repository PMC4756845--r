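probe_id	sampleA	sampleB
cg0001	1200.5	1300
cg0002	2200	2100.25
cg0003	5000	5100
cg0004	300	310
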