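probe_id	sampleA	sampleB
cg0001	800	820
cg0002	900	910
cg0003	400	410
cg0004	6000	6100
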