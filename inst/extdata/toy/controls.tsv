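sample_id	control_type	red	green
sampleA	negative	93	113
sampleA	negative	96	116
sampleA	negative	99	119
sampleA	negative	102	122
sampleA	negative	105	125
sampleA	negative	108	128
sampleA	negative	111	131
sampleA	negative	114	134
sampleA	negative	117	137
sampleA	negative	120	140
sampleA	negative	123	143
sampleA	negative	126	146
sampleA	negative	129	149
sampleA	negative	132	152
sampleA	negative	135	155
sampleA	negative	138	158
sampleA	negative	141	161
sampleA	negative	144	164
sampleA	negative	147	167
sampleA	negative	150	170
sampleA	negative	153	173
sampleA	negative	156	176
sampleA	negative	159	179
sampleA	negative	162	182
sampleA	negative	165	185
sampleA	nonpolymorphic_red	5000	150
sampleA	nonpolymorphic_green	160	5200
sampleB	negative	93	113
sampleB	negative	96	116
sampleB	negative	99	119
sampleB	negative	102	122
sampleB	negative	105	125
sampleB	negative	108	128
sampleB	negative	111	131
sampleB	negative	114	134
sampleB	negative	117	137
sampleB	negative	120	140
sampleB	negative	123	143
sampleB	negative	126	146
sampleB	negative	129	149
sampleB	negative	132	152
sampleB	negative	135	155
sampleB	negative	138	158
sampleB	negative	141	161
sampleB	negative	144	164
sampleB	negative	147	167
sampleB	negative	150	170
sampleB	negative	153	173
sampleB	negative	156	176
sampleB	negative	159	179
sampleB	negative	162	182
sampleB	negative	165	185
sampleB	nonpolymorphic_red	5000	150
sampleB	nonpolymorphic_green	160	5200
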